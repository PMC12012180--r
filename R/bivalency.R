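#' Call bivalent domains from H3K4me3 and H3K27me3 peaks
#'
#' A bivalent domain is an H3K4me3 peak with at least one overlapping
#' H3K27me3 peak (at least 1 shared bp); the domain keeps the H3K4me3 peak's
#' span, since H3K27me3 peaks are typically much broader.
#'
#' @param k4_peaks,k27_peaks `GRanges` on the same assembly.
#' @return Subset of `k4_peaks` with an added `overlapping_k27_ids` column
#'   (comma-separated ids of the overlapping H3K27me3 peaks).
#' @export
call_bivalent <- function(k4_peaks, k27_peaks) {
  hits <- GenomicRanges::findOverlaps(k4_peaks, k27_peaks,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  k27_ids <- if (!is.null(k27_peaks$source_id)) k27_peaks$source_id
             else paste0("k27_", seq_along(k27_peaks))
  keep <- sort(unique(q))
  ids_by_k4 <- split(k27_ids[s], q)
  out <- k4_peaks[keep]
  out$overlapping_k27_ids <- vapply(ids_by_k4[as.character(keep)],
                                    paste, "", collapse = ",")
  out
}

#' Promoter mark states for a set of genes at one stage
#'
#' Each gene's promoter window (TSS +/- `flank`) is assigned exactly one
#' state: `bivalent` when the window overlaps a bivalent domain, otherwise
#' `K4_only` / `K27_only` / `none` according to which peak sets overlap the
#' window. A promoter that overlaps a K4 peak and a K27 peak which do not
#' overlap each other is *not* promoted to bivalent (bivalency requires
#' peak-to-peak overlap); it is reported as `K4_only` with the
#' `both_marks_nonoverlapping` flag set.
#'
#' @param tss_table TSS annotation (see [read_tss()]).
#' @param k4_peaks,k27_peaks Per-stage peak sets (`GRanges`).
#' @param bivalent_domains Optional precomputed [call_bivalent()] output;
#'   derived from the peak sets when `NULL`.
#' @param flank Promoter half-width (default 2000).
#' @param assembly Optional assembly.
#' @return data.frame with columns `gene_id`, `state`,
#'   `both_marks_nonoverlapping`.
#' @export
promoter_states <- function(tss_table, k4_peaks, k27_peaks,
                            bivalent_domains = NULL, flank = 2000,
                            assembly = NULL) {
  if (is.null(bivalent_domains)) {
    bivalent_domains <- call_bivalent(k4_peaks, k27_peaks)
  }
  win <- promoter_windows(tss_table, flank = flank, assembly = assembly)
  has_biv <- GenomicRanges::countOverlaps(win, bivalent_domains,
                                          ignore.strand = TRUE) > 0
  has_k4 <- GenomicRanges::countOverlaps(win, k4_peaks,
                                         ignore.strand = TRUE) > 0
  has_k27 <- GenomicRanges::countOverlaps(win, k27_peaks,
                                          ignore.strand = TRUE) > 0
  state <- ifelse(has_biv, "bivalent",
           ifelse(has_k4, "K4_only",
           ifelse(has_k27, "K27_only", "none")))
  data.frame(
    gene_id = tss_table$gene_id,
    state = state,
    both_marks_nonoverlapping = !has_biv & has_k4 & has_k27,
    stringsAsFactors = FALSE
  )
}

#' Promoter mark states across a stage series
#'
#' @param stage_peaks Named list (stage -> list with elements `k4` and `k27`,
#'   each a `GRanges`).
#' @param tss_table TSS annotation.
#' @param flank Promoter half-width.
#' @param assembly Optional assembly.
#' @return Character matrix, genes (rows, named by `gene_id`) by stages
#'   (columns, in canonical order).
#' @export
promoter_state_matrix <- function(stage_peaks, tss_table, flank = 2000,
                                  assembly = NULL) {
  stages <- order_stages(names(stage_peaks))
  cols <- lapply(stages, function(st) {
    promoter_states(tss_table, stage_peaks[[st]]$k4, stage_peaks[[st]]$k27,
                    flank = flank, assembly = assembly)$state
  })
  states <- do.call(cbind, cols)
  dimnames(states) <- list(tss_table$gene_id, stages)
  states
}

#' Restrict a state matrix to the bivalent gene universe
#'
#' The trajectory universe is the set of genes bivalent in at least one of
#' the analyzed stages.
#'
#' @param states Gene-by-stage state matrix.
#' @return Subset of rows bivalent somewhere.
#' @export
bivalent_gene_universe <- function(states) {
  states[rowSums(states == "bivalent") > 0, , drop = FALSE]
}

PROMOTER_STATES <- c("bivalent", "K4_only", "K27_only", "none")

#' Track promoter-state trajectories across consecutive stages
#'
#' @param states Gene-by-stage character matrix of promoter states, complete
#'   (no missing entries) over the tracked gene universe; columns must be
#'   stages in developmental order.
#' @return List with `transitions` (one 4x4 state-by-state count matrix per
#'   consecutive stage pair, named "A->B") and `trajectories` (data.frame
#'   `gene_id`, `trajectory` with ">"-separated state strings, ready for
#'   alluvial-style export).
#' @export
track_trajectories <- function(states) {
  if (anyNA(states)) {
    stop("state matrix must be complete; missing stage assignments found")
  }
  bad <- setdiff(unique(as.vector(states)), PROMOTER_STATES)
  if (length(bad) > 0L) stop("unknown promoter state(s): ",
                             paste(bad, collapse = ", "))
  stages <- colnames(states)
  transitions <- list()
  for (i in seq_len(ncol(states) - 1L)) {
    from <- factor(states[, i], levels = PROMOTER_STATES)
    to <- factor(states[, i + 1L], levels = PROMOTER_STATES)
    transitions[[paste0(stages[i], "->", stages[i + 1L])]] <- table(from, to)
  }
  list(
    transitions = transitions,
    trajectories = data.frame(
      gene_id = rownames(states),
      trajectory = apply(states, 1L, paste, collapse = ">"),
      stringsAsFactors = FALSE
    )
  )
}

#' Persistence fractions between two stages
#'
#' Among genes in `from_state` at `stage_a`, the fraction found in each state
#' at `stage_b`. Fractions sum to 1. With zero genes in `from_state` the
#' result is undefined and reported as all-`NA`.
#'
#' @param states Gene-by-stage state matrix.
#' @param stage_a,stage_b Column names in `states`.
#' @param from_state Origin state (default `"bivalent"`).
#' @return Named numeric vector over the four destination states, with
#'   attribute `n` (number of origin genes).
#' @export
persistence_fractions <- function(states, stage_a, stage_b,
                                  from_state = "bivalent") {
  stopifnot(all(c(stage_a, stage_b) %in% colnames(states)))
  origin <- states[, stage_a] == from_state
  n <- sum(origin)
  if (n == 0L) {
    out <- setNames(rep(NA_real_, length(PROMOTER_STATES)), PROMOTER_STATES)
    attr(out, "n") <- 0L
    return(out)
  }
  dest <- factor(states[origin, stage_b], levels = PROMOTER_STATES)
  out <- as.vector(table(dest)) / n
  names(out) <- PROMOTER_STATES
  attr(out, "n") <- n
  out
}
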