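#' Parse a chromatin-state segmentation (BED4)
#'
#' Segments carry state labels `E<k>` or bare integers in `1..n_states`.
#' Within each chromosome segments must be non-overlapping; gaps are allowed
#' and treated as unassigned (excluded from every denominator downstream).
#'
#' @param lines Character vector of BED4 records.
#' @param n_states Number of model states (default 15).
#' @param assembly Optional assembly.
#' @return Sorted `GRanges` with an integer `state` column.
#' @export
parse_segmentation <- function(lines, n_states = 15, assembly = NULL) {
  idx <- strip_noise_lines(lines)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("segmentation requires 4 columns; offending line ",
         idx[which(lengths(fields) < 4L)[1L]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- parse_int_strict(vapply(fields, `[[`, "", 2L))
  end0 <- parse_int_strict(vapply(fields, `[[`, "", 3L))
  lab <- vapply(fields, `[[`, "", 4L)
  if (anyNA(start0) || anyNA(end0) || any(start0 >= end0)) {
    stop("invalid segment coordinates")
  }
  state <- suppressWarnings(as.integer(sub("^E", "", lab)))
  bad <- is.na(state) | state < 1L | state > n_states
  if (any(bad)) {
    stop("state label out of range 1..", n_states, " at line ",
         idx[which(bad)[1L]], ": ", lab[which(bad)[1L]])
  }
  gr <- granges_from_bed0(chrom, start0, end0, state = state,
                          seqinfo = assembly)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!IRanges::isDisjoint(gr)) {
    stop("segments overlap within a chromosome")
  }
  gr
}

#' Read a segmentation file
#' @inheritParams parse_segmentation
#' @param path File path.
#' @return Sorted `GRanges` with `state`.
#' @export
read_segmentation <- function(path, n_states = 15, assembly = NULL) {
  parse_segmentation(readLines(path), n_states = n_states,
                     assembly = assembly)
}

#' Write a segmentation as BED4
#' @param seg `GRanges` with `state`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_segmentation <- function(seg, path) {
  seg <- GenomicRanges::sort(seg, ignore.strand = TRUE)
  bed <- bed0_from_granges(seg)
  bed$state <- paste0("E", seg$state)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Genomic coverage per chromatin state
#'
#' @param seg Segmentation `GRanges`.
#' @param n_states Number of states (default 15).
#' @return data.frame with `state`, `bp`, `fraction` (over assigned bases;
#'   fractions sum to 1).
#' @export
state_coverage <- function(seg, n_states = 15) {
  bp <- vapply(seq_len(n_states), function(s) {
    sum(as.numeric(GenomicRanges::width(seg[seg$state == s])))
  }, 0)
  data.frame(state = seq_len(n_states), bp = bp, fraction = bp / sum(bp))
}

#' Fraction of variable bases between two segmentations
#'
#' Directional (a -> b): for each state `s`, the fraction of bases labeled
#' `s` in `seg_a` whose `seg_b` label differs, over the bases labeled `s` in
#' `seg_a` that `seg_b` also assigns. Bases assigned in only one segmentation
#' are excluded everywhere. The overall fraction is changed bases over
#' commonly assigned bases. Note the measure is not symmetric in its
#' arguments.
#'
#' @param seg_a,seg_b Segmentations on the same assembly (earlier stage
#'   first).
#' @param n_states Number of states.
#' @return List with `per_state` (data.frame `state`, `common_bp`,
#'   `changed_bp`, `fraction`; `NA` fraction when a state has no commonly
#'   assigned bases) and `overall` (list `common_bp`, `changed_bp`,
#'   `fraction`).
#' @export
variable_bases <- function(seg_a, seg_b, n_states = 15) {
  hits <- GenomicRanges::findOverlaps(seg_a, seg_b, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::ranges(seg_a)[q], GenomicRanges::ranges(seg_b)[s]))
  sa <- seg_a$state[q]; sb <- seg_b$state[s]
  changed <- sa != sb
  common_bp <- vapply(seq_len(n_states), function(st)
    sum(as.numeric(w[sa == st])), 0)
  changed_bp <- vapply(seq_len(n_states), function(st)
    sum(as.numeric(w[sa == st & changed])), 0)
  frac <- ifelse(common_bp > 0, changed_bp / common_bp, NA_real_)
  list(
    per_state = data.frame(state = seq_len(n_states), common_bp = common_bp,
                           changed_bp = changed_bp, fraction = frac),
    overall = list(common_bp = sum(common_bp), changed_bp = sum(changed_bp),
                   fraction = sum(changed_bp) / sum(common_bp))
  )
}

#' Chromatin-state score model
#'
#' State `k` scores `n_states + 1 - k`, so state 1 (active promoter) gets the
#' highest score and state `n_states` (no signal) the lowest (1). Scores are
#' a bijection onto `1..n_states`.
#'
#' @param n_states Number of states (default 15).
#' @param labels Optional character vector of descriptive state labels.
#' @return data.frame with `state`, `score`, `label`.
#' @export
chromatin_state_model <- function(n_states = 15, labels = NULL) {
  if (is.null(labels)) labels <- paste0("E", seq_len(n_states))
  stopifnot(length(labels) == n_states)
  data.frame(state = seq_len(n_states), score = n_states + 1L - seq_len(n_states),
             label = labels)
}

#' Binned chromatin-state score matrix across stages
#'
#' The genome is split into `bin`-bp tiling bins; each bin's score per stage
#' is the length-weighted mean state score over its assigned bases. Bins
#' lacking any assignment in one or more stages are dropped from the matrix.
#'
#' @param segs Named list of segmentations (stage -> `GRanges`).
#' @param assembly Assembly defining the bins.
#' @param n_states Number of states.
#' @param bin Bin width in bp (default 5000).
#' @return Numeric matrix, stages x bins, bin names `chrom:start-end`.
#' @export
state_score_matrix <- function(segs, assembly, n_states = 15, bin = 5000) {
  bins <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(assembly),
                                    tilewidth = bin,
                                    cut.last.tile.in.chrom = TRUE)
  score_rows <- lapply(segs, function(seg) {
    score <- n_states + 1L - seg$state
    hits <- GenomicRanges::findOverlaps(bins, seg, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::ranges(bins)[q], GenomicRanges::ranges(seg)[s]))
    num <- rep(0, length(bins)); den <- rep(0, length(bins))
    if (length(hits) > 0L) {
      nm <- rowsum(w * score[s], group = q)
      dn <- rowsum(w, group = q)
      num[as.integer(rownames(nm))] <- nm[, 1L]
      den[as.integer(rownames(dn))] <- dn[, 1L]
    }
    ifelse(den > 0, num / den, NA_real_)
  })
  scores <- do.call(rbind, score_rows)
  keep <- colSums(is.na(scores)) == 0L
  scores <- scores[, keep, drop = FALSE]
  bed <- bed0_from_granges(bins[keep])
  colnames(scores) <- paste0(bed$chrom, ":", bed$start, "-", bed$end)
  rownames(scores) <- names(segs)
  scores
}

#' Apply an exclusion mask and chromosome whitelist to a segmentation
#'
#' Supports the usual pre-filtering of segmentations before counting:
#' removal of designated regions (e.g. a DSB-hotspot or pseudo-autosomal
#' exclusion BED) and restriction to a chromosome whitelist (e.g. autosomes
#' only).
#'
#' @param seg Segmentation `GRanges`.
#' @param exclude Optional `GRanges` of regions to remove.
#' @param chrom_whitelist Optional character vector of chromosomes to keep.
#' @return Filtered segmentation.
#' @export
filter_segmentation <- function(seg, exclude = NULL, chrom_whitelist = NULL) {
  if (!is.null(chrom_whitelist)) {
    seg <- seg[as.character(GenomicRanges::seqnames(seg)) %in% chrom_whitelist]
  }
  if (!is.null(exclude) && length(exclude) > 0L && length(seg) > 0L) {
    pieces <- GenomicRanges::subtract(
      seg, GenomicRanges::reduce(GenomicRanges::granges(exclude)),
      ignore.strand = TRUE)
    kept <- unlist(pieces, use.names = FALSE)
    kept$state <- rep(seg$state, lengths(pieces))
    seg <- GenomicRanges::sort(kept, ignore.strand = TRUE)
  }
  seg
}
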