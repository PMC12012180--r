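#' Read an FPKM matrix (genes x stages)
#'
#' Tab-separated with header; first column `gene_id`, remaining columns one
#' per stage.
#'
#' @param path File path.
#' @return Numeric matrix, genes (rownames) x stages (colnames).
#' @export
read_fpkm <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  m
}

#' Read a differential-expression table
#'
#' Tab-separated with header columns `gene_id`, `log2_fc`, `p_adj`; such
#' tables are consumed, never fitted, by this package.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_de <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "log2_fc", "p_adj")
  if (!all(need %in% names(tab))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Expressed/repressed flags per gene per stage
#'
#' A gene is expressed at a stage when its FPKM is at least `threshold`;
#' values strictly smaller than the threshold are repressed.
#'
#' @param matrix Genes x stages FPKM matrix.
#' @param threshold Expressed bound, inclusive (default 0.5).
#' @return Character matrix of `"expressed"`/`"repressed"`, same shape.
#' @export
expressed_flags <- function(matrix, threshold = 0.5) {
  out <- ifelse(matrix >= threshold, "expressed", "repressed")
  dimnames(out) <- dimnames(matrix)
  out
}

#' Classify differential-expression calls
#'
#' `up` when `log2_fc >= lfc_min` and `p_adj <= p_max`; `down` when
#' `log2_fc <= -lfc_min` and `p_adj <= p_max`; otherwise `ns`. Bounds are
#' inclusive. Missing adjusted p-values give `ns` with a warning.
#'
#' @param table DE data.frame (`gene_id`, `log2_fc`, `p_adj`).
#' @param lfc_min Absolute log2 fold-change bound (default 0.5).
#' @param p_max Adjusted p bound (default 0.05).
#' @return data.frame with an added `de_class` column.
#' @export
de_classify <- function(table, lfc_min = 0.5, p_max = 0.05) {
  p <- table$p_adj
  if (anyNA(p)) {
    warning(sum(is.na(p)), " gene(s) with missing p_adj classified ns")
  }
  sig <- !is.na(p) & p <= p_max
  cls <- rep("ns", nrow(table))
  cls[sig & table$log2_fc >= lfc_min] <- "up"
  cls[sig & table$log2_fc <= -lfc_min] <- "down"
  table$de_class <- cls
  table
}

#' Filter stage-specifically expressed genes
#'
#' A gene is kept when its maximal stage FPKM is at least `min_peak_fpkm` and
#' at least `specificity_ratio` times the median FPKM of the remaining
#' stages. The defaults are package decisions (the underlying study does not
#' print its criterion).
#'
#' @param matrix Genes x stages FPKM matrix (restricted to the stages of
#'   interest).
#' @param min_peak_fpkm Minimum peak expression (default 1.0).
#' @param specificity_ratio Peak-to-median ratio (default 2.0).
#' @return Character vector of retained gene ids.
#' @export
stage_specific_filter <- function(matrix, min_peak_fpkm = 1.0,
                                  specificity_ratio = 2.0) {
  peak <- apply(matrix, 1L, max)
  med_rest <- vapply(seq_len(nrow(matrix)), function(i) {
    row <- matrix[i, ]
    stats::median(row[-which.max(row)])
  }, 0)
  rownames(matrix)[peak >= min_peak_fpkm & peak >= specificity_ratio * med_rest]
}

#' Peak expression timing of spermatid genes
#'
#' Each gene's peak stage is the argmax of FPKM over the supplied spermatid
#' stages (ties resolved to the earliest stage in developmental order); the
#' label is `early` when the peak falls in `early_stages`, `late` when it
#' falls in `late_stages`, and `unclassified` for all-zero genes.
#'
#' @param matrix Genes x stages FPKM matrix containing all stages in
#'   `early_stages` and `late_stages`.
#' @param early_stages Stages defining early spermiogenesis (default RS2,
#'   RS4).
#' @param late_stages Stages defining late spermiogenesis (default RS8, LS).
#' @return data.frame with `gene_id`, `peak_stage`, `label`.
#' @export
peak_timing <- function(matrix, early_stages = c("RS2", "RS4"),
                        late_stages = c("RS8", "LS")) {
  stages <- c(early_stages, late_stages)
  if (!all(stages %in% colnames(matrix))) {
    stop("matrix must contain stages: ", paste(stages, collapse = ", "))
  }
  sub <- matrix[, order_stages(stages), drop = FALSE]
  peak_idx <- apply(sub, 1L, which.max)  # first max = earliest stage
  peak_stage <- colnames(sub)[peak_idx]
  all_zero <- apply(sub, 1L, function(r) all(r == 0))
  label <- ifelse(all_zero, "unclassified",
           ifelse(peak_stage %in% early_stages, "early", "late"))
  peak_stage[all_zero] <- NA_character_
  data.frame(gene_id = rownames(sub), peak_stage = peak_stage, label = label,
             stringsAsFactors = FALSE)
}

#' Timing-shift signature counts under knockout
#'
#' Given peak-timing labels and per-stage differential-expression tables for
#' knockout versus control, counts the four timing-shift signatures: early
#' genes down at early stages, early genes up at late stages ("early up
#' late"), late genes down at late stages, and late genes up at early stages
#' ("late up early"). A gene is counted once per signature if it qualifies at
#' any stage of the relevant group.
#'
#' @param timing data.frame from [peak_timing()].
#' @param de_by_stage Named list (stage -> DE data.frame).
#' @param early_stages,late_stages Stage groups (defaults as in
#'   [peak_timing()]).
#' @param lfc_min,p_max Classification bounds (see [de_classify()]).
#' @return List with `counts` (named integer vector) and `genes` (named list
#'   of gene-id vectors).
#' @export
timing_shift_summary <- function(timing, de_by_stage,
                                 early_stages = c("RS2", "RS4"),
                                 late_stages = c("RS8", "LS"),
                                 lfc_min = 0.5, p_max = 0.05) {
  class_at <- function(stages, wanted_class) {
    hits <- lapply(stages, function(st) {
      de <- de_by_stage[[st]]
      if (is.null(de)) return(character())
      de <- de_classify(de, lfc_min = lfc_min, p_max = p_max)
      de$gene_id[de$de_class == wanted_class]
    })
    unique(unlist(hits))
  }
  early_genes <- timing$gene_id[timing$label == "early"]
  late_genes <- timing$gene_id[timing$label == "late"]
  genes <- list(
    early_down_early = intersect(early_genes, class_at(early_stages, "down")),
    early_up_late = intersect(early_genes, class_at(late_stages, "up")),
    late_down_late = intersect(late_genes, class_at(late_stages, "down")),
    late_up_early = intersect(late_genes, class_at(early_stages, "up"))
  )
  list(counts = vapply(genes, length, 0L), genes = genes)
}

#' Assign distal domains to their nearest gene within a distance bound
#'
#' The distance from the domain center (`floor((start+end)/2)` in 0-based
#' half-open coordinates) to each TSS is computed; the closest gene is
#' assigned when the distance is at most `max_dist`, with exact ties broken
#' to the lexicographically smaller gene id.
#'
#' @param domains `GRanges` of distal domains.
#' @param tss_table TSS annotation.
#' @param max_dist Assignment bound in bp (default 1e5).
#' @return data.frame with `domain` (index), `gene_id` (`NA` when
#'   unassigned), `distance`.
#' @export
assign_distal_to_gene <- function(domains, tss_table, max_dist = 100000) {
  center0 <- (GenomicRanges::start(domains) - 1L +
                GenomicRanges::end(domains)) %/% 2L
  chroms <- as.character(GenomicRanges::seqnames(domains))
  tss_table <- tss_table[order(tss_table$gene_id), , drop = FALSE]
  out <- data.frame(domain = seq_along(domains),
                    gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(domains)) {
    cand <- tss_table[tss_table$chrom == chroms[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- abs(cand$tss - center0[i])
    j <- which.min(d)  # first minimum = smallest gene_id after the sort
    if (d[j] <= max_dist) {
      out$gene_id[i] <- cand$gene_id[j]
      out$distance[i] <- d[j]
    }
  }
  out
}

#' Classify enhancers by broad-domain and super-enhancer overlap
#'
#' Enhancers are distal H3K27ac peaks: peaks with no overlap of any TSS +/-
#' `flank` window. Each enhancer is `Broad_SEplus` when it overlaps a broad
#' H3K4me3 domain that itself overlaps a super-enhancer, `Broad_SEminus`
#' when it overlaps only broad domains without SE overlap, and `typical`
#' when it overlaps no broad domain.
#'
#' @param k27_peaks `GRanges` of H3K27ac peaks.
#' @param tss_table TSS annotation.
#' @param broad_k4_domains `GRanges` of broad H3K4me3 domains.
#' @param super_enhancers `GRanges` of super-enhancers.
#' @param flank TSS exclusion half-width (default 2000).
#' @param assembly Optional assembly.
#' @return Subset of `k27_peaks` (the enhancers) with an added
#'   `enhancer_class` column.
#' @export
enhancer_classes <- function(k27_peaks, tss_table, broad_k4_domains,
                             super_enhancers, flank = 2000, assembly = NULL) {
  win <- promoter_windows(tss_table, flank = flank, assembly = assembly)
  distal <- GenomicRanges::countOverlaps(k27_peaks, win,
                                         ignore.strand = TRUE) == 0
  enh <- k27_peaks[distal]
  broad_se <- broad_k4_domains[GenomicRanges::countOverlaps(
    broad_k4_domains, super_enhancers, ignore.strand = TRUE) > 0]
  in_broad <- GenomicRanges::countOverlaps(enh, broad_k4_domains,
                                           ignore.strand = TRUE) > 0
  in_broad_se <- GenomicRanges::countOverlaps(enh, broad_se,
                                              ignore.strand = TRUE) > 0
  enh$enhancer_class <- ifelse(in_broad_se, "Broad_SEplus",
                        ifelse(in_broad, "Broad_SEminus", "typical"))
  enh
}

#' Compare eRNA expression across enhancer classes
#'
#' Per-class medians/quartiles plus pairwise two-sided Wilcoxon rank-sum
#' tests. Classes with fewer than two values are summarised but skipped in
#' the tests (with a note).
#'
#' @param erna_values Numeric per-enhancer expression values.
#' @param classes Character class labels, parallel to `erna_values`.
#' @return List with `summary` (data.frame class/n/q25/median/q75) and
#'   `tests` (data.frame class_a/class_b/p_value, `NA` rows skipped).
#' @export
erna_compare <- function(erna_values, classes) {
  stopifnot(length(erna_values) == length(classes))
  cls <- sort(unique(classes))
  if (sum(vapply(cls, function(k) sum(classes == k) > 0, TRUE)) < 2L) {
    stop("need at least two non-empty classes")
  }
  summ <- do.call(rbind, lapply(cls, function(k) {
    v <- erna_values[classes == k]
    data.frame(class = k, n = length(v),
               q25 = unname(stats::quantile(v, 0.25)),
               median = stats::median(v),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  pairs <- utils::combn(cls, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- erna_values[classes == pairs[1L, j]]
    b <- erna_values[classes == pairs[2L, j]]
    p <- if (length(a) < 2L || length(b) < 2L) {
      message("skipping ", pairs[1L, j], " vs ", pairs[2L, j],
              ": class too small")
      NA_real_
    } else {
      stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)$p.value
    }
    data.frame(class_a = pairs[1L, j], class_b = pairs[2L, j], p_value = p)
  }))
  list(summary = summ, tests = tests)
}

#' eRNA expression from read counts
#'
#' FPKM-style normalisation over enhancer intervals:
#' `counts / (width_kb * library_size_millions)`.
#'
#' @param counts Per-enhancer read counts.
#' @param widths Enhancer widths in bp.
#' @param library_size Total mapped reads of the library.
#' @return Numeric expression values.
#' @export
erna_fpkm <- function(counts, widths, library_size) {
  counts / ((widths / 1000) * (library_size / 1e6))
}

#' Row-standardize an expression matrix
#'
#' Each row is centred and scaled to unit standard deviation; constant rows
#' become all-zero and are flagged in the `"constant_rows"` attribute.
#'
#' @param matrix Numeric matrix with at least two columns.
#' @return Z-scored matrix with logical attribute `constant_rows`.
#' @export
zscore_rows <- function(matrix) {
  stopifnot(ncol(matrix) >= 2L)
  mu <- rowMeans(matrix)
  sdv <- apply(matrix, 1L, stats::sd)
  constant <- sdv == 0 | !is.finite(sdv)
  sdv[constant] <- 1
  out <- (matrix - mu) / sdv
  out[constant, ] <- 0
  attr(out, "constant_rows") <- constant
  out
}
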