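#' Consolidate peaks into merged domains
#'
#' Any two peaks separated by no more than `max_gap` bp are consolidated into
#' a single domain (transitive closure of the gap relation, per chromosome).
#' For half-open intervals `[a,b)` and `[c,d)` with `c >= b` the gap is
#' `c - b`; touching intervals (gap 0) always merge. The default 500-bp gap is
#' the consolidation distance used to define broad H3K4me3/H3K27ac domains.
#'
#' @param peaks `GRanges` of peaks (e.g. from [parse_intervals()]), optionally
#'   with `signal` and `source_id` metadata.
#' @param max_gap Maximum gap in bp for consolidation (inclusive; default 500).
#' @return `GRanges` of merged domains, sorted and pairwise separated by more
#'   than `max_gap`, with metadata columns `n_peaks`, `member_peaks`
#'   (comma-separated source ids) and `mean_signal` (width-weighted mean of
#'   member peak signals over the domain span; uncovered bases count 0).
#' @examples
#' p <- parse_intervals(c("chr1\t100\t2000", "chr1\t2500\t4000"))
#' merge_peaks(p, max_gap = 500)  # gap is exactly 500 -> one domain
#' @export
merge_peaks <- function(peaks, max_gap = 500) {
  stopifnot(max_gap >= 0)
  merged <- GenomicRanges::reduce(peaks, min.gapwidth = max_gap + 1,
                                  with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(merged)$revmap
  sig <- if (!is.null(peaks$signal)) peaks$signal else rep(0, length(peaks))
  ids <- if (!is.null(peaks$source_id)) peaks$source_id
         else paste0("peak_", seq_along(peaks))
  pw <- GenomicRanges::width(peaks)
  mean_sig <- vapply(seq_along(merged), function(i) {
    m <- revmap[[i]]
    sum(sig[m] * pw[m])
  }, 0) / GenomicRanges::width(merged)
  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
    n_peaks = lengths(revmap),
    member_peaks = vapply(revmap, function(m) paste(ids[m], collapse = ","), ""),
    mean_signal = mean_sig
  )
  merged
}

#' Classify merged domains as broad or regular
#'
#' A domain strictly wider than `broad_min` bp is broad; all others are
#' regular. The partition is exhaustive and exclusive.
#'
#' @param domains `GRanges` of merged domains.
#' @param broad_min Width threshold in bp, strict (default 5000: domains
#'   "exceeding 5 kb" are broad, so width 5000 itself is regular).
#' @return `domains` with an added `width_class` column
#'   (`"broad"`/`"regular"`).
#' @export
classify_broad <- function(domains, broad_min = 5000) {
  domains$width_class <- ifelse(GenomicRanges::width(domains) > broad_min,
                                "broad", "regular")
  domains
}

#' Split domains into promoter-proximal and distal
#'
#' A domain overlapping (by at least 1 bp) any TSS +/- `flank` window is
#' promoter-proximal; all remaining domains are distal.
#'
#' @param domains `GRanges`.
#' @param tss_table TSS annotation (see [read_tss()]).
#' @param flank Promoter half-width in bp (default 2000).
#' @param assembly Optional assembly for window clipping.
#' @return `domains` with an added `location_class` column
#'   (`"promoter"`/`"distal"`).
#' @export
split_promoter_distal <- function(domains, tss_table, flank = 2000,
                                  assembly = NULL) {
  win <- promoter_windows(tss_table, flank = flank, assembly = assembly)
  hit <- GenomicRanges::countOverlaps(domains, win, ignore.strand = TRUE) > 0
  domains$location_class <- ifelse(hit, "promoter", "distal")
  domains
}

#' Select sharp and random-control domains from regular peaks
#'
#' The `n` regular merged domains with the highest mean signal density are
#' classified as sharp; a same-sized control set is drawn uniformly without
#' replacement from the remainder.
#'
#' @param regular_domains `GRanges` of regular (non-broad) merged domains.
#' @param track Optional signal track; when supplied, per-domain density is
#'   recomputed with [mean_signal()], otherwise the `mean_signal` column is
#'   used.
#' @param n Set size (default 500). Capped (with a warning) at half the input
#'   when fewer domains are available.
#' @param seed Integer seed for the control draw.
#' @return List with `GRanges` elements `sharp` and `control` (disjoint).
#' @export
select_sharp_control <- function(regular_domains, track = NULL, n = 500,
                                 seed = 1L) {
  if (length(regular_domains) == 0L) stop("no regular domains supplied")
  sig <- if (!is.null(track)) mean_signal(track, regular_domains)
         else regular_domains$mean_signal
  if (is.null(sig)) stop("no signal available; supply a track")
  if (n > length(regular_domains) - 1L) {
    n <- max(1L, length(regular_domains) %/% 2L)
    warning("fewer domains than requested; capping n at ", n)
  }
  ord <- order(-sig, as.character(GenomicRanges::seqnames(regular_domains)),
               GenomicRanges::start(regular_domains))
  sharp_idx <- ord[seq_len(n)]
  rest <- ord[-seq_len(n)]
  ctrl_idx <- with_private_seed(seed, sample(rest, size = min(n, length(rest))))
  list(sharp = regular_domains[sort(sharp_idx)],
       control = regular_domains[sort(ctrl_idx)])
}

#' Element-wise overlap (Venn) counts between two interval sets
#'
#' Overlap means at least one shared base. Counts are of elements, so the two
#' overlap counts may differ (one element of `a` can span several of `b`).
#'
#' @param set_a,set_b `GRanges`.
#' @return Named integer vector: `a_overlap_b`, `b_overlap_a`, `a_only`,
#'   `b_only`.
#' @export
overlap_counts <- function(set_a, set_b) {
  a_hit <- GenomicRanges::countOverlaps(set_a, set_b, ignore.strand = TRUE) > 0
  b_hit <- GenomicRanges::countOverlaps(set_b, set_a, ignore.strand = TRUE) > 0
  c(a_overlap_b = sum(a_hit), b_overlap_a = sum(b_hit),
    a_only = sum(!a_hit), b_only = sum(!b_hit))
}

# ROSE-style geometric cutoff: sort signals ascending, rescale ranks and
# signals to [0,1], and find the point whose unit-slope tangent leaves the
# fewest points below it; the signal value there is the cutoff.
rose_cutoff <- function(total_signal) {
  v <- sort(total_signal)
  n <- length(v)
  if (n < 2L) stop("need at least 2 stitched regions for a cutoff")
  if (max(v) == min(v)) return(max(v))
  x <- seq_len(n) / n
  y <- (v - min(v)) / (max(v) - min(v))
  below <- vapply(seq_len(n), function(i) {
    b <- y[i] - x[i]
    sum(y <= x + b)
  }, 0L)
  v[which.min(below)]
}

#' Identify super domains by signal-ranked stitching
#'
#' Reimplementation of the ROSE super-enhancer procedure applied to arbitrary
#' peak sets: peaks within `stitch` bp are stitched into regions, each region
#' is scored by its total signal (mean density times width), regions are
#' ranked ascending, ranks and signals are rescaled to the unit square, and
#' the cutoff is the signal value at the point where the tangent to the
#' scaled rank-signal curve has slope 1. Regions with total signal strictly
#' above the cutoff are super.
#'
#' @param peaks `GRanges` of peaks.
#' @param track Optional signal track to score stitched regions; otherwise
#'   member peak signals are used (see [merge_peaks()]).
#' @param stitch Stitching distance in bp (default 12500, the ROSE default).
#' @return `GRanges` of stitched regions with metadata `total_signal`, `rank`
#'   (1 = strongest), `is_super`; the cutoff itself is stored in
#'   `S4Vectors::metadata()` under `"cutoff"`.
#' @export
super_domains <- function(peaks, track = NULL, stitch = 12500) {
  stitched <- merge_peaks(peaks, max_gap = stitch)
  if (length(stitched) < 2L) {
    stop("fewer than 2 stitched regions; no cutoff exists")
  }
  dens <- if (!is.null(track)) mean_signal(track, stitched)
          else stitched$mean_signal
  total <- dens * GenomicRanges::width(stitched)
  cutoff <- rose_cutoff(total)
  out <- stitched
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    total_signal = total,
    rank = as.integer(rank(-total, ties.method = "first")),
    is_super = total > cutoff
  )
  S4Vectors::metadata(out)$cutoff <- cutoff
  out
}
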