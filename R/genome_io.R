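#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps
#'   countOverlaps reduce pintersect mcols mcols<- sort tileGenome
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols Rle
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo seqinfo<-
#' @importFrom methods is
#' @importFrom stats pchisq rbinom rpois runif setNames median quantile sd
#'   wilcox.test
#' @importFrom utils read.table write.table
NULL

# Coordinate convention: every file format read or written by this package is
# BED-family, i.e. 0-based half-open.  Internally intervals are held as
# Bioconductor GRanges (1-based closed); the two helpers below convert at the
# boundary and nothing else in the package is allowed to add or subtract 1.

granges_from_bed0 <- function(chrom, start0, end0, ..., seqinfo = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    ...
  )
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  gr
}

bed0_from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Describe a genome assembly as an explicit chromosome size table
#'
#' Concrete reference assemblies (mm10, hg19, toy genomes) are all represented
#' the same way: an ordered set of chromosome names with strictly positive
#' base-pair lengths, held as a `Seqinfo` object so that interval validity can
#' be enforced by the container.
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_sizes Integer-like vector of lengths, parallel to
#'   `chrom_names`. May also be passed alone as a named vector.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' genome_assembly(c(chr1 = 2e6, chr2 = 1e6))
#' @export
genome_assembly <- function(chrom_names, chrom_sizes = NULL) {
  if (is.null(chrom_sizes)) {
    chrom_sizes <- unname(chrom_names)
    chrom_names <- names(chrom_names)
  }
  if (is.null(chrom_names) || anyDuplicated(chrom_names) > 0L) {
    stop("chromosome names must be present and unique")
  }
  chrom_sizes <- as.numeric(chrom_sizes)
  if (length(chrom_sizes) != length(chrom_names) ||
      any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("chromosome sizes must be strictly positive and parallel to names")
  }
  GenomeInfoDb::Seqinfo(seqnames = as.character(chrom_names),
                        seqlengths = as.integer(chrom_sizes))
}

#' Read a two-column chromosome sizes table
#'
#' @param path Tab-separated file with columns chromosome name and length.
#' @return A [GenomeInfoDb::Seqinfo] assembly.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "size"))
  genome_assembly(tab$chrom, tab$size)
}

strip_noise_lines <- function(lines) {
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  which(keep)
}

parse_int_strict <- function(x) {
  suppressWarnings(ix <- as.numeric(x))
  ix[!grepl("^-?[0-9]+$", x)] <- NA_real_
  ix
}

#' Parse BED3/BED6/narrowPeak records into peaks
#'
#' Accepts the three common peak dialects on a per-line basis: BED3
#' (chrom, start, end), BED6 (plus name, score, strand) and ENCODE narrowPeak
#' (10 columns; column 7, signalValue, becomes the peak signal). Comment,
#' `track`, `browser` and empty lines are skipped. Coordinates are 0-based
#' half-open as in all BED-family formats.
#'
#' @param lines Character vector of tab-separated records.
#' @param assembly Optional [genome_assembly()] used to attach and validate
#'   chromosome bounds.
#' @return A `GRanges` with metadata columns `source_id` (column 4 where
#'   present, otherwise a generated identifier) and `signal` (narrowPeak
#'   signalValue, else 0).
#' @examples
#' parse_intervals("chr1\t100\t200")
#' @export
parse_intervals <- function(lines, assembly = NULL) {
  idx <- strip_noise_lines(lines)
  if (length(idx) == 0L) {
    return(granges_from_bed0(character(), integer(), integer(),
                             source_id = character(), signal = numeric(),
                             seqinfo = assembly))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop("fewer than 3 tab-separated columns at line ",
         idx[which(ncols < 3L)[1L]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- parse_int_strict(vapply(fields, `[[`, "", 2L))
  end0 <- parse_int_strict(vapply(fields, `[[`, "", 3L))
  bad_int <- is.na(start0) | is.na(end0)
  if (any(bad_int)) {
    stop("non-integer coordinates at line ", idx[which(bad_int)[1L]])
  }
  bad_ord <- start0 >= end0
  if (any(bad_ord)) {
    stop("start >= end at line ", idx[which(bad_ord)[1L]], ": ",
         lines[idx[which(bad_ord)[1L]]])
  }
  source_id <- vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  gen_id <- paste0("peak_", seq_along(fields))
  missing_id <- is.na(source_id) | source_id == "." | source_id == ""
  source_id[missing_id] <- gen_id[missing_id]
  strand <- rep("*", length(fields))
  has_strand <- ncols >= 6L
  strand[has_strand] <- vapply(fields[has_strand], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  signal <- rep(0, length(fields))
  is_np <- ncols >= 10L
  if (any(is_np)) {
    sv <- suppressWarnings(as.numeric(vapply(fields[is_np], `[[`, "", 7L)))
    sv[is.na(sv) | sv < 0] <- 0
    signal[is_np] <- sv
  }
  gr <- granges_from_bed0(chrom, start0, end0, strand = strand,
                          source_id = source_id, signal = signal,
                          seqinfo = assembly)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Read a peak file (BED3/BED6/narrowPeak)
#'
#' @inheritParams parse_intervals
#' @param path File path.
#' @return `GRanges` as in [parse_intervals()].
#' @export
read_peaks <- function(path, assembly = NULL) {
  parse_intervals(readLines(path), assembly = assembly)
}

#' Write intervals as a BED file
#'
#' Records are emitted tab-separated in deterministic (chrom, start, end)
#' order, 0-based half-open, with any metadata columns appended after the
#' canonical six.
#'
#' @param gr `GRanges` to write.
#' @param path Output file.
#' @param extra_cols Metadata column names to append (default: all).
#' @return Invisibly, the path.
#' @export
write_bed <- function(gr, path, extra_cols = names(S4Vectors::mcols(gr))) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  bed <- bed0_from_granges(gr)
  meta <- as.data.frame(S4Vectors::mcols(gr))
  bed$name <- if ("source_id" %in% names(meta)) meta$source_id else "."
  bed$score <- if ("signal" %in% names(meta)) meta$signal else 0
  bed$strand <- as.character(GenomicRanges::strand(gr))
  bed$strand[bed$strand == "*"] <- "."
  extra_cols <- setdiff(extra_cols, c("source_id", "signal"))
  for (col in extra_cols) bed[[col]] <- meta[[col]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse bedGraph step segments into a signal track
#'
#' A signal track is a `GRanges` with a numeric `score`, non-overlapping
#' within each chromosome; uncovered bases read as zero everywhere in the
#' package ("mean0" convention).
#'
#' @param lines Character vector of 4-column bedGraph records.
#' @param assembly Optional assembly to attach.
#' @return `GRanges` with a `score` column.
#' @export
parse_bedgraph <- function(lines, assembly = NULL) {
  idx <- strip_noise_lines(lines)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("bedGraph requires 4 columns; offending line ",
         idx[which(lengths(fields) < 4L)[1L]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- parse_int_strict(vapply(fields, `[[`, "", 2L))
  end0 <- parse_int_strict(vapply(fields, `[[`, "", 3L))
  score <- as.numeric(vapply(fields, `[[`, "", 4L))
  if (anyNA(start0) || anyNA(end0) || any(start0 >= end0)) {
    stop("invalid bedGraph coordinates")
  }
  if (any(!is.finite(score))) stop("bedGraph values must be finite")
  gr <- granges_from_bed0(chrom, start0, end0, score = score,
                          seqinfo = assembly)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!IRanges::isDisjoint(gr)) {
    stop("bedGraph segments overlap within a chromosome")
  }
  gr
}

#' Read a bedGraph signal track
#' @inheritParams parse_bedgraph
#' @param path File path.
#' @return `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path, assembly = NULL) {
  parse_bedgraph(readLines(path), assembly = assembly)
}

#' Write a signal track as bedGraph
#' @param track `GRanges` with a `score` column.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path) {
  track <- GenomicRanges::sort(track, ignore.strand = TRUE)
  bed <- bed0_from_granges(track)
  bed$score <- track$score
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean signal density per base over intervals
#'
#' For each query interval, `sum(value * covered bp) / width`, with bases not
#' covered by the track contributing zero (the `bigWigAverageOverBed` "mean0"
#' convention used to score merged peaks).
#'
#' @param track Signal track (`GRanges` with `score`).
#' @param intervals Query `GRanges`.
#' @return Numeric vector of per-base mean densities, parallel to `intervals`.
#' @export
mean_signal <- function(track, intervals) {
  if (length(intervals) == 0L) return(numeric())
  hits <- GenomicRanges::findOverlaps(intervals, track, ignore.strand = TRUE)
  out <- numeric(length(intervals))
  if (length(hits) > 0L) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::ranges(intervals)[q], GenomicRanges::ranges(track)[s]))
    contrib <- rowsum(ov * track$score[s], group = q)
    out[as.integer(rownames(contrib))] <- contrib[, 1L]
  }
  out / GenomicRanges::width(intervals)
}

#' Spike-in normalization of signal tracks
#'
#' Scales each sample's coverage track by
#' `factor_i = min_j(spike_count_j) / spike_count_i`, so the sample with the
#' fewest exogenous spike-in reads is left unchanged and every other sample is
#' scaled down proportionally.
#'
#' @param tracks Named list of signal tracks (`GRanges` with `score`).
#' @param spike_counts Named numeric vector of aligned spike-in read counts,
#'   strictly positive, names matching `tracks`.
#' @param reference How the reference count is chosen: `"min"` (default,
#'   smallest sample unchanged) or a positive number used as the fixed
#'   reference count.
#' @return List with elements `tracks` (scaled) and `factors`.
#' @examples
#' tr <- parse_bedgraph(c("chr1\t0\t100\t2", "chr1\t100\t200\t4"))
#' spikein_normalize(list(a = tr, b = tr), c(a = 1000, b = 2000))$factors
#' @export
spikein_normalize <- function(tracks, spike_counts, reference = "min") {
  if (is.null(names(tracks)) || !setequal(names(tracks), names(spike_counts))) {
    stop("tracks and spike_counts must share names")
  }
  spike_counts <- spike_counts[names(tracks)]
  if (any(!is.finite(spike_counts)) || any(spike_counts <= 0)) {
    stop("spike-in counts must be strictly positive; normalization undefined")
  }
  ref <- if (identical(reference, "min")) min(spike_counts) else as.numeric(reference)
  factors <- ref / spike_counts
  scaled <- mapply(function(tr, f) {
    tr$score <- tr$score * f
    tr
  }, tracks, factors, SIMPLIFY = FALSE)
  list(tracks = scaled, factors = factors)
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `strand`, `tss`,
#' `tes`; positions are 0-based.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_tss <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(tab))) {
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Write a TSS annotation table
#' @param tss data.frame as returned by [read_tss()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss[, c("gene_id", "chrom", "strand", "tss", "tes")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Symmetric promoter windows around TSSs
#'
#' Builds `[TSS - flank, TSS + flank)` windows (0-based half-open), clipped to
#' chromosome bounds when an assembly is supplied. The window is symmetric, so
#' it is identical for plus- and minus-strand genes.
#'
#' @param tss_table data.frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based TSS position); `strand` is carried through but unused.
#' @param flank Half-width in bp (default 2000, the promoter definition used
#'   throughout: 2 kb either side of the TSS).
#' @param assembly Optional assembly for bounds checking/clipping.
#' @return `GRanges` with metadata column `gene_id`, parallel to rows of
#'   `tss_table`.
#' @export
promoter_windows <- function(tss_table, flank = 2000, assembly = NULL) {
  tss <- as.numeric(tss_table$tss)
  if (!is.null(assembly)) {
    sizes <- GenomeInfoDb::seqlengths(assembly)[as.character(tss_table$chrom)]
    bad <- is.na(sizes) | tss < 0 | tss >= sizes
    if (any(bad)) {
      stop("TSS outside chromosome bounds for gene(s): ",
           paste(tss_table$gene_id[bad], collapse = ", "))
    }
    start0 <- pmax(0, tss - flank)
    end0 <- pmin(as.numeric(sizes), tss + flank)
  } else {
    start0 <- pmax(0, tss - flank)
    end0 <- tss + flank
  }
  granges_from_bed0(as.character(tss_table$chrom), start0, end0,
                    gene_id = tss_table$gene_id, seqinfo = assembly)
}

# run expr with a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
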