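# shared fixture builders and independent oracles

# GRanges from 0-based half-open coordinates (the convention of all examples)
g0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         ...)
}

bed0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

random_peaks <- function(n, chrom = "chr1", max_pos = 1e5,
                         width_range = c(50, 800), signal = TRUE) {
  start0 <- sort(sample.int(max_pos, n))
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  gr <- g0(chrom, start0, start0 + w)
  if (signal) gr$signal <- runif(n, 0, 10)
  gr$source_id <- paste0("p", seq_len(n))
  gr
}

# independent O(n^2) transitive-closure merge oracle: connected components of
# the "gap <= max_gap" graph via igraph, one chromosome at a time
merge_oracle <- function(peaks, max_gap = 500) {
  pieces <- lapply(split(peaks, as.character(GenomicRanges::seqnames(peaks))),
                   function(gr) {
    b <- bed0(gr)
    n <- nrow(b)
    if (n == 1L) return(b)
    # gap between half-open [s1,e1) and [s2,e2): s2-e1 (or s1-e2); overlap
    # or touch gives gap <= 0
    m <- outer(b$start, b$end, `-`)
    gap <- pmax(m, t(m))
    adj <- gap <= max_gap
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    do.call(rbind, lapply(split(seq_len(n), comp), function(ix) {
      data.frame(chrom = b$chrom[ix[1]], start = min(b$start[ix]),
                 end = max(b$end[ix]))
    }))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# per-base brute-force mean0 signal oracle
mean_signal_oracle <- function(track, interval) {
  b <- bed0(interval)
  tb <- bed0(track)
  vals <- numeric(b$end - b$start)
  pos0 <- seq.int(b$start, b$end - 1L)
  for (i in seq_len(nrow(tb))) {
    if (tb$chrom[i] != b$chrom) next
    hit <- pos0 >= tb$start[i] & pos0 < tb$end[i]
    vals[hit] <- track$score[i]
  }
  mean(vals)
}

# build a cytosine call table directly
make_calls <- function(chrom, pos, meth, unmeth, context = "GCH",
                       strand = "+") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, context = context,
                         meth = as.integer(meth),
                         unmeth = as.integer(unmeth))
}

# Jaccard of best-matching called region for each truth region
jaccard_by_truth <- function(truth, called) {
  ov <- GenomicRanges::findOverlaps(truth, called)
  if (length(ov) == 0L) return(numeric())
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(truth[q], called[s]))
  un <- GenomicRanges::width(truth)[q] + GenomicRanges::width(called)[s] - w
  tapply(w / un, q, max)
}
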