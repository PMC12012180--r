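#' @import data.table
NULL

# The NOMe engine works on per-cytosine call tables held as data.tables with
# columns: chrom (character), pos (integer, 0-based position of the C on its
# own strand), strand ("+"/"-"), context ("WCG"/"GCH"/"other"), meth
# (reads supporting C), unmeth (reads supporting T).

RAW_A <- charToRaw("A"); RAW_C <- charToRaw("C")
RAW_G <- charToRaw("G"); RAW_T <- charToRaw("T")

# classify every cytosine position of one chromosome sequence (character
# scalar) on both strands; returns data.table(pos, strand, context)
classify_chrom_cytosines <- function(seq) {
  r <- charToRaw(seq)
  n <- length(r)
  if (n < 1L) return(data.table::data.table(pos = integer(), strand = character(),
                                            context = character()))
  isA <- r == RAW_A; isC <- r == RAW_C; isG <- r == RAW_G; isT <- r == RAW_T
  # plus strand: C at i, preceding base i-1, following base i+1
  ip <- which(isC)
  prev_ok <- ip > 1L
  next_ok <- ip < n
  ctx_p <- rep("other", length(ip))
  prevA_T <- prev_ok & (isA[pmax(ip - 1L, 1L)] | isT[pmax(ip - 1L, 1L)])
  nextG <- next_ok & isG[pmin(ip + 1L, n)]
  ctx_p[prevA_T & nextG] <- "WCG"
  prevG <- prev_ok & isG[pmax(ip - 1L, 1L)]
  nextH <- next_ok & (isA[pmin(ip + 1L, n)] | isC[pmin(ip + 1L, n)] |
                        isT[pmin(ip + 1L, n)])
  ctx_p[prevG & nextH] <- "GCH"
  # minus strand: C on minus = G on plus at i; 5' neighbour on minus is the
  # complement of plus base i+1, 3' neighbour is the complement of plus base
  # i-1
  im <- which(isG)
  prev_ok_m <- im < n       # needs plus base i+1
  next_ok_m <- im > 1L      # needs plus base i-1
  ctx_m <- rep("other", length(im))
  # prev in {A,T} on minus <=> plus base i+1 in {T,A}
  prevW_m <- prev_ok_m & (isA[pmin(im + 1L, n)] | isT[pmin(im + 1L, n)])
  # next == G on minus <=> plus base i-1 == C
  nextG_m <- next_ok_m & isC[pmax(im - 1L, 1L)]
  ctx_m[prevW_m & nextG_m] <- "WCG"
  # prev == G on minus <=> plus base i+1 == C
  prevG_m <- prev_ok_m & isC[pmin(im + 1L, n)]
  # next in {A,C,T} on minus <=> plus base i-1 in {T,G,A}
  nextH_m <- next_ok_m & (isT[pmax(im - 1L, 1L)] | isG[pmax(im - 1L, 1L)] |
                            isA[pmax(im - 1L, 1L)])
  ctx_m[prevG_m & nextH_m] <- "GCH"
  data.table::data.table(
    pos = c(ip, im) - 1L,
    strand = rep(c("+", "-"), c(length(ip), length(im))),
    context = c(ctx_p, ctx_m)
  )
}

#' Classify all cytosines of a genome by trinucleotide context
#'
#' Contexts follow the NOMe-seq convention: `WCG` (ACG/TCG) reads out
#' endogenous CpG methylation, `GCH` (GCA/GCC/GCT) reads out GpC
#' methyltransferase accessibility, and everything else (notably the
#' ambiguous GCG) is `other` and excluded from both analyses. Positions are
#' 0-based coordinates of the cytosine on its own strand; classification uses
#' reverse-complement logic on the minus strand. Cytosines at sequence edges
#' are `other` (context undeterminable).
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @return data.table with columns `chrom`, `pos`, `strand`, `context`,
#'   sorted by (chrom, pos).
#' @export
classify_cytosines <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  out <- data.table::rbindlist(lapply(names(genome), function(ch) {
    dt <- classify_chrom_cytosines(genome[[ch]])
    dt[, chrom := ch]
    dt
  }))
  data.table::setcolorder(out, c("chrom", "pos", "strand", "context"))
  data.table::setkey(out, chrom, pos)
  out[]
}

#' Trinucleotide context of a single cytosine
#'
#' @param genome As in [classify_cytosines()].
#' @param chrom Chromosome name.
#' @param pos 0-based position of the C on `strand`.
#' @param strand `"+"` or `"-"`.
#' @return One of `"WCG"`, `"GCH"`, `"other"`.
#' @export
derive_context <- function(genome, chrom, pos, strand = "+") {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  seq <- genome[[chrom]]
  n <- nchar(seq)
  i <- pos + 1L
  if (i < 1L || i > n) stop("position outside chromosome")
  base <- substr(seq, i, i)
  if (strand == "+") {
    if (base != "C") stop("no cytosine at chrom ", chrom, " pos ", pos, " (+)")
    if (i == 1L || i == n) return("other")
    prev <- substr(seq, i - 1L, i - 1L)
    nxt <- substr(seq, i + 1L, i + 1L)
  } else {
    if (base != "G") stop("no cytosine at chrom ", chrom, " pos ", pos, " (-)")
    if (i == 1L || i == n) return("other")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    prev <- comp[[substr(seq, i + 1L, i + 1L)]]
    nxt <- comp[[substr(seq, i - 1L, i - 1L)]]
  }
  if (prev %in% c("A", "T") && nxt == "G") return("WCG")
  if (prev == "G" && nxt %in% c("A", "C", "T")) return("GCH")
  "other"
}

#' Read a cytosine-report-style call table
#'
#' Tab-separated with header `chrom`, `pos` (0-based), `strand`, `context`,
#' `meth`, `unmeth`.
#'
#' @param path File path.
#' @return Call data.table.
#' @export
read_cytosine_calls <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "strand",
                                                          "context")))
  need <- c("chrom", "pos", "strand", "context", "meth", "unmeth")
  if (!all(need %in% names(dt))) {
    stop("cytosine call table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(dt$meth < 0) || any(dt$unmeth < 0)) stop("negative read counts")
  data.table::setkey(dt, chrom, pos)
  dt[]
}

#' Write a cytosine call table
#' @param calls Call data.table.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_cytosine_calls <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}

#' Per-site methylation/accessibility levels with a depth filter
#'
#' Only sites with read depth at least `min_depth` are retained; the level of
#' a retained site is `meth / (meth + unmeth)`.
#'
#' @param calls Call data.table (any context mix; filter by `context`
#'   beforehand or with the `context` argument).
#' @param min_depth Minimum depth, inclusive (default 3).
#' @param context Optional context to restrict to (`"WCG"` or `"GCH"`).
#' @return data.table of qualifying sites with an added `level` column.
#' @export
site_levels <- function(calls, min_depth = 3, context = NULL) {
  dt <- data.table::as.data.table(calls)
  wanted_ctx <- context
  if (!is.null(wanted_ctx)) dt <- dt[dt$context == wanted_ctx]
  dt <- dt[(dt$meth + dt$unmeth) >= min_depth]
  dt[, level := meth / (meth + unmeth)]
  data.table::setkey(dt, chrom, pos)
  dt[]
}

#' Mean level over regions with a minimum site count
#'
#' Unweighted mean of site levels falling inside each region; regions with
#' fewer than `min_sites` qualifying sites get `NA`.
#'
#' @param levels Site-level table from [site_levels()].
#' @param regions `GRanges` (1-based closed internally; sites at 0-based
#'   position p fall in a region covering base p).
#' @param min_sites Minimum number of sites (default 3).
#' @return data.frame with `n_sites` and `mean_level`, parallel to `regions`.
#' @export
region_mean <- function(levels, regions, min_sites = 3) {
  n <- length(regions)
  out <- data.frame(n_sites = integer(n), mean_level = rep(NA_real_, n))
  if (n == 0L || nrow(levels) == 0L) return(out)
  reg <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,  # 0-based inclusive
    end = GenomicRanges::end(regions),           # 0-based exclusive
    idx = seq_len(n)
  )
  sites <- data.table::data.table(chrom = levels$chrom, start = levels$pos,
                                  end = levels$pos + 1L, level = levels$level)
  data.table::setkey(reg, chrom, start, end)
  ov <- data.table::foverlaps(sites, reg, type = "within", nomatch = NULL)
  if (nrow(ov) > 0L) {
    agg <- ov[, list(n_sites = .N, mean_level = mean(level)), by = "idx"]
    out$n_sites[agg$idx] <- agg$n_sites
    out$mean_level[agg$idx] <- agg$mean_level
  }
  out$mean_level[out$n_sites < min_sites] <- NA_real_
  out
}

#' Fit the whole-genome accessibility background
#'
#' Pools methylated/unmethylated read counts over all depth-qualified GCH
#' sites; the background rate is `meth_total / (meth_total + unmeth_total)`.
#'
#' @param gch_calls Call table (GCH rows are selected if a `context` column
#'   is present).
#' @param min_depth Site depth filter (default 3).
#' @return List with `meth_total`, `unmeth_total`, `rate`, `n_sites`.
#' @export
fit_background <- function(gch_calls, min_depth = 3) {
  dt <- data.table::as.data.table(gch_calls)
  if ("context" %in% names(dt)) dt <- dt[dt$context == "GCH"]
  dt <- dt[(dt$meth + dt$unmeth) >= min_depth]
  mt <- sum(as.numeric(dt$meth)); ut <- sum(as.numeric(dt$unmeth))
  if (mt + ut <= 0) stop("zero total depth; background undefined")
  list(meth_total = mt, unmeth_total = ut, rate = mt / (mt + ut),
       n_sites = nrow(dt))
}

# vectorised Pearson chi-square statistic (1 df, no continuity correction) on
# 2x2 tables [m, u; M, U]; degenerate tables (a zero margin) get statistic 0
chi2_stat <- function(m, u, M, U) {
  m <- as.numeric(m); u <- as.numeric(u)
  n <- m + u + M + U
  stat <- n * (m * U - u * M)^2 /
    ((m + u) * (M + U) * (m + M) * (u + U))
  degenerate <- (m + u) == 0 | (M + U) == 0 | (m + M) == 0 | (u + U) == 0
  stat[degenerate] <- 0
  stat
}

chi2_p <- function(m, u, M, U) {
  stat <- chi2_stat(m, u, M, U)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  degenerate <- (m + u) == 0 | (M + U) == 0 | (m + M) == 0 | (u + U) == 0
  p[degenerate] <- 1
  p
}

#' Chi-square accessibility test against the genome background
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' window (meth, unmeth) read counts versus the pooled background counts.
#' Direction (window rate above background) is enforced downstream as a
#' separate gate, not by halving the p-value.
#'
#' @param meth,unmeth Window read counts (vectorised).
#' @param background Background model from [fit_background()].
#' @return p-values (1 for degenerate tables).
#' @export
chi2_accessibility_test <- function(meth, unmeth, background) {
  chi2_p(meth, unmeth, background$meth_total, background$unmeth_total)
}

#' Scan sliding windows for candidate accessible regions
#'
#' Tiles each chromosome with `window`-bp windows every `step` bp (grid
#' anchored at coordinate 0, so window k covers `[k*step, k*step + window)`),
#' pools the (meth, unmeth) counts of the depth-qualified GCH sites each
#' window contains, and keeps windows whose accessibility exceeds the
#' background rate with chi-square p at most `p_max`.
#'
#' @param gch_levels Depth-qualified GCH site table (from [site_levels()]
#'   with `context = "GCH"`, or any table with chrom/pos/meth/unmeth already
#'   filtered).
#' @param background Background model ([fit_background()]).
#' @param window,step Window width and slide in bp (defaults 100 and 20).
#' @param p_max Candidate significance threshold (default `1e-10`).
#' @return data.table of candidate windows: `chrom`, `start`, `end` (0-based
#'   half-open), `meth`, `unmeth`, `n_sites`, `p`.
#' @export
scan_candidate_windows <- function(gch_levels, background, window = 100,
                                   step = 20, p_max = 1e-10) {
  dt <- data.table::as.data.table(gch_levels)
  out <- lapply(split(dt, dt$chrom), function(cdt) {
    data.table::setorder(cdt, pos)
    pos <- cdt$pos
    cm <- cumsum(as.numeric(cdt$meth))
    cu <- cumsum(as.numeric(cdt$unmeth))
    k_lo <- max(0L, (min(pos) - window + step) %/% step)
    k_hi <- max(pos) %/% step
    starts <- seq.int(k_lo, k_hi) * step
    lo <- findInterval(starts - 1L, pos)        # sites with pos < start
    hi <- findInterval(starts + window - 1L, pos)  # sites with pos < start+window
    keep <- hi > lo
    starts <- starts[keep]; lo <- lo[keep]; hi <- hi[keep]
    cm0 <- c(0, cm); cu0 <- c(0, cu)
    m <- cm0[hi + 1L] - cm0[lo + 1L]
    u <- cu0[hi + 1L] - cu0[lo + 1L]
    data.table::data.table(
      chrom = cdt$chrom[1L], start = starts, end = starts + window,
      meth = m, unmeth = u, n_sites = hi - lo
    )
  })
  cand <- data.table::rbindlist(out)
  if (nrow(cand) == 0L) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      meth = numeric(), unmeth = numeric(), n_sites = integer(),
      p = numeric()))
  }
  cand[, p := chi2_accessibility_test(meth, unmeth, background)]
  cand <- cand[meth / (meth + unmeth) > background$rate & p <= p_max]
  data.table::setorder(cand, chrom, start)
  cand[]
}

#' Call nucleosome-depleted regions from candidate windows
#'
#' Overlapping or book-ended candidate windows are merged into regions,
#' region-level counts are pooled over the qualified GCH sites inside and the
#' chi-square test is recomputed; a region is reported as an NDR only if all
#' three criteria hold: p at most `p_max`, strictly more than
#' `min_sites_exclusive` GCH sites, and width strictly greater than
#' `min_width_exclusive` bp (plus the direction gate, region rate above
#' background).
#'
#' @param candidates Candidate windows from [scan_candidate_windows()].
#' @param gch_levels Depth-qualified GCH site table used for region-level
#'   pooling.
#' @param background Background model.
#' @param p_max Significance threshold (default `1e-10`).
#' @param min_sites_exclusive Exclusive site-count bound (default 5: a region
#'   needs more than 5 sites).
#' @param min_width_exclusive Exclusive width bound in bp (default 140).
#' @param refine_boundaries Refine each merged region to the
#'   maximum-likelihood contiguous run of GCH sites under a two-rate model
#'   (region rate inside, background rate outside), i.e. the contiguous run
#'   maximising the summed per-site binomial log likelihood ratio (default
#'   `TRUE`). The 100-bp seed windows locate accessible patches only to
#'   within about half a window; this parameter-free, deterministic
#'   refinement narrows the reported region to the sites actually supporting
#'   the elevation. All three criteria are evaluated on the refined region.
#' @return `GRanges` of NDRs, disjoint and sorted, with metadata `n_gch`,
#'   `level` (pooled read-level accessibility), `p_value`.
#' @export
call_ndrs <- function(candidates, gch_levels, background, p_max = 1e-10,
                      min_sites_exclusive = 5, min_width_exclusive = 140,
                      refine_boundaries = TRUE) {
  empty <- granges_from_bed0(character(), integer(), integer(),
                             n_gch = integer(), level = numeric(),
                             p_value = numeric())
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  win <- granges_from_bed0(candidates$chrom, candidates$start, candidates$end)
  regions <- GenomicRanges::reduce(win, ignore.strand = TRUE)  # book-ended merge
  reg <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    rstart = GenomicRanges::start(regions) - 1L,
    rend = GenomicRanges::end(regions),
    idx = seq_along(regions)
  )
  dt <- data.table::as.data.table(gch_levels)
  sites <- data.table::data.table(chrom = dt$chrom, start = dt$pos,
                                  end = dt$pos + 1L,
                                  meth = as.numeric(dt$meth),
                                  unmeth = as.numeric(dt$unmeth))
  reg2 <- data.table::data.table(chrom = reg$chrom, start = reg$rstart,
                                 end = reg$rend, idx = reg$idx)
  data.table::setkey(reg2, chrom, start, end)
  ov <- data.table::foverlaps(sites, reg2, type = "within", nomatch = NULL)
  data.table::setorder(ov, idx, i.start)
  # nearest qualified sites just beyond each seed region, used to place
  # refined boundaries at gap midpoints
  out_prev <- rep(NA_integer_, nrow(reg))
  out_next <- rep(NA_integer_, nrow(reg))
  for (ch in unique(reg$chrom)) {
    pos <- sort(dt$pos[dt$chrom == ch])
    ri <- which(reg$chrom == ch)
    kp <- findInterval(reg$rstart[ri] - 1L, pos)    # sites with pos < rstart
    out_prev[ri] <- ifelse(kp >= 1L, as.integer(pos[pmax(kp, 1L)] + 1L),
                           NA_integer_)
    kn <- findInterval(reg$rend[ri] - 1L, pos) + 1L # first site at/after rend
    out_next[ri] <- ifelse(kn <= length(pos),
                           as.integer(pos[pmin(kn, length(pos))]),
                           NA_integer_)
  }
  ov[, `:=`(out_prev = ..out_prev[idx], out_next = ..out_next[idx])]
  p0 <- min(max(background$rate, 1e-12), 1 - 1e-12)
  rows <- lapply(split(ov, ov$idx), function(rs) {
    l <- 1L; r <- nrow(rs)
    sm <- sum(rs$meth); su <- sum(rs$unmeth)
    if (refine_boundaries && sm + su > 0) {
      # report the maximum-likelihood contiguous sub-run of sites under a
      # two-rate model (sites inside the region at the elevated rate,
      # outside at the background rate): maximise the summed per-site
      # binomial log likelihood ratio over contiguous runs. Two iterations
      # so the elevated-rate estimate comes from the refined core.
      for (iter in 1:2) {
        p1 <- min(max(sm / (sm + su), p0 + 1e-12), 1 - 1e-12)
        x <- rs$meth * (log(p1) - log(p0)) +
          rs$unmeth * (log1p(-p1) - log1p(-p0))
        cs <- cumsum(x)
        best <- -Inf; best_l <- 1L; best_r <- 1L
        min_pref <- 0; min_at <- 0L
        for (j in seq_along(x)) {
          val <- cs[j] - min_pref
          if (val > best) { best <- val; best_l <- min_at + 1L; best_r <- j }
          if (cs[j] < min_pref) { min_pref <- cs[j]; min_at <- j }
        }
        l <- best_l; r <- best_r
        sm <- sum(rs$meth[l:r]); su <- sum(rs$unmeth[l:r])
      }
    }
    if (refine_boundaries) {
      # place each boundary midway between the outermost retained site and
      # the nearest excluded (background-classified or outside-region) site:
      # the changepoint is equally likely anywhere in that site-free gap, so
      # the gap midpoint minimises the expected boundary error. Sentinel
      # columns out_prev/out_next carry the nearest site positions beyond
      # the seed region.
      prev_end <- if (l > 1L) rs$i.end[l - 1L] else rs$out_prev[1L]
      next_start <- if (r < nrow(rs)) rs$i.start[r + 1L] else rs$out_next[1L]
      b_start <- if (is.na(prev_end)) rs$i.start[l]
                 else (prev_end + rs$i.start[l]) %/% 2L
      b_end <- if (is.na(next_start)) rs$i.end[r]
               else (rs$i.end[r] + next_start + 1L) %/% 2L
      # refinement only ever narrows the seed region
      b_start <- max(b_start, rs$start[1L])
      b_end <- min(b_end, rs$end[1L])
    } else {
      b_start <- rs$start[1L]
      b_end <- rs$end[1L]
    }
    data.table::data.table(
      chrom = rs$chrom[1L], start = b_start, end = b_end,
      meth = sm, unmeth = su, n_sites = r - l + 1L)
  })
  res <- data.table::rbindlist(rows)
  p <- chi2_accessibility_test(res$meth, res$unmeth, background)
  depth <- res$meth + res$unmeth
  rate <- res$meth / pmax(depth, 1)
  keep <- p <= p_max & res$n_sites > min_sites_exclusive &
    (res$end - res$start) > min_width_exclusive &
    rate > background$rate & depth > 0
  if (!any(keep)) return(empty)
  out <- granges_from_bed0(res$chrom[keep], res$start[keep], res$end[keep],
                           n_gch = res$n_sites[keep],
                           level = rate[keep],
                           p_value = p[keep])
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

# pooled (meth, unmeth, n_sites) of sites inside each region
region_counts <- function(levels, regions) {
  n <- length(regions)
  res <- data.frame(meth = numeric(n), unmeth = numeric(n),
                    n_sites = integer(n))
  if (n == 0L) return(res)
  reg <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    idx = seq_len(n)
  )
  dt <- data.table::as.data.table(levels)
  sites <- data.table::data.table(chrom = dt$chrom, start = dt$pos,
                                  end = dt$pos + 1L,
                                  meth = dt$meth, unmeth = dt$unmeth)
  data.table::setkey(reg, chrom, start, end)
  ov <- data.table::foverlaps(sites, reg, type = "within", nomatch = NULL)
  if (nrow(ov) > 0L) {
    agg <- ov[, list(meth = sum(as.numeric(meth)),
                     unmeth = sum(as.numeric(unmeth)),
                     n_sites = .N), by = "idx"]
    res$meth[agg$idx] <- agg$meth
    res$unmeth[agg$idx] <- agg$unmeth
    res$n_sites[agg$idx] <- agg$n_sites
  }
  res
}

#' One-call NDR detection
#'
#' Convenience wrapper: depth-filter GCH sites, fit the genome background,
#' scan candidate windows and call region-level NDRs.
#'
#' @param calls Cytosine call table (all contexts allowed; GCH selected).
#' @param min_depth Site depth filter.
#' @param window,step,p_max,min_sites_exclusive,min_width_exclusive See
#'   [scan_candidate_windows()] and [call_ndrs()].
#' @return List with `ndrs` (`GRanges`), `background`, `candidates`.
#' @export
find_ndrs <- function(calls, min_depth = 3, window = 100, step = 20,
                      p_max = 1e-10, min_sites_exclusive = 5,
                      min_width_exclusive = 140, refine_boundaries = TRUE) {
  gch <- site_levels(calls, min_depth = min_depth, context = "GCH")
  bg <- fit_background(gch, min_depth = min_depth)
  cand <- scan_candidate_windows(gch, bg, window = window, step = step,
                                 p_max = p_max)
  ndrs <- call_ndrs(cand, gch, bg, p_max = p_max,
                    min_sites_exclusive = min_sites_exclusive,
                    min_width_exclusive = min_width_exclusive,
                    refine_boundaries = refine_boundaries)
  list(ndrs = ndrs, background = bg, candidates = cand)
}

#' Classify NDRs as promoter-proximal or distal
#'
#' Proximal means at least 1 bp overlap with any TSS +/- `flank` window
#' (default 1.5 kb either side of the TSS).
#'
#' @param ndrs `GRanges` of NDRs.
#' @param tss_table TSS annotation.
#' @param flank Half-width (default 1500).
#' @param assembly Optional assembly.
#' @return `ndrs` with an added `location_class` column
#'   (`"proximal"`/`"distal"`).
#' @export
classify_ndrs <- function(ndrs, tss_table, flank = 1500, assembly = NULL) {
  win <- promoter_windows(tss_table, flank = flank, assembly = assembly)
  hit <- GenomicRanges::countOverlaps(ndrs, win, ignore.strand = TRUE) > 0
  ndrs$location_class <- ifelse(hit, "proximal", "distal")
  ndrs
}

#' Merge NDRs across samples
#'
#' Union of all per-sample NDR intervals, merged whenever the gap is at most
#' `gap` bp (default 10).
#'
#' @param ndr_sets List of `GRanges`.
#' @param gap Merge distance, inclusive (default 10).
#' @return Merged `GRanges`.
#' @export
merge_ndrs_across_samples <- function(ndr_sets, gap = 10) {
  all <- do.call(c, lapply(unname(ndr_sets), GenomicRanges::granges))
  GenomicRanges::reduce(all, min.gapwidth = gap + 1, ignore.strand = TRUE)
}

#' Genome-binned level matrix across samples
#'
#' Splits the genome into `bin`-bp bins, computes the mean site level per bin
#' per sample (requiring at least `min_sites` sites), and drops every bin
#' that is undefined in any sample. The resulting samples-by-bins matrix
#' feeds downstream ordination.
#'
#' @param level_sets Named list of site-level tables ([site_levels()]).
#' @param assembly Assembly defining the bins.
#' @param bin Bin width in bp (default 1000).
#' @param min_sites Minimum sites per bin (default 3).
#' @return Numeric matrix, samples x bins; bin names are
#'   `chrom:start-end` (0-based half-open).
#' @export
bin_level_matrix <- function(level_sets, assembly, bin = 1000, min_sites = 3) {
  bins <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(assembly),
                                    tilewidth = bin,
                                    cut.last.tile.in.chrom = TRUE)
  vals <- do.call(rbind, lapply(level_sets, function(lv) {
    region_mean(lv, bins, min_sites = min_sites)$mean_level
  }))  # samples x bins
  keep <- colSums(is.na(vals)) == 0L
  if (!any(keep)) stop("all bins undefined in at least one sample")
  vals <- vals[, keep, drop = FALSE]
  bed <- bed0_from_granges(bins[keep])
  colnames(vals) <- paste0(bed$chrom, ":", bed$start, "-", bed$end)
  rownames(vals) <- names(level_sets)
  vals
}

# build the 10 + body_bins + 10 bin table for one orientation-resolved gene
gene_profile_bins <- function(gene_table, body_bins = 100, flank = 5000,
                              flank_bin = 500) {
  n_flank <- as.integer(flank / flank_bin)
  res <- lapply(seq_len(nrow(gene_table)), function(i) {
    g <- gene_table[i, ]
    lo <- min(g$tss, g$tes); hi <- max(g$tss, g$tes)
    body <- round(seq(lo, hi, length.out = body_bins + 1L))
    up <- seq(lo - flank, lo, by = flank_bin)
    down <- seq(hi, hi + flank, by = flank_bin)
    starts <- c(up[-length(up)], body[-length(body)], down[-length(down)])
    ends <- c(up[-1L], body[-1L], down[-1L])
    bin_index <- seq_len(n_flank + body_bins + n_flank)
    if (g$strand == "-") bin_index <- rev(bin_index)
    data.table::data.table(chrom = g$chrom, start = starts, end = ends,
                           gene_id = g$gene_id, bin = bin_index)
  })
  data.table::rbindlist(res)
}

#' Metagene level profile over scaled gene bodies
#'
#' Each gene body (TSS to TES) is split into `body_bins` fractional bins and
#' extended by `flank` bp on each side split into fixed `flank_bin`-bp bins;
#' bins are strand-flipped so bin 1 is always the 5' end. The per-bin mean of
#' defined region means across genes is returned.
#'
#' @param levels Site-level table.
#' @param gene_table data.frame with `gene_id`, `chrom`, `strand`, `tss`,
#'   `tes` (0-based; numeric order free, orientation comes from `strand`).
#' @param body_bins Number of gene-body bins (default 100).
#' @param flank Flank size in bp (default 5000).
#' @param flank_bin Flank bin size in bp (default 500).
#' @param min_sites Minimum sites per gene-bin (default 3).
#' @return data.frame with `bin`, `mean_level`, `n_genes` (genes contributing
#'   a defined value).
#' @export
gene_body_profile <- function(levels, gene_table, body_bins = 100,
                              flank = 5000, flank_bin = 500, min_sites = 3) {
  bins <- gene_profile_bins(gene_table, body_bins, flank, flank_bin)
  bins <- bins[bins$end > bins$start & bins$start >= 0]
  gr <- granges_from_bed0(bins$chrom, bins$start, bins$end)
  rm_ <- region_mean(levels, gr, min_sites = min_sites)
  dt <- data.table::data.table(bin = bins$bin, level = rm_$mean_level)
  agg <- dt[!is.na(level), list(mean_level = mean(level), n_genes = .N),
            by = "bin"]
  n_bins <- as.integer(2 * flank / flank_bin) + body_bins
  out <- data.frame(bin = seq_len(n_bins), mean_level = NA_real_,
                    n_genes = 0L)
  out$mean_level[agg$bin] <- agg$mean_level
  out$n_genes[agg$bin] <- agg$n_genes
  out
}

#' Accessibility profile around TSSs with baseline subtraction
#'
#' TSS +/- `flank` windows are split into fixed `bin`-bp bins (strand-flipped
#' so bin 1 is always upstream); GCH site levels are pooled per relative bin
#' across all windows. The per-sample baseline -- the genome-wide mean GCH
#' site level -- is subtracted unless `subtract_baseline = FALSE`.
#'
#' @param gch_levels Depth-qualified GCH site-level table.
#' @param tss_table TSS annotation.
#' @param flank Window half-width (default 2000).
#' @param bin Bin size in bp (default 20; gives 200 bins).
#' @param subtract_baseline Subtract the genome-wide mean site level
#'   (default `TRUE`).
#' @return data.frame with `bin`, `offset` (bp of bin start relative to TSS),
#'   `level`, `n_sites`.
#' @export
tss_accessibility_profile <- function(gch_levels, tss_table, flank = 2000,
                                      bin = 20, subtract_baseline = TRUE) {
  n_bins <- as.integer(2 * flank / bin)
  dt <- data.table::as.data.table(gch_levels)
  pieces <- lapply(seq_len(nrow(tss_table)), function(i) {
    g <- tss_table[i, ]
    sel <- dt[dt$chrom == g$chrom & dt$pos >= g$tss - flank &
                dt$pos < g$tss + flank]
    if (nrow(sel) == 0L) return(NULL)
    rel <- sel$pos - (g$tss - flank)
    if (identical(g$strand, "-")) rel <- 2 * flank - 1L - rel
    data.table::data.table(bin = rel %/% bin + 1L, level = sel$level)
  })
  pooled <- data.table::rbindlist(pieces)
  base <- if (subtract_baseline) mean(dt$level) else 0
  out <- data.frame(bin = seq_len(n_bins),
                    offset = (seq_len(n_bins) - 1L) * bin - flank,
                    level = NA_real_, n_sites = 0L)
  if (nrow(pooled) > 0L) {
    agg <- pooled[, list(level = mean(level), n_sites = .N), by = "bin"]
    out$level[agg$bin] <- agg$level - base
    out$n_sites[agg$bin] <- agg$n_sites
  }
  out
}

#' Flag hypomethylated domains
#'
#' A domain is hypomethylated when its mean WCG (endogenous CpG) methylation
#' is defined (at least `min_sites` sites) and strictly below `threshold`.
#'
#' @param domains `GRanges`.
#' @param wcg_levels WCG site-level table.
#' @param threshold Strict upper bound (default 0.3).
#' @param min_sites Minimum WCG sites (default 3).
#' @return data.frame with `hypomethylated` (logical) and `indeterminate`
#'   (too few sites; such domains are excluded from any denominator).
#' @export
hypomethylation_flags <- function(domains, wcg_levels, threshold = 0.3,
                                  min_sites = 3) {
  rm_ <- region_mean(wcg_levels, domains, min_sites = min_sites)
  data.frame(
    hypomethylated = !is.na(rm_$mean_level) & rm_$mean_level < threshold,
    indeterminate = is.na(rm_$mean_level),
    mean_level = rm_$mean_level
  )
}
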