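test_that("trinucleotide context classification follows the WCG/GCH lists", {
  genome <- c(chr1 = "TACGTGCATGCGA")
  #            0123456789...
  expect_equal(derive_context(genome, "chr1", 2, "+"), "WCG")   # ACG
  expect_equal(derive_context(genome, "chr1", 6, "+"), "GCH")   # GCA
  expect_equal(derive_context(genome, "chr1", 10, "+"), "other") # GCG
  # minus strand: G at plus position 4 reads CGT -> C context ACG on minus
  expect_equal(derive_context(genome, "chr1", 3, "-"), "WCG")
  expect_error(derive_context(genome, "chr1", 0, "+"), "no cytosine")
})

test_that("edge cytosines are unclassifiable", {
  genome <- c(chr1 = "CGAAC")
  expect_equal(derive_context(genome, "chr1", 0, "+"), "other")
  expect_equal(derive_context(genome, "chr1", 4, "+"), "other")
})

test_that("genome-wide classification agrees with per-site derivation", {
  withr::with_seed(12, {
    seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                           collapse = ""))
  })
  sites <- classify_cytosines(seqs)
  pick <- sites[sample(nrow(sites), 60)]
  for (i in seq_len(nrow(pick))) {
    expect_equal(derive_context(seqs, pick$chrom[i], pick$pos[i],
                                pick$strand[i]),
                 pick$context[i])
  }
  # every C on either strand is present exactly once
  r <- strsplit(seqs[["chr1"]], "")[[1]]
  expect_equal(nrow(sites), sum(r == "C") + sum(r == "G"))
})

test_that("site levels apply the depth filter and ratio definition", {
  calls <- make_calls("chr1", c(10, 20, 30), meth = c(3, 1, 0),
                      unmeth = c(1, 1, 5))
  lv <- site_levels(calls, min_depth = 3)
  expect_equal(lv$pos, c(10L, 30L))  # depth-2 site excluded
  expect_equal(lv$level, c(0.75, 0))
})

test_that("region means require three sites and match brute force", {
  withr::with_seed(21, {
    pos <- sort(sample.int(5000, 300))
    calls <- make_calls("chr1", pos, meth = rbinom(300, 10, 0.3),
                        unmeth = 10 - rbinom(300, 10, 0.3))
    calls$unmeth <- 10 - calls$meth
    lv <- site_levels(calls)
    regions <- {
      s <- sort(sample.int(4500, 40))
      g0("chr1", s, s + sample(20:500, 40, replace = TRUE))
    }
    rm_ <- region_mean(lv, regions)
    b <- bed0(regions)
    for (i in seq_len(40)) {
      inside <- lv$level[lv$pos >= b$start[i] & lv$pos < b$end[i]]
      if (length(inside) < 3) {
        expect_true(is.na(rm_$mean_level[i]))
      } else {
        expect_equal(rm_$mean_level[i], mean(inside))
      }
    }
  })
  # direct arithmetic example
  lv3 <- site_levels(make_calls("chr1", c(5, 6, 7), c(1, 2, 3), c(4, 3, 2)),
                     min_depth = 3)
  expect_equal(region_mean(lv3, g0("chr1", 0, 10))$mean_level, 0.4)
  expect_true(is.na(region_mean(lv3[1:2], g0("chr1", 0, 10))$mean_level))
})

test_that("background pooling and simulated rate recovery", {
  calls <- make_calls("chr1", c(1, 2), meth = c(3, 1), unmeth = c(7, 9))
  bg <- fit_background(calls)
  expect_equal(bg$meth_total, 4)
  expect_equal(bg$unmeth_total, 16)
  expect_equal(bg$rate, 0.2)

  # all-unmethylated genome
  calls0 <- make_calls("chr1", 1:10, meth = 0, unmeth = 10)
  expect_equal(fit_background(calls0)$rate, 0)

  withr::with_seed(14, {
    n <- 20000; p0 <- 0.1
    depth <- rpois(n, 10)
    m <- rbinom(n, depth, p0)
    sim <- make_calls("chr1", seq_len(n), m, depth - m)
    bg <- fit_background(sim)
    se <- sqrt(p0 * (1 - p0) / sum(depth[depth >= 3]))
    expect_lt(abs(bg$rate - p0), 3 * se)
  })
})

test_that("chi-square test matches the closed-form survival oracle", {
  skip_if_not_installed("pracma")
  bg <- list(meth_total = 1e5, unmeth_total = 9e5,
             rate = 0.1)
  grid <- expand.grid(meth = seq(2, 20, by = 2), unmeth = seq(2, 20, by = 2))
  got <- chi2_accessibility_test(grid$meth, grid$unmeth, bg)
  want <- vapply(seq_len(nrow(grid)), function(i) {
    tab <- c(grid$meth[i], grid$unmeth[i], bg$meth_total, bg$unmeth_total)
    n <- sum(tab)
    rs <- c(tab[1] + tab[2], tab[3] + tab[4])
    cs <- c(tab[1] + tab[3], tab[2] + tab[4])
    e <- outer(rs, cs) / n
    o <- matrix(tab, 2, byrow = TRUE)
    stat <- sum((o - e)^2 / e)
    pracma::erfc(sqrt(stat / 2))
  }, 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("chi-square behaviour at the null, extremes and under row swap", {
  bg <- list(meth_total = 1e5, unmeth_total = 9e5, rate = 0.1)
  # window at exactly the background rate
  expect_gt(chi2_accessibility_test(10, 90, bg), 0.99)
  # strongly accessible window
  expect_lt(chi2_accessibility_test(30, 10, bg), 1e-10)
  # swapping the two rows leaves the statistic unchanged
  bg2 <- list(meth_total = 30, unmeth_total = 10, rate = 0.75)
  expect_equal(chi2_accessibility_test(1e5, 9e5, bg2),
               chi2_accessibility_test(30, 10, bg))
  # degenerate table
  expect_equal(chi2_accessibility_test(0, 0, bg), 1)
})

test_that("window scan finds a run of candidates over an accessible cluster", {
  withr::with_seed(33, {
    pos_bg <- seq(0, 9999, by = 15)
    pos_hi <- seq(5000, 5299, by = 15)
    meth_bg <- rbinom(length(pos_bg), 10, 0.1)
    meth_hi <- rbinom(length(pos_hi), 10, 0.9)
    calls <- rbind(
      make_calls("chr1", pos_bg, meth_bg, 10 - meth_bg),
      make_calls("chr1", pos_hi, meth_hi, 10 - meth_hi))
    calls <- calls[!duplicated(pos)]
    lv <- site_levels(calls)
    bg <- fit_background(lv)
    cand <- scan_candidate_windows(lv, bg)
    # window grid is positional: starts are multiples of the 20-bp step
    expect_true(all(cand$start %% 20 == 0))
    expect_true(all(cand$end - cand$start == 100))
    run <- cand[cand$start >= 4900 & cand$start <= 5300]
    expect_gte(nrow(run), 11)
    expect_true(all(cand$p <= 1e-10))
  })
})

test_that("region criteria are enforced exclusively at the boundaries", {
  bg_calls <- make_calls("chr1", seq(1000, 50000, by = 15), meth = 1,
                         unmeth = 9)
  # exactly 5 strongly accessible sites -> rejected; 6 -> accepted
  five <- make_calls("chr1", seq(300, 460, by = 40), meth = 10, unmeth = 0)
  six <- make_calls("chr1", seq(60000, 60200, by = 40), meth = 10,
                    unmeth = 0)
  calls <- rbind(bg_calls, five, six)
  lv <- site_levels(calls)
  bg <- fit_background(lv)
  cand5 <- data.table::data.table(chrom = "chr1", start = 280L, end = 480L,
                                  meth = 50, unmeth = 0, n_sites = 5L,
                                  p = 0)
  cand6 <- data.table::data.table(chrom = "chr1", start = 59980L,
                                  end = 60220L, meth = 60, unmeth = 0,
                                  n_sites = 6L, p = 0)
  got5 <- call_ndrs(cand5, lv, bg, refine_boundaries = FALSE)
  got6 <- call_ndrs(cand6, lv, bg, refine_boundaries = FALSE)
  expect_length(got5, 0L)
  expect_length(got6, 1L)
  expect_equal(got6$n_gch, 6L)

  # width exactly 140 -> rejected; 141 -> eligible (same six sites)
  c140 <- data.table::data.table(chrom = "chr1", start = 60000L,
                                 end = 60140L, meth = 0, unmeth = 0,
                                 n_sites = 0L, p = 0)
  c141 <- data.table::data.table(chrom = "chr1", start = 60000L,
                                 end = 60141L, meth = 0, unmeth = 0,
                                 n_sites = 0L, p = 0)
  # put 6 hot sites inside [60000, 60140)
  hot <- make_calls("chr1", seq(60000, 60125, by = 25), meth = 10, unmeth = 0)
  lv2 <- site_levels(rbind(bg_calls, hot))
  bg2 <- fit_background(lv2)
  expect_length(call_ndrs(c140, lv2, bg2, refine_boundaries = FALSE), 0L)
  expect_length(call_ndrs(c141, lv2, bg2, refine_boundaries = FALSE), 1L)
})

test_that("every emitted NDR satisfies the three criteria by construction", {
  cfg <- sim_config(seed = 2, chrom_sizes = c(chr1 = 5e5), n_ndr = 10,
                    n_genes = 10)
  nome <- simulate_nome(cfg, simulate_genome(cfg))
  res <- find_ndrs(nome$calls)
  expect_gt(length(res$ndrs), 0L)
  expect_true(all(res$ndrs$p_value <= 1e-10))
  expect_true(all(res$ndrs$n_gch > 5))
  expect_true(all(GenomicRanges::width(res$ndrs) > 140))
  expect_true(all(res$ndrs$level > res$background$rate))
})

test_that("NDR calling is equivariant under 20-bp multiples of translation", {
  cfg <- sim_config(seed = 9, chrom_sizes = c(chr1 = 3e5), n_ndr = 6,
                    n_genes = 10)
  nome <- simulate_nome(cfg, simulate_genome(cfg))
  shift <- 200L
  shifted <- data.table::copy(nome$calls)
  shifted[, pos := pos + shift]
  r1 <- find_ndrs(nome$calls)
  r2 <- find_ndrs(shifted)
  expect_equal(GenomicRanges::start(r2$ndrs),
               GenomicRanges::start(r1$ndrs) + shift)
  expect_equal(GenomicRanges::width(r2$ndrs), GenomicRanges::width(r1$ndrs))
})

test_that("proximal/distal NDR classification uses the 1.5-kb TSS window", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    tss = 10000, tes = 12000)
  ndrs <- g0("chr1", c(9000, 13000), c(9200, 13200))
  got <- classify_ndrs(ndrs, tss)
  expect_equal(got$location_class, c("proximal", "distal"))
})

test_that("cross-sample NDR merging respects the 10-bp gap", {
  a <- g0("chr1", 100, 300)
  b <- g0("chr1", 310, 500)   # gap 10 -> merge
  c_ <- g0("chr1", 511, 700)  # gap 11 -> keep separate
  m <- merge_ndrs_across_samples(list(a, b, c_))
  expect_equal(bed0(m), data.frame(chrom = "chr1", start = c(100, 511),
                                   end = c(500, 700)))
  # idempotent and sample-order invariant
  expect_equal(bed0(merge_ndrs_across_samples(list(m))), bed0(m))
  expect_equal(bed0(merge_ndrs_across_samples(list(c_, b, a))), bed0(m))
})

test_that("binned level matrices drop bins undefined in any sample", {
  asm <- genome_assembly(c(chr1 = 3000))
  mk <- function(pos, level) {
    dt <- make_calls("chr1", pos, meth = round(level * 10),
                     unmeth = 10 - round(level * 10))
    site_levels(dt)
  }
  s1 <- mk(c(100, 200, 300, 1100, 1200, 1300, 2100, 2200, 2300), 0.4)
  s2 <- mk(c(100, 200, 300, 1100, 1200, 2100, 2200, 2300), 0.4)  # bin 2: 2 sites
  m <- bin_level_matrix(list(a = s1, b = s2), asm, bin = 1000)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(colnames(m), c("chr1:0-1000", "chr1:2000-3000"))
  expect_equal(m["a", ], m["b", ])
})

test_that("gene-body profiles are flat on constant fields and mirror by strand", {
  withr::with_seed(17, {
    pos <- sort(sample.int(40000, 4000))
    calls <- make_calls("chr1", pos, meth = 5, unmeth = 5)
    lv <- site_levels(calls)
    genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                        strand = c("+", "-"), tss = c(10000, 30000),
                        tes = c(20000, 22000))
    prof <- gene_body_profile(lv, genes[1, ], body_bins = 20, flank = 2000,
                              flank_bin = 500)
    expect_equal(nrow(prof), 28)
    expect_true(all(abs(prof$mean_level - 0.5) < 1e-12, na.rm = TRUE))
  })
  # mirrored data for a minus-strand gene gives the mirrored profile
  pos_up <- seq(0, 999, by = 20)     # upstream of plus gene at [1000,2000)
  pos_body <- seq(1000, 1999, by = 20)
  calls_p <- rbind(make_calls("chr1", pos_up, 9, 1),
                   make_calls("chr1", pos_body, 1, 9))
  # minus gene at [1000,2000) with its 5' flank on the right
  pos_dn <- seq(2000, 2999, by = 20)
  calls_m <- rbind(make_calls("chr1", pos_dn, 9, 1),
                   make_calls("chr1", pos_body, 1, 9))
  gp <- data.frame(gene_id = "gp", chrom = "chr1", strand = "+",
                   tss = 1000, tes = 2000)
  gm <- data.frame(gene_id = "gm", chrom = "chr1", strand = "-",
                   tss = 2000, tes = 1000)
  pp <- gene_body_profile(site_levels(calls_p), gp, body_bins = 10,
                          flank = 1000, flank_bin = 500)
  pm <- gene_body_profile(site_levels(calls_m), gm, body_bins = 10,
                          flank = 1000, flank_bin = 500)
  expect_equal(pp$mean_level, pm$mean_level)
})

test_that("TSS accessibility profiles subtract the genome baseline", {
  pos <- seq(0, 19999, by = 20)
  calls <- make_calls("chr1", pos, meth = 2, unmeth = 8)
  lv <- site_levels(calls)
  tss <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    tss = 10000, tes = 12000)
  prof <- tss_accessibility_profile(lv, tss)
  expect_equal(nrow(prof), 200)
  expect_true(all(abs(prof$level) < 1e-12, na.rm = TRUE))
  # disabling subtraction adds exactly the baseline constant
  prof2 <- tss_accessibility_profile(lv, tss, subtract_baseline = FALSE)
  expect_equal(prof2$level - prof$level, rep(0.2, 200))
})

test_that("a planted promoter accessibility bump shows up centrally", {
  withr::with_seed(41, {
    pos <- seq(0, 39999, by = 15)
    p <- ifelse(abs(pos - 20000) <= 300, 0.7, 0.1)
    m <- rbinom(length(pos), 10, p)
    lv <- site_levels(make_calls("chr1", pos, m, 10 - m))
    tss <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 20000, tes = 25000)
    prof <- tss_accessibility_profile(lv, tss)
    centre <- prof$level[prof$offset >= -200 & prof$offset < 200]
    flank <- prof$level[abs(prof$offset) > 1000]
    expect_gt(mean(centre, na.rm = TRUE), 0.4)
    expect_lt(abs(mean(flank, na.rm = TRUE)), 0.05)
  })
})

test_that("hypomethylation flags use a strict 0.3 bound and report indeterminates", {
  mk_dom <- g0("chr1", c(0, 1000, 2000), c(500, 1500, 2500))
  calls <- rbind(
    make_calls("chr1", c(10, 20, 30), meth = 2, unmeth = 8, context = "WCG"),
    make_calls("chr1", c(1010, 1020, 1030), meth = 3, unmeth = 7,
               context = "WCG"),
    make_calls("chr1", c(2010, 2020), meth = 0, unmeth = 10,
               context = "WCG"))
  lv <- site_levels(calls, context = "WCG")
  fl <- hypomethylation_flags(mk_dom, lv)
  expect_equal(fl$hypomethylated, c(TRUE, FALSE, FALSE))  # 0.2, 0.30, NA
  expect_equal(fl$indeterminate, c(FALSE, FALSE, TRUE))
})
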