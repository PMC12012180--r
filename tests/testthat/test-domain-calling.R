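test_that("peaks within 500 bp merge, 501 bp stay separate", {
  p <- parse_intervals(c("chr1\t100\t2000", "chr1\t2500\t4000"))
  m <- merge_peaks(p, max_gap = 500)
  expect_equal(bed0(m), data.frame(chrom = "chr1", start = 100, end = 4000))
  expect_equal(m$n_peaks, 2L)

  p2 <- parse_intervals(c("chr1\t100\t2000", "chr1\t2501\t4000"))
  expect_length(merge_peaks(p2, max_gap = 500), 2L)

  # touching intervals always merge, even at max_gap = 0
  p3 <- parse_intervals(c("chr1\t0\t10", "chr1\t10\t20"))
  expect_length(merge_peaks(p3, max_gap = 0), 1L)
})

test_that("merge_peaks matches the O(n^2) transitive-closure oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(7, {
    for (rep in 1:20) {
      peaks <- random_peaks(sample(5:120, 1), max_pos = 3e4,
                            width_range = c(50, 600))
      got <- bed0(merge_peaks(peaks, max_gap = 500))
      want <- merge_oracle(peaks, max_gap = 500)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  })
})

test_that("merge_peaks is idempotent and input-order invariant", {
  withr::with_seed(3, {
    peaks <- random_peaks(80, max_pos = 2e4, width_range = c(100, 900))
    m1 <- merge_peaks(peaks)
    m2 <- merge_peaks(m1)
    expect_equal(bed0(m1), bed0(m2))
    perm <- sample(length(peaks))
    expect_equal(bed0(merge_peaks(peaks[perm])), bed0(m1))
  })
})

test_that("broad classification is a strict 5-kb partition", {
  d <- g0("chr1", c(0, 10000, 30000), c(5001, 15000, 35000))
  d <- classify_broad(d)
  expect_equal(d$width_class, c("broad", "regular", "regular"))
  expect_equal(sum(d$width_class == "broad") +
                 sum(d$width_class == "regular"), length(d))
})

test_that("promoter/distal split uses >=1 bp window overlap", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    tss = 10000, tes = 15000)
  d <- g0("chr1", c(8000, 12000), c(9000, 13000))
  d <- split_promoter_distal(d, tss, flank = 2000)
  # [8000,9000) overlaps [8000,12000); [12000,13000) does not (half-open)
  expect_equal(d$location_class, c("promoter", "distal"))
})

test_that("promoter/distal split matches the all-pairs overlap oracle", {
  withr::with_seed(19, {
    d <- random_peaks(60, max_pos = 8e4, width_range = c(100, 3000))
    tss <- data.frame(gene_id = paste0("g", 1:15), chrom = "chr1",
                      strand = "+", tss = sample.int(8e4, 15), tes = 0)
    got <- split_promoter_distal(d, tss, flank = 2000)$location_class
    b <- bed0(d)
    want <- vapply(seq_len(nrow(b)), function(i) {
      hit <- any(pmax(tss$tss - 2000, 0) < b$end[i] &
                   b$start[i] < tss$tss + 2000)
      if (hit) "promoter" else "distal"
    }, "")
    expect_equal(got, want)
  })
})

test_that("sharp/control selection is deterministic and disjoint", {
  withr::with_seed(5, {
    d <- random_peaks(50, max_pos = 1e5)
  })
  d$mean_signal <- d$signal
  s1 <- select_sharp_control(d, n = 10, seed = 99)
  s2 <- select_sharp_control(d, n = 10, seed = 99)
  expect_equal(bed0(s1$control), bed0(s2$control))
  expect_equal(bed0(s1$sharp),
               bed0(d[order(-d$mean_signal)][1:10][order(
                 GenomicRanges::start(d[order(-d$mean_signal)][1:10]))]))
  expect_length(GenomicRanges::findOverlaps(s1$sharp, s1$control,
                                            type = "equal"), 0L)
  s3 <- select_sharp_control(d, n = 10, seed = 100)
  expect_false(identical(bed0(s1$control), bed0(s3$control)))

  # ties broken by coordinate, deterministically
  dt <- g0("chr1", c(300, 100, 200), c(400, 150, 280))
  dt$mean_signal <- c(1, 1, 1)
  st <- select_sharp_control(dt, n = 1, seed = 1)
  expect_equal(bed0(st$sharp)$start, 100)
})

test_that("overlap counts are element-wise and asymmetric", {
  a <- g0("chr1", c(0, 1000), c(100, 1100))
  b <- g0("chr1", c(5000, 6000), c(5100, 6100))
  expect_equal(unname(overlap_counts(a, b)), c(0, 0, 2, 2))
  expect_equal(unname(overlap_counts(a, a)), c(2, 2, 0, 0))
  # one a-element spanning two b-elements
  a2 <- g0("chr1", 0, 1000)
  b2 <- g0("chr1", c(100, 700), c(200, 800))
  expect_equal(unname(overlap_counts(a2, b2)), c(1, 2, 0, 0))
})

test_that("super-domain elbow isolates a single outlier", {
  withr::with_seed(1, {
    starts <- seq(0, by = 20000, length.out = 20)
    peaks <- g0("chr1", starts, starts + 1000)
    peaks$signal <- c(rep(1, 19), 1000)
    peaks$source_id <- paste0("p", 1:20)
  })
  sup <- super_domains(peaks, stitch = 500)
  expect_equal(sum(sup$is_super), 1L)
  expect_true(sup$is_super[which.max(sup$total_signal)])
  # scale invariance of the super set
  peaks2 <- peaks; peaks2$signal <- peaks2$signal * 37
  sup2 <- super_domains(peaks2, stitch = 500)
  expect_equal(sup$is_super, sup2$is_super)
})

test_that("flat signal curves produce zero supers and tiny sets error", {
  starts <- seq(0, by = 20000, length.out = 10)
  peaks <- g0("chr1", starts, starts + 1000)
  peaks$signal <- rep(3, 10)
  sup <- super_domains(peaks, stitch = 500)
  expect_equal(sum(sup$is_super), 0L)
  expect_error(super_domains(peaks[1], stitch = 500), "2 stitched regions")
})

test_that("the elbow cutoff matches a dense-grid tangent-slope-1 oracle", {
  # strictly convex rank curve: unique point where the scaled tangent slope
  # crosses 1
  n <- 60
  starts <- seq(0, by = 20000, length.out = n)
  peaks <- g0("chr1", starts, starts + 1000)
  peaks$signal <- (1:n)^2 / 100
  sup <- super_domains(peaks, stitch = 500)
  cutoff <- S4Vectors::metadata(sup)$cutoff

  # oracle: interpolate the scaled curve on a dense grid; first grid point
  # whose numerical derivative reaches 1 marks the elbow
  v <- sort(sup$total_signal)
  x <- seq_len(n) / n
  y <- (v - min(v)) / (max(v) - min(v))
  grid <- seq(1 / n, 1, length.out = 20000)
  yg <- approx(x, y, xout = grid, rule = 2)$y
  slope <- diff(yg) / diff(grid)
  ix <- which(slope >= 1)[1]
  oracle_idx <- ceiling(grid[ix] * n)
  got_idx <- which(abs(v - cutoff) < 1e-9)[1]
  expect_lte(abs(got_idx - oracle_idx), 1L)
  # the resulting super set agrees up to that one rank step
  expect_lte(abs(sum(sup$is_super) - sum(v > v[oracle_idx])), 1L)
})

test_that("stitching uses the stitch distance on gap-consolidation semantics", {
  p <- parse_intervals(c("chr1\t0\t1000", "chr1\t13500\t14000",
                         "chr1\t40000\t41000"))
  p$signal <- c(1, 1, 1)
  m <- merge_peaks(p, max_gap = 12500)
  expect_length(m, 2L)  # gap 12500 merges, larger gap does not
})
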