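test_that("genome simulation is bit-reproducible and respects GC bounds", {
  cfg <- sim_config(seed = 5, chrom_sizes = c(chr1 = 50000), n_genes = 10)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)

  # GC 0 gives no GCH sites at all
  cfg0 <- sim_config(seed = 5, chrom_sizes = c(chr1 = 20000), n_genes = 10,
                     gc_content = 1e-9)
  g0_ <- simulate_genome(cfg0)
  sites <- classify_cytosines(g0_$genome)
  expect_equal(sum(sites$context == "GCH"), 0L)
})

test_that("GCH density matches its trinucleotide expectation", {
  cfg <- sim_config(seed = 3, chrom_sizes = c(chr1 = 1e6), n_genes = 10,
                    gc_content = 0.5)
  g <- simulate_genome(cfg)
  sites <- classify_cytosines(g$genome)
  n_gch <- sum(sites$context == "GCH")
  # per strand: P(G) * P(C) * P(H); two strands
  p <- 0.25 * 0.25 * 0.75 * 2
  expectation <- p * 1e6
  sdev <- sqrt(1e6 * p * (1 - p)) * 2  # conservative for overlapping sites
  expect_lt(abs(n_gch - expectation), 3 * sdev)
})

test_that("planted peak landscape is recovered exactly by domain calling", {
  cfg <- sim_config(seed = 10)
  genes <- simulate_genes(cfg)
  pk <- simulate_peaks(cfg, genes)
  stage <- pk$truth$broad_stages[1]
  d <- classify_broad(merge_peaks(pk$peaks[[stage]]))
  broad <- d[d$width_class == "broad"]
  expect_equal(bed0(broad), bed0(pk$truth$broad))
  # a stage without planted broads yields zero broad calls
  no_broad_stage <- setdiff(cfg$stages, pk$truth$broad_stages)[1]
  d2 <- classify_broad(merge_peaks(pk$peaks[[no_broad_stage]]))
  expect_equal(sum(d2$width_class == "broad"), 0L)
  # scaling all signals by 10 changes no classification
  p10 <- pk$peaks[[stage]]
  p10$signal <- p10$signal * 10
  d3 <- classify_broad(merge_peaks(p10))
  expect_equal(d3$width_class, d$width_class)
})

test_that("promoter/distal truth labels match the pipeline split", {
  cfg <- sim_config(seed = 10)
  genes <- simulate_genes(cfg)
  pk <- simulate_peaks(cfg, genes)
  stage <- pk$truth$broad_stages[1]
  d <- split_promoter_distal(
    classify_broad(merge_peaks(pk$peaks[[stage]])), genes)
  broad <- d[d$width_class == "broad"]
  expect_equal(broad$location_class, pk$truth$broad$location_class)
})

test_that("null NOMe genomes (p1 = p0) yield no NDR calls", {
  cfg <- sim_config(seed = 20, chrom_sizes = c(chr1 = 1e6), n_genes = 10,
                    p1 = 0.1)
  nome <- simulate_nome(cfg, simulate_genome(cfg))
  res <- find_ndrs(nome$calls)
  expect_length(res$ndrs, 0L)
})

test_that("NOMe simulation respects the binomial model inside and outside NDRs", {
  cfg <- sim_config(seed = 30, chrom_sizes = c(chr1 = 1e6), n_genes = 10)
  nome <- simulate_nome(cfg, simulate_genome(cfg))
  gch <- site_levels(nome$calls, context = "GCH")
  tb <- bed0(nome$truth)
  inside <- rep(FALSE, nrow(gch))
  for (i in seq_len(nrow(tb))) {
    inside <- inside | (gch$pos >= tb$start[i] & gch$pos < tb$end[i])
  }
  rate_in <- sum(gch$meth[inside]) / sum(gch$meth[inside] + gch$unmeth[inside])
  rate_out <- sum(gch$meth[!inside]) /
    sum(gch$meth[!inside] + gch$unmeth[!inside])
  expect_lt(abs(rate_in - cfg$p1), 0.05)
  expect_lt(abs(rate_out - cfg$p0), 0.005)
  # WCG methylation sits at its own level
  wcg <- site_levels(nome$calls, context = "WCG")
  expect_lt(abs(mean(wcg$level) - cfg$wcg_level), 0.02)
})

test_that("segmentations with zero and unit change rates hit the extremes", {
  cfg0 <- sim_config(seed = 40, chrom_sizes = c(chr1 = 1e5), n_genes = 10,
                     change_rates = rep(0, 15))
  s0 <- simulate_segmentations(cfg0)
  for (j in seq_along(s0$segs)[-1]) {
    vb <- variable_bases(s0$segs[[j - 1]], s0$segs[[j]])
    expect_equal(vb$overall$fraction, 0)
  }
  cfg1 <- sim_config(seed = 40, chrom_sizes = c(chr1 = 1e5), n_genes = 10,
                     change_rates = rep(1, 15))
  s1 <- simulate_segmentations(cfg1)
  vb1 <- variable_bases(s1$segs[[1]], s1$segs[[2]])
  expect_equal(vb1$overall$fraction, 1)
})

test_that("a null knockout produces no differential calls", {
  cfg <- sim_config(seed = 50, ko_dampening = 1, ko_leak = 1)
  ex <- simulate_expression(cfg)
  for (de in ex$de_by_stage) {
    expect_true(all(de_classify(de)$de_class == "ns"))
  }
})

test_that("the default knockout signature counts equal the planted counts", {
  cfg <- sim_config(seed = 60)
  ex <- simulate_expression(cfg)
  keep <- stage_specific_filter(ex$control)
  expect_setequal(keep, ex$truth$gene_id[ex$truth$timed])
  timing <- peak_timing(ex$control[keep, ])
  truth <- ex$truth[match(timing$gene_id, ex$truth$gene_id), ]
  expect_equal(timing$label, truth$label)
  expect_equal(timing$peak_stage, truth$peak_stage)
  shift <- timing_shift_summary(timing, ex$de_by_stage)
  expect_equal(shift$counts[names(ex$expected_counts)],
               ex$expected_counts, ignore_attr = TRUE)
})

test_that("emitted files re-parse through the readers without loss", {
  cfg <- sim_config(seed = 70, chrom_sizes = c(chr1 = 3e5, chr2 = 3e5),
                    n_genes = 30, n_broad = 6, n_regular = 40, n_ndr = 6,
                    n_timed = 12, n_bivalent = 8, n_biv_affected = 4)
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, out_dir = dir)
  stage <- cfg$stages[1]
  peaks <- read_peaks(file.path(dir, paste0("k4me3_", stage, ".narrowPeak")))
  expect_equal(bed0(peaks), bed0(sim$peaks$peaks[[stage]]))
  expect_equal(peaks$signal, sim$peaks$peaks[[stage]]$signal,
               tolerance = 1e-9)
  track <- read_bedgraph(file.path(dir, paste0("k4me3_", stage, ".bedGraph")))
  expect_equal(bed0(track), bed0(sim$peaks$tracks[[stage]]))
  seg <- read_segmentation(file.path(dir, paste0("segments_", stage, ".bed")))
  expect_equal(seg$state, sim$segs$segs[[stage]]$state)
  calls <- read_cytosine_calls(file.path(dir, "cytosine_calls.tsv"))
  expect_equal(nrow(calls), nrow(sim$nome$calls))
  fpkm <- read_fpkm(file.path(dir, "fpkm_control.tsv"))
  expect_equal(fpkm, sim$expr$control)
  tss <- read_tss(file.path(dir, "genes.tsv"))
  expect_equal(tss$gene_id, sim$genes$gene_id)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})

test_that("the whole dataset generator is deterministic under its seed", {
  cfg <- sim_config(seed = 80, chrom_sizes = c(chr1 = 2e5), n_genes = 20,
                    n_broad = 4, n_regular = 30, n_ndr = 4, n_timed = 8,
                    n_bivalent = 6, n_biv_affected = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
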