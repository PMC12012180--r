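# spermEpi

Downstream analytics for stage-resolved epigenomic profiling of developing
male germ cells. Spermatogenesis traverses a fixed developmental axis —
mitotic spermatogonia (Undiff, A1, B), meiotic spermatocytes (pL, L, Z, mP,
D), round spermatids (RS2, RS4, RS8), elongating spermatids (LS), mature
sperm — and the chromatin data collected along it need several bespoke
computations once generic processing (alignment, peak calling, segmentation
training, DE fitting) is done. This package implements those computations
for analysts working with such data:

* **Broad H3K4me3/H3K27ac domain calling** — peaks within 500 bp are
  consolidated; merged domains wider than 5 kb are *broad*; domains are
  split promoter/distal against TSS ± 2 kb windows; *sharp* (top-500 by mean
  density) and random control sets support contrast analyses; ROSE-style
  stitching (12.5 kb) with the unit-slope tangent cutoff on the scaled
  rank–signal curve identifies *super* domains.
* **NOMe-seq engine** — WCG/GCH cytosine context classification,
  depth-filtered (≥ 3 reads) site levels, region means (≥ 3 sites), and
  nucleosome-depleted region (NDR) detection: 100-bp windows every 20 bp
  tested by Pearson χ² against the genome background, merged, boundary-
  refined to the maximum-likelihood site run, and kept only when *P* ≤ 1e-10
  with > 5 GCH sites over > 140 bp. Proximal/distal classification (TSS
  ± 1.5 kb), cross-sample merging (10 bp), binned matrices and metagene/TSS
  profiles with baseline subtraction.
* **Bivalent promoter dynamics** — H3K4me3 peaks overlapping H3K27me3 peaks
  define bivalent domains; promoter states (bivalent / K4_only / K27_only /
  none) are tracked across stages into transition tables, trajectory
  strings and persistence fractions.
* **Chromatin-state segmentation dynamics** — per-state coverage, the
  directional fraction of variable bases between adjacent stages, and 5-kb
  binned state-score matrices (state 1 → score 15 … state 15 → score 1).
* **Expression timing** — expressed/repressed flags (FPKM 0.5), DE classes
  (|log₂FC| ≥ 0.5, adjusted p ≤ 0.05), stage-specificity filtering, early
  (RS2/RS4) vs late (RS8/LS) peak-timing labels, and knockout timing-shift
  signatures ("early gene up late, late gene up early"); distal-domain
  gene assignment within 100 kb; enhancer classes and eRNA comparisons.
* **Synthetic-data generator** — emits every input above (FASTA, narrowPeak,
  bedGraph, cytosine calls, segmentation BEDs, FPKM/DE tables) with ground
  truth, so the full pipeline is verifiable on a 4-Mb toy genome in
  seconds.

## Worked example

```r
library(spermEpi)

cfg <- sim_config(seed = 1)          # demo conditions: 2 x 2 Mb, 200 genes,
sim <- simulate_dataset(cfg)         # 40 broad domains, 50 NDRs, 5 stages

# broad-domain calling on the RS4 stage
domains <- split_promoter_distal(
  classify_broad(merge_peaks(sim$peaks$peaks[["RS4"]])),
  sim$genes)
table(domains$width_class, domains$location_class)
#>           distal promoter
#>   broad        9       31
#>   regular    298      102

# NDR detection
ndr <- find_ndrs(sim$nome$calls)
ndr$background$rate                  # 0.102 — the genome background
length(ndr$ndrs)                     # 50 (all planted regions, no false calls)
head(as.data.frame(ndr$ndrs), 3)
#>   seqnames  start    end width strand n_gch     level       p_value
#> 1     chr1  11724  12012   289      *    17 0.6390533 1.243765e-117
#> 2     chr1  84016  84310   295      *    20 0.6446701 1.286857e-139
#> 3     chr1 191111 191417   307      *    26 0.6425856 2.831872e-184

# knockout timing-shift signatures
ex <- simulate_expression(cfg, gene_ids = sim$genes$gene_id)
timing <- peak_timing(ex$control[stage_specific_filter(ex$control), ])
timing_shift_summary(timing, ex$de_by_stage)$counts
#> early_down_early    early_up_late   late_down_late    late_up_early
#>               30               30               30               30
```

The 40 merged domains wider than 5 kb are exactly the 40 planted broad
domains (31 over promoters, 9 distal, matching the planted geometry). All 50
planted NDRs are recovered with in-region accessibility near the simulated
0.6 against the 0.1 background. Each of the 30 planted early genes is
significantly up at a late stage in the knockout and vice versa — the
timing-shift signature the analysis is designed to quantify.

The same analyses run from files behind one configuration:

```r
cfg <- run_config(seed = 1, sim_dir = "sim", out_dir = "out")
run_subcommand("simulate", cfg)   # writes the full input tree + ground truth
run_subcommand("all", cfg)        # domains, ndr, bivalency, states, timing
```

Each run writes a manifest JSON (version, parameters, input digests, summary
counts); reruns are byte-identical. A thin CLI wrapper is installed at
`inst/scripts/spermepi.R`.

## Documentation

The methods vignette (`vignettes/spermatid-epigenome-analytics.Rmd`)
describes the models, every threshold with its default and rationale, the
boundary-refinement procedure for NDRs, what the synthetic data do and do
not emulate, and known limitations.
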