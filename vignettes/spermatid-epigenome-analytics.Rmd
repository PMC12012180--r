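---
title: "Models and methods: staged spermatogenesis epigenome analytics"
author: "spermEpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: staged spermatogenesis epigenome analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermEpi)
```

# The analytical problem

Male germ cell development traverses an ordered series of stages — mitotic
spermatogonia (Undiff, A1, B), meiotic spermatocytes (pL, L, Z, mP, D), round
spermatids (RS2, RS4, RS8), elongating spermatids (LS) and mature sperm —
each with its own chromatin configuration. Stage-resolved profiling of this
axis produces several data classes that need bespoke downstream computation
once the generic processing (alignment, peak calling, segmentation training,
differential-expression fitting) is done:

* ChIP-seq peak sets and coverage tracks for histone marks, from which
  unusually **broad H3K4me3/H3K27ac domains** are defined;
* NOMe-seq per-cytosine methylation calls, from which **chromatin
  accessibility** (GCH context) and **endogenous CpG methylation** (WCG
  context) are estimated and **nucleosome-depleted regions (NDRs)** are
  detected;
* ChromHMM-style **chromatin-state segmentations** per stage, compared
  between adjacent stages;
* FPKM matrices and differential-expression tables, from which
  **stage-specific expression timing** and its disruption in a knockout are
  quantified.

This package implements those downstream computations as tested, reusable
functions, and pairs them with a synthetic-data generator that emits every
input with ground truth, so the entire analysis is verifiable on a desk-scale
toy genome. All file formats are BED-family (0-based, half-open); internally
intervals are `GRanges`.

# Broad domain calling

Peaks are consolidated by transitive closure of a gap relation: two peaks
separated by at most `max_gap` bp (default **500 bp**, inclusive; touching
intervals always merge) become one merged domain. Merged domains strictly
wider than **5 kb** are *broad*; the rest are *regular*. A domain is
*promoter-proximal* when it overlaps a TSS ± **2 kb** window by at least one
base, otherwise *distal*. The gap is measured between half-open intervals
(`next.start − prev.end`), matching standard interval-merge tools.

Design notes:

* The threshold is strict (`width > 5000`), reading "exceeding 5 kb"
  literally: a 5000-bp domain is regular.
* Promoter assignment is by ≥ 1 bp overlap with the symmetric window; the
  window is strand-independent by construction. A center-containment variant
  is not provided — overlap is the weakest faithful reading of "positioned
  2 kb either side of the TSS".
* *Sharp* peaks are the top-*n* (default 500) regular merged domains by mean
  signal density over the domain (`mean0` averaging: uncovered bases count
  zero), with ties broken by coordinate so the selection is deterministic;
  the *control* set is an equal-sized uniform draw without replacement from
  the remainder under a caller-supplied seed. "Peak height" is read as mean
  density; callers who prefer summit height can supply any per-domain score.

## Super domains (ROSE-style)

Stitched regions (peaks merged within **12.5 kb**, the published default;
TSS exclusion off) are scored by total signal (mean density × width), sorted
ascending, and both ranks and signals are rescaled to the unit square. The
cutoff is the signal value at the point whose unit-slope tangent leaves the
fewest points below it — the standard geometric elbow criterion — and a
region is *super* when its total signal strictly exceeds the cutoff. The
criterion is invariant to multiplying all signals by a positive constant; a
flat curve (all signals equal) yields zero supers by the strict inequality.

## Spike-in normalization

The scaling convention is `factor_i = min_j(count_j) / count_i`: the sample
with the fewest spike-in reads is unchanged and every other sample is scaled
down. Any fixed reference count only rescales all samples jointly, so the
choice does not affect cross-sample contrasts; the reference is an argument
(`reference`) for sensitivity analyses.

# Bivalent promoter dynamics

A *bivalent domain* is an H3K4me3 peak with at least one overlapping
H3K27me3 peak (≥ 1 bp; the domain keeps the H3K4me3 span since H3K27me3
peaks are broader). A gene is *bivalent* at a stage when its TSS ± 2 kb
window overlaps a bivalent domain. A promoter overlapping a K4 peak and a
K27 peak that do **not** overlap each other is *not* promoted to bivalent —
bivalency requires peak-to-peak overlap — and is reported `K4_only` with a
`both_marks_nonoverlapping` flag so the case stays visible.

Trajectories are tracked over the gene universe bivalent in at least one
analyzed stage: per consecutive stage pair a 4 × 4 transition count matrix
(states bivalent / K4_only / K27_only / none) whose rows conserve the
universe, plus per-gene trajectory strings for alluvial-style export.
`persistence_fractions()` summarises destination-state proportions between
any two stages (e.g. bivalent-domain retention from elongating spermatids to
mature sperm).

# The NOMe-seq engine

## Contexts and levels

GpC methyltransferase treatment marks accessible DNA, so **GCH**
(GCA/GCC/GCT) methylation reads out accessibility while **WCG** (ACG/TCG)
methylation reads out endogenous CpG methylation; GCG is ambiguous and
excluded. Context classification is sequence-based, per strand, with
reverse-complement logic on the minus strand; edge cytosines are
unclassifiable. A site enters any computation only with read depth ≥ 3
(`min_depth`, configurable — the source material is internally inconsistent
between "3× coverage" and "depth greater than three", and the inclusive ≥ 3
reading is adopted); its level is `meth / (meth + unmeth)`. Region-level
means are unweighted over sites and require at least 3 qualifying sites.

## NDR detection

1. **Background**: pooled counts over all depth-qualified GCH sites
   genome-wide give the background accessibility rate. Candidate windows are
   not excluded from the background; they are a vanishing genome fraction.
2. **Window scan**: 100-bp windows every 20 bp, grid anchored at coordinate
   0 of each chromosome (so phase is deterministic). Each window pools the
   counts of the sites it contains and is a candidate when its rate exceeds
   the background and the Pearson χ² test (1 df, no continuity correction)
   on the 2 × 2 window-vs-background count table gives *P* ≤ 10⁻¹⁰.
   One-sidedness is enforced by the rate-direction gate, not by halving the
   p-value. The seed threshold equals the final region threshold.
3. **Region assembly**: overlapping or book-ended candidate windows merge;
   the merged region's counts are pooled and re-tested.
4. **Boundary refinement** (default on): a 100-bp window passes the χ² test
   once roughly half of it overlaps an accessible patch, so the union of
   significant windows systematically over-extends true regions by tens of
   bp. Each merged region is therefore narrowed to the maximum-likelihood
   contiguous run of its GCH sites under a two-rate binomial model — the
   contiguous run maximising the summed per-site log likelihood ratio
   between the region's pooled rate and the background rate (computed by a
   maximum-sum-subarray scan, iterated twice so the elevated-rate estimate
   comes from the refined core). Each boundary is then placed at the
   midpoint of the site-free gap between the outermost retained site and its
   nearest excluded neighbour — the changepoint is equally likely anywhere
   in that gap — and refinement never widens a region beyond its seed. The
   procedure is deterministic and parameter-free. On simulated data
   (background accessibility 0.1, in-NDR 0.6, depth 10, ~15-bp site
   spacing) it reduces the median boundary error from ~35 bp per side to
   about one site spacing.
5. **Criteria**: a region is an NDR only if *P* ≤ 10⁻¹⁰, it has strictly
   more than 5 qualified GCH sites, and is strictly longer than 140 bp (all
   evaluated on the refined region, which also must exceed the background
   rate).

NDRs within 1.5 kb of a TSS are *proximal*, otherwise *distal* (the TSS
reading is used throughout; the alternative TES phrasing in the source
material is treated as a slip). Cross-sample consolidation merges NDRs
within 10 bp.

## Matrices and profiles

* `bin_level_matrix()`: 1-kb genome bins, mean level per bin per sample with
  ≥ 3 sites, bins undefined in *any* sample dropped — the input to
  ordination (the decomposition itself is delegated to standard tooling).
* `gene_body_profile()`: gene bodies scaled to 100 bins plus 5-kb flanks in
  ten 500-bp bins each, strand-flipped so bin 1 is always 5′.
* `tss_accessibility_profile()`: TSS ± 2 kb in 200 × 20-bp bins, minus the
  per-sample genome-wide mean GCH site level (the "basic line"); disabling
  the subtraction adds exactly that constant.
* `hypomethylation_flags()`: a domain is hypomethylated when its mean WCG
  level is defined and < 0.3 (strict); domains with < 3 WCG sites are
  indeterminate and excluded from denominators.

# Chromatin-state dynamics

Segmentations (BED4, states `E1..E15`) are validated on read: per-chromosome
non-overlap, states in range; gaps are unassigned and excluded from every
denominator. `variable_bases()` is **directional** (earlier stage → later
stage): for state *s*, the fraction of bases labeled *s* at the earlier
stage whose later label differs, over commonly assigned bases; the symmetric
union denominator is not offered. Conservation holds by construction: summed
per-state changed bases equal total changed bases. `state_score_matrix()`
maps state *k* to score *16 − k* (state 1, active promoter, scores 15; state
15, no signal, scores 1) and averages scores per 5-kb bin weighted by
assigned length. Optional pre-filters support an exclusion BED (e.g.
recombination hotspots and pseudo-autosomal regions) and a chromosome
whitelist (e.g. autosomes only); no exclusion catalogue is bundled.

# Expression timing

* Expressed ⇔ FPKM ≥ 0.5 (strictly smaller is repressed).
* Differential classes use inclusive bounds: up ⇔ log₂FC ≥ 0.5 ∧ adjusted
  *p* ≤ 0.05; down mirrors it. DE tables are inputs, never fitted here.
* The stage-specificity filter (peak FPKM ≥ 1.0 and ≥ 2 × the median of the
  other stages) is a package decision — the underlying criterion is not
  printed in the source material — with both constants exposed.
* Peak timing over RS2/RS4/RS8/LS: argmax stage with ties to the earliest
  stage; *early* = peak in RS2/RS4, *late* = RS8/LS; all-zero genes are
  unclassified.
* `timing_shift_summary()` counts the knockout signatures ("early genes up
  at late stages", "late genes up at early stages", and their
  down-at-own-peak mirrors); a gene counts once per signature if it
  qualifies at any stage of the group.
* Distal domains are assigned to the nearest TSS within 100 kb of the domain
  centre (`floor((start+end)/2)`), ties to the lexicographically smaller
  gene id.
* Enhancers are distal H3K27ac peaks (no TSS ± 2 kb overlap), classed
  `Broad_SEplus` / `Broad_SEminus` / `typical` by whether they overlap a
  broad H3K4me3 domain that does / does not itself overlap a super-enhancer;
  eRNA levels are compared with two-sided Wilcoxon rank-sum tests.

# The synthetic-data generator

`sim_config()` fixes the demo conditions: two 2-Mb chromosomes, 200 genes on
an even grid, 40 planted broad domains (5.1–20 kb) over 400 regular peaks
(0.5–2 kb) all separated by > 500 bp, 50 planted 300-bp NDRs, five stages
(A1, B, Z, mP, RS4), GC content 0.4 (one GCH site per ~15 bp across both
strands), background accessibility 0.1 vs 0.6 inside NDRs at mean depth 10
(Poisson), WCG methylation 0.75, 15-state segmentations on 200-bp bins with
per-state change rates 0.02–0.16, and an expression model with peak FPKM 10
against off-peak 1 where the knockout halves peak-stage expression
(dampening 0.5) and doubles off-peak expression (leak 2.0) of the 60 timed
broad-domain genes. Expression is noise-free by default so planted timing
labels and signature counts are exact; noise robustness is a property of the
classifiers' thresholds, not exercised here.

What the generator emulates: peak landscapes whose merge/classification
round-trips exactly; site-level binomial NOMe counts with spacing that
emerges from sequence composition (so window-phase edge cases occur
naturally); Markov bin relabeling between stages with realized change counts
recorded; planted H3K27me3 erasure from stage B through Z with restoration
from mid-pachytene. What it does **not** emulate: read-level bisulfite
conversion errors, fragment-level ChIP coverage autocorrelation, mapping
artefacts, copy-number structure, replicate variability, or DE p-value
calibration (p-values are planted, since DE fitting is out of scope).
Passing tests therefore demonstrate the correctness of the downstream
computations under their stated models, not robustness to upstream
artefacts in real sequencing data.

Simulation sizes used by the test-suite: the 4-Mb demo genome for
round-trips and the end-to-end pipeline, and a single 10-Mb chromosome with
50 planted NDRs for detector calibration, where the caller recovers ≥ 90%
of planted regions at Jaccard ≥ 0.8 with no false regions and stays silent
on matched null genomes.

# Numerical and degenerate-case choices

* χ² is Pearson without Yates correction; degenerate tables (a zero margin)
  give *p* = 1 and never seed a region.
* The elbow cutoff handles flat curves (zero supers) and requires ≥ 2
  stitched regions.
* All deterministic tie-breaks are documented at the call site: coordinate
  order for sharp peaks, earliest stage for timing, smaller gene id for
  assignment.
* Random draws (control-set selection, every simulator) run in private RNG
  streams derived from caller-supplied seeds and restore the caller's RNG
  state.
* Zero-gene origins in `persistence_fractions()` report `NA` with `n = 0`
  rather than dividing by zero; genes without a TSS are skipped with a
  warning upstream.

# Orchestration

`run_subcommand()` drives the stages (`simulate`, `domains`, `ndr`,
`bivalency`, `states`, `timing`, `all`) from one `run_config()` (or YAML)
holding every threshold named above. Each run writes its outputs plus a
manifest JSON recording package version, parameters, input digests and
summary counts; reruns with identical inputs are byte-identical. A thin
command-line wrapper is installed at `inst/scripts/spermepi.R`.

# Known limitations

* NDR boundary precision is limited by site spacing: where a region edge
  falls in a site-free gap the changepoint is unidentifiable within the gap,
  and the midpoint estimate carries that irreducible uncertainty.
* The NDR background is a single genome-wide rate; locally varying enzyme
  efficiency or coverage would require a stratified background.
* Bivalency uses symmetric promoter windows; asymmetric or
  annotation-specific promoter definitions must be prepared upstream.
* The stage-specificity filter is a stand-in with documented defaults, not a
  published criterion.
* Segmentation analytics assume a shared bin structure is not required but
  do assume per-stage segmentations refer to the same assembly.
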