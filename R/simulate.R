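#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with the defaults that
#' define the packaged demo conditions: a 2 x 2 Mb toy genome, 200 genes, 40
#' planted broad domains over 400 regular peaks, 50 planted 300-bp
#' nucleosome-depleted regions over a 0.1 accessibility background (0.6
#' inside NDRs, mean depth 10), Markov-perturbed 15-state segmentations on
#' 200-bp bins, and stage-peaked expression with a knockout that halves
#' peak-stage expression (dampening 0.5) and doubles off-peak expression
#' (leak 2.0) of broad-domain genes.
#'
#' @param seed Integer master seed; every generator draws from a stream
#'   derived from it.
#' @param chrom_sizes Named vector of chromosome sizes.
#' @param stages Stage subset simulated for peaks/segmentations (canonical
#'   order enforced).
#' @param n_genes Number of annotated genes.
#' @param n_broad,broad_width_range Planted broad domains (widths strictly
#'   above 5 kb).
#' @param n_regular,regular_width_range Planted regular peaks.
#' @param broad_stages Stages carrying the planted broad domains (default:
#'   the simulated stages from diplotene onward).
#' @param gc_content Genome GC fraction (default 0.4, giving a GCH site
#'   roughly every 15 bp across both strands).
#' @param n_ndr,ndr_width Planted accessible regions.
#' @param p0,p1 Background and in-NDR GCH accessibility.
#' @param depth_mean Mean per-site read depth (Poisson).
#' @param wcg_level Endogenous CpG methylation level.
#' @param n_states,seg_bin Segmentation model size and bin width.
#' @param state_freq Initial state frequencies (length `n_states`).
#' @param change_rates Per-state per-stage-pair relabeling probabilities.
#' @param n_timed,peak_fpkm,off_fpkm,base_fpkm Expression model sizes/levels.
#' @param ko_dampening,ko_leak Knockout effect multipliers (< 1 and > 1).
#' @param n_bivalent,n_biv_affected Bivalency simulation: genes bivalent
#'   somewhere, and the subset whose H3K27me3 is erased from stage B through
#'   Z and restored from mid-pachytene on.
#' @param spike_counts Named per-stage spike-in read counts.
#' @return List of class `spermepi_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                       stages = c("A1", "B", "Z", "mP", "RS4"),
                       n_genes = 200L,
                       n_broad = 40L, broad_width_range = c(5100, 20000),
                       n_regular = 400L, regular_width_range = c(500, 2000),
                       broad_stages = NULL,
                       gc_content = 0.4,
                       n_ndr = 50L, ndr_width = 300L,
                       p0 = 0.1, p1 = 0.6, depth_mean = 10,
                       wcg_level = 0.75,
                       n_states = 15L, seg_bin = 200L,
                       state_freq = c(rep(0.04, 14), 0.44),
                       change_rates = seq(0.02, 0.16, length.out = 15),
                       n_timed = 60L, peak_fpkm = 10, off_fpkm = 1,
                       base_fpkm = 2,
                       ko_dampening = 0.5, ko_leak = 2.0,
                       n_bivalent = 30L, n_biv_affected = 15L,
                       spike_counts = NULL) {
  stages <- order_stages(stages)
  if (is.null(broad_stages)) {
    late <- spermatogenic_stages()[match("D", spermatogenic_stages()):13]
    broad_stages <- intersect(stages, late)
    if (length(broad_stages) == 0L) broad_stages <- stages[length(stages)]
  }
  if (is.null(spike_counts)) {
    spike_counts <- setNames(1e6 + 2e5 * seq_along(stages), stages)
  }
  stopifnot(p1 >= p0, p0 > 0, p0 < 1, p1 < 1, depth_mean > 0,
            all(change_rates >= 0 & change_rates <= 1),
            length(state_freq) == n_states,
            length(change_rates) == n_states)
  cfg <- list(seed = seed, chrom_sizes = chrom_sizes, stages = stages,
              n_genes = n_genes, n_broad = n_broad,
              broad_width_range = broad_width_range, n_regular = n_regular,
              regular_width_range = regular_width_range,
              broad_stages = broad_stages, gc_content = gc_content,
              n_ndr = n_ndr, ndr_width = ndr_width, p0 = p0, p1 = p1,
              depth_mean = depth_mean, wcg_level = wcg_level,
              n_states = n_states, seg_bin = seg_bin,
              state_freq = state_freq, change_rates = change_rates,
              n_timed = n_timed, peak_fpkm = peak_fpkm, off_fpkm = off_fpkm,
              base_fpkm = base_fpkm, ko_dampening = ko_dampening,
              ko_leak = ko_leak, n_bivalent = n_bivalent,
              n_biv_affected = n_biv_affected, spike_counts = spike_counts)
  class(cfg) <- "spermepi_sim_config"
  cfg
}

#' Simulate a random genome sequence
#'
#' Independent bases at the configured GC content, deterministic under the
#' seed. At GC 0.4 the expected GCH density (`P(G)P(C)P(H)` per strand,
#' summed over strands) is about one site per 15-16 bp.
#'
#' @param config [sim_config()].
#' @return List with `genome` (named character vector of sequences) and
#'   `assembly` ([genome_assembly()]).
#' @export
simulate_genome <- function(config) {
  with_private_seed(config$seed + 101L, {
    g <- config$gc_content
    probs <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    genome <- vapply(names(config$chrom_sizes), function(ch) {
      paste(sample(names(probs), config$chrom_sizes[[ch]], replace = TRUE,
                   prob = probs), collapse = "")
    }, "")
    list(genome = genome, assembly = genome_assembly(config$chrom_sizes))
  })
}

#' Simulate a gene annotation table
#'
#' Genes are laid out on an even grid per chromosome with alternating
#' strands and lengths drawn between 2 and 8 kb; TSS positions are 0-based.
#'
#' @param config [sim_config()].
#' @return TSS table (`gene_id`, `chrom`, `strand`, `tss`, `tes`).
#' @export
simulate_genes <- function(config) {
  with_private_seed(config$seed + 202L, {
    sizes <- config$chrom_sizes
    per_chrom <- table(rep(names(sizes), length.out = config$n_genes))
    rows <- lapply(names(sizes), function(ch) {
      n <- per_chrom[[ch]]
      if (is.na(n) || n == 0L) return(NULL)
      spacing <- floor(sizes[[ch]] / (n + 1L))
      tss <- spacing * seq_len(n)
      len <- sample(2000:8000, n, replace = TRUE)
      strand <- rep(c("+", "-"), length.out = n)
      tes <- ifelse(strand == "+", pmin(tss + len, sizes[[ch]] - 1),
                    pmax(tss - len, 0))
      data.frame(chrom = ch, strand = strand, tss = tss, tes = tes,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$gene_id <- sprintf("gene_%03d", seq_len(nrow(out)))
    out[, c("gene_id", "chrom", "strand", "tss", "tes")]
  })
}

# lay widths down along chromosomes with gaps > min_gap, returns 0-based
# intervals; errors if the packing does not fit
pack_intervals <- function(widths, chrom_sizes, min_gap = 600, max_gap = 1500) {
  chroms <- names(chrom_sizes)
  order_ix <- sample(seq_along(widths))
  per <- split(order_ix, rep_len(seq_along(chroms), length(widths)))
  rows <- lapply(seq_along(chroms), function(ci) {
    ix <- per[[ci]]
    if (is.null(ix) || length(ix) == 0L) return(NULL)
    cursor <- 1000
    out <- matrix(0, nrow = length(ix), ncol = 2L)
    for (j in seq_along(ix)) {
      gap <- sample(min_gap:max_gap, 1L)
      start <- cursor + gap
      end <- start + widths[ix[j]]
      out[j, ] <- c(start, end)
      cursor <- end
    }
    if (cursor > chrom_sizes[[ci]] - 1000) {
      stop("infeasible packing: planted regions exceed chromosome ",
           chroms[ci])
    }
    data.frame(chrom = chroms[ci], start = out[, 1L], end = out[, 2L],
               idx = ix, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$idx), c("chrom", "start", "end")]
}

#' Plant a stage-structured peak landscape
#'
#' Broad domains (width > 5 kb) are present only in `broad_stages`; regular
#' peaks are present at every simulated stage. All planted regions are
#' separated by more than 500 bp, so gap-consolidation can never join two
#' planted regions. About half of the broad domains are emitted split into
#' 2-3 sub-peaks with internal gaps of at most 500 bp, so the merge step is
#' exercised; the merged span always equals the planted span. Broad signals
#' are drawn above all regular signals.
#'
#' @param config [sim_config()].
#' @param genes Gene table from [simulate_genes()] (used only to record the
#'   planted promoter/distal geometry in the truth).
#' @return List: `peaks` (stage -> `GRanges` of emitted peaks), `tracks`
#'   (stage -> signal-track `GRanges`), `spike_counts`, and `truth` (list
#'   with `broad` / `regular` planted `GRanges`, the broad domains carrying
#'   `location_class` derived arithmetically from the TSS grid, and
#'   `broad_stages`).
#' @export
simulate_peaks <- function(config, genes) {
  with_private_seed(config$seed + 303L, {
    nb <- config$n_broad; nr <- config$n_regular
    widths <- c(round(runif(nb, config$broad_width_range[1L],
                            config$broad_width_range[2L])),
                round(runif(nr, config$regular_width_range[1L],
                            config$regular_width_range[2L])))
    placed <- pack_intervals(widths, config$chrom_sizes)
    is_broad <- c(rep(TRUE, nb), rep(FALSE, nr))
    broad <- placed[is_broad, ]
    regular <- placed[!is_broad, ]
    broad_sig <- runif(nb, 20, 40)
    regular_sig <- runif(nr, 1, 10)

    # promoter/distal truth from plain arithmetic on the TSS grid
    loc <- vapply(seq_len(nb), function(i) {
      g <- genes[genes$chrom == broad$chrom[i], ]
      any(g$tss - 2000 < broad$end[i] & broad$start[i] < g$tss + 2000)
    }, TRUE)

    emit_stage <- function(with_broad) {
      rows <- list()
      if (with_broad) {
        for (i in seq_len(nb)) {
          s <- broad$start[i]; e <- broad$end[i]
          n_sub <- sample(1:3, 1L)
          if (n_sub == 1L) {
            rows[[length(rows) + 1L]] <-
              data.frame(chrom = broad$chrom[i], start = s, end = e,
                         signal = broad_sig[i])
          } else {
            # cut the span into n_sub pieces separated by gaps <= 500
            gaps <- sample(100:500, n_sub - 1L, replace = TRUE)
            inner <- (e - s) - sum(gaps)
            cuts <- sort(sample(seq_len(inner - n_sub), n_sub - 1L))
            lens <- diff(c(0L, cuts, inner))
            st <- s
            for (k in seq_len(n_sub)) {
              rows[[length(rows) + 1L]] <-
                data.frame(chrom = broad$chrom[i], start = st,
                           end = st + lens[k], signal = broad_sig[i])
              st <- st + lens[k] + if (k < n_sub) gaps[k] else 0L
            }
          }
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = regular$chrom, start = regular$start,
                   end = regular$end, signal = regular_sig)
      df <- do.call(rbind, rows)
      gr <- granges_from_bed0(df$chrom, df$start, df$end,
                              signal = df$signal,
                              source_id = sprintf("p%04d", seq_len(nrow(df))))
      GenomicRanges::sort(gr, ignore.strand = TRUE)
    }

    peaks <- lapply(setNames(config$stages, config$stages), function(st) {
      emit_stage(st %in% config$broad_stages)
    })
    tracks <- lapply(peaks, function(p) {
      tr <- GenomicRanges::granges(p)
      tr$score <- p$signal
      tr
    })
    truth_broad <- granges_from_bed0(broad$chrom, broad$start, broad$end,
                                     signal = broad_sig,
                                     location_class = ifelse(loc, "promoter",
                                                             "distal"))
    truth_regular <- granges_from_bed0(regular$chrom, regular$start,
                                       regular$end, signal = regular_sig)
    list(peaks = peaks, tracks = tracks, spike_counts = config$spike_counts,
         truth = list(broad = GenomicRanges::sort(truth_broad),
                      regular = GenomicRanges::sort(truth_regular),
                      broad_stages = config$broad_stages))
  })
}

#' Simulate NOMe-seq cytosine calls with planted accessible regions
#'
#' Every WCG/GCH cytosine of the genome receives a Poisson read depth and a
#' binomial methylated-read count: GCH sites at accessibility `p1` inside
#' planted NDRs and `p0` elsewhere; WCG sites at the endogenous methylation
#' level. Site spacing emerges from sequence composition, so window-phase
#' edge cases are exercised naturally.
#'
#' @param config [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return List: `calls` (cytosine call data.table restricted to WCG/GCH
#'   sites) and `truth` (planted NDR `GRanges`).
#' @export
simulate_nome <- function(config, genome) {
  with_private_seed(config$seed + 404L, {
    sites <- classify_cytosines(genome$genome)
    sites <- sites[sites$context != "other"]
    # plant NDRs on a coarse grid, separated by at least 1 kb
    sizes <- config$chrom_sizes
    n_ndr <- config$n_ndr
    per_chrom <- table(rep(names(sizes), length.out = n_ndr))
    ndr_rows <- lapply(names(sizes), function(ch) {
      n <- per_chrom[[ch]]
      if (is.na(n) || n == 0L) return(NULL)
      slot <- floor((sizes[[ch]] - 2000) / n)
      if (slot < config$ndr_width + 1000) {
        stop("infeasible NDR packing on ", ch)
      }
      offs <- sample.int(slot - config$ndr_width - 1000, n, replace = TRUE)
      start <- 1000 + (seq_len(n) - 1L) * slot + offs
      data.frame(chrom = ch, start = start, end = start + config$ndr_width,
                 stringsAsFactors = FALSE)
    })
    ndr <- do.call(rbind, ndr_rows)
    truth <- GenomicRanges::sort(
      granges_from_bed0(ndr$chrom, ndr$start, ndr$end))

    depth <- stats::rpois(nrow(sites), config$depth_mean)
    in_ndr <- rep(FALSE, nrow(sites))
    for (i in seq_len(nrow(ndr))) {
      in_ndr <- in_ndr | (sites$chrom == ndr$chrom[i] &
                            sites$pos >= ndr$start[i] &
                            sites$pos < ndr$end[i])
    }
    p <- ifelse(sites$context == "GCH",
                ifelse(in_ndr, config$p1, config$p0),
                config$wcg_level)
    meth <- stats::rbinom(nrow(sites), depth, p)
    calls <- data.table::data.table(
      chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
      context = sites$context, meth = meth, unmeth = depth - meth)
    data.table::setkey(calls, chrom, pos)
    list(calls = calls[], truth = truth)
  })
}

#' Simulate Markov-perturbed chromatin-state segmentations
#'
#' Stage 1 assigns each `seg_bin`-bp bin a state from `state_freq`; every
#' later stage relabels each bin with its current state's change rate, the
#' new state drawn uniformly from the other states. The truth records, per
#' stage pair and per state, the realized number of changed bases and the
#' number of bases at risk.
#'
#' @param config [sim_config()].
#' @return List: `segs` (stage -> `GRanges` with `state`, adjacent
#'   equal-state bins run-length merged) and `truth` (data.frame `pair`,
#'   `state`, `at_risk_bp`, `changed_bp`, `rate`).
#' @export
simulate_segmentations <- function(config) {
  with_private_seed(config$seed + 505L, {
    sizes <- config$chrom_sizes
    n_states <- config$n_states
    bins <- lapply(names(sizes), function(ch) {
      n_bin <- floor(sizes[[ch]] / config$seg_bin)
      data.frame(chrom = ch,
                 start = (seq_len(n_bin) - 1L) * config$seg_bin,
                 end = seq_len(n_bin) * config$seg_bin,
                 stringsAsFactors = FALSE)
    })
    bins <- do.call(rbind, bins)
    n <- nrow(bins)
    stages <- config$stages
    states <- matrix(0L, nrow = n, ncol = length(stages),
                     dimnames = list(NULL, stages))
    states[, 1L] <- sample.int(n_states, n, replace = TRUE,
                               prob = config$state_freq)
    truth <- list()
    for (j in seq_along(stages)[-1L]) {
      cur <- states[, j - 1L]
      flip <- stats::runif(n) < config$change_rates[cur]
      nxt <- cur
      if (any(flip)) {
        # uniform over the other states
        shift <- sample.int(n_states - 1L, sum(flip), replace = TRUE)
        nxt[flip] <- ((cur[flip] - 1L + shift) %% n_states) + 1L
      }
      states[, j] <- nxt
      pair <- paste0(stages[j - 1L], "->", stages[j])
      for (s in seq_len(n_states)) {
        at_risk <- sum(cur == s)
        changed <- sum(cur == s & flip)
        truth[[length(truth) + 1L]] <- data.frame(
          pair = pair, state = s,
          at_risk_bp = at_risk * config$seg_bin,
          changed_bp = changed * config$seg_bin,
          rate = config$change_rates[s], stringsAsFactors = FALSE)
      }
    }
    segs <- lapply(setNames(seq_along(stages), stages), function(j) {
      # run-length merge of equal-state neighbouring bins
      rl <- S4Vectors::Rle(paste(bins$chrom, states[, j]))
      starts <- cumsum(c(1L, S4Vectors::runLength(rl)))
      i0 <- starts[-length(starts)]
      i1 <- i0 + S4Vectors::runLength(rl) - 1L
      granges_from_bed0(bins$chrom[i0], bins$start[i0], bins$end[i1],
                        state = states[i0, j])
    })
    list(segs = segs, truth = do.call(rbind, truth))
  })
}

#' Simulate control and knockout expression with planted timing
#'
#' Timed (broad-domain) genes peak at an assigned spermatid stage in the
#' control; the knockout multiplies their peak-stage FPKM by `ko_dampening`
#' and their off-peak FPKM by `ko_leak`. Differential-expression tables are
#' planted from the realized fold-changes (adjusted p below threshold for
#' affected genes, uniform on [0.2, 1] elsewhere), since DE fitting is out
#' of scope.
#'
#' @param config [sim_config()].
#' @param gene_ids Optional gene identifiers to draw from (defaults to the
#'   simulated gene table's ids).
#' @return List: `control`, `ko` (FPKM matrices over RS2/RS4/RS8/LS),
#'   `de_by_stage` (stage -> DE data.frame), `truth` (data.frame `gene_id`,
#'   `timed`, `label`, `peak_stage` plus attribute-free planted signature
#'   counts in `expected_counts`).
#' @export
simulate_expression <- function(config, gene_ids = NULL) {
  with_private_seed(config$seed + 606L, {
    stages <- c("RS2", "RS4", "RS8", "LS")
    if (is.null(gene_ids)) {
      gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
    }
    n <- length(gene_ids)
    nt <- min(config$n_timed, n)
    peak_stage <- rep(NA_character_, n)
    peak_stage[seq_len(nt)] <- rep(stages, length.out = nt)
    control <- matrix(config$base_fpkm, nrow = n, ncol = 4L,
                      dimnames = list(gene_ids, stages))
    ko <- control
    for (i in seq_len(nt)) {
      prof <- rep(config$off_fpkm, 4L)
      prof[match(peak_stage[i], stages)] <- config$peak_fpkm
      control[i, ] <- prof
      ko_prof <- prof * config$ko_leak
      ko_prof[match(peak_stage[i], stages)] <-
        config$peak_fpkm * config$ko_dampening
      ko[i, ] <- ko_prof
    }
    de_by_stage <- lapply(setNames(stages, stages), function(st) {
      lfc <- log2(ko[, st] / control[, st])
      affected <- abs(lfc) > 0
      p <- stats::runif(n, 0.2, 1)
      p[affected] <- stats::runif(sum(affected), 1e-6, 1e-4)
      data.frame(gene_id = gene_ids, log2_fc = lfc, p_adj = p,
                 stringsAsFactors = FALSE)
    })
    label <- ifelse(is.na(peak_stage), "untimed",
             ifelse(peak_stage %in% c("RS2", "RS4"), "early", "late"))
    truth <- data.frame(gene_id = gene_ids, timed = !is.na(peak_stage),
                        label = label, peak_stage = peak_stage,
                        stringsAsFactors = FALSE)
    n_early <- sum(label == "early"); n_late <- sum(label == "late")
    list(control = control, ko = ko, de_by_stage = de_by_stage,
         truth = truth,
         expected_counts = c(early_down_early = n_early,
                             early_up_late = n_early,
                             late_down_late = n_late,
                             late_up_early = n_late))
  })
}

#' Simulate per-stage H3K4me3/H3K27me3 peak sets with a bivalency scenario
#'
#' Bivalent genes carry an H3K4me3 promoter peak at every stage and an
#' overlapping H3K27me3 peak whose presence follows the planted scenario:
#' affected genes lose H3K27me3 from stage B through Z (promoters become
#' K4-only) and regain it from mid-pachytene onward; unaffected bivalent
#' genes keep both marks throughout.
#'
#' @param config [sim_config()].
#' @param genes Gene table.
#' @return List: `stage_peaks` (stage -> list(k4, k27)) and `truth`
#'   (`bivalent_genes`, `affected_genes`).
#' @export
simulate_bivalency <- function(config, genes) {
  with_private_seed(config$seed + 707L, {
    nb <- min(config$n_bivalent, nrow(genes))
    na_ <- min(config$n_biv_affected, nb)
    biv <- genes[seq_len(nb), ]
    affected <- biv$gene_id[seq_len(na_)]
    all_stages <- spermatogenic_stages()
    erased <- function(stage) {
      i <- match(stage, all_stages)
      i >= match("B", all_stages) && i < match("mP", all_stages)
    }
    stage_peaks <- lapply(setNames(config$stages, config$stages), function(st) {
      k4 <- granges_from_bed0(biv$chrom, pmax(0, biv$tss - 500),
                              biv$tss + 500,
                              source_id = paste0("k4_", biv$gene_id))
      keep_k27 <- if (erased(st)) !(biv$gene_id %in% affected)
                  else rep(TRUE, nrow(biv))
      k27 <- granges_from_bed0(biv$chrom[keep_k27],
                               pmax(0, biv$tss[keep_k27] - 1500),
                               biv$tss[keep_k27] + 1500,
                               source_id = paste0("k27_", biv$gene_id[keep_k27]))
      list(k4 = GenomicRanges::sort(k4, ignore.strand = TRUE),
           k27 = GenomicRanges::sort(k27, ignore.strand = TRUE))
    })
    list(stage_peaks = stage_peaks,
         truth = list(bivalent_genes = biv$gene_id,
                      affected_genes = affected))
  })
}

#' Simulate the complete demo dataset
#'
#' Runs every generator under one configuration and, when `out_dir` is
#' given, writes the full directory tree of plain-text inputs (FASTA,
#' chrom.sizes, narrowPeak, bedGraph, cytosine calls, segmentation BEDs,
#' FPKM/DE tables, TSS table, spike counts) plus a machine-readable
#' ground-truth JSON.
#'
#' @param config [sim_config()].
#' @param out_dir Optional output directory.
#' @return List with all generator outputs (`genome`, `genes`, `peaks`,
#'   `nome`, `segs`, `expr`, `biv`) and, when written, `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  genome <- simulate_genome(config)
  genes <- simulate_genes(config)
  peaks <- simulate_peaks(config, genes)
  nome <- simulate_nome(config, genome)
  segs <- simulate_segmentations(config)
  expr <- simulate_expression(config, gene_ids = genes$gene_id)
  biv <- simulate_bivalency(config, genes)
  sim <- list(config = config, genome = genome, genes = genes, peaks = peaks,
              nome = nome, segs = segs, expr = expr, biv = biv)
  if (!is.null(out_dir)) {
    sim$paths <- write_simulation(sim, out_dir)
  }
  sim
}

gr_to_bed_list <- function(gr) {
  bed <- bed0_from_granges(gr)
  extra <- as.data.frame(S4Vectors::mcols(gr))
  cbind(bed, extra)
}

write_fpkm <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write narrowPeak records
#' @param gr Peak `GRanges` with `signal` and `source_id`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_narrowpeak <- function(gr, path) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  bed <- bed0_from_granges(gr)
  df <- data.frame(bed$chrom, bed$start, bed$end,
                   name = if (!is.null(gr$source_id)) gr$source_id else ".",
                   score = 0L, strand = ".",
                   signalValue = if (!is.null(gr$signal)) gr$signal else 0,
                   pValue = -1, qValue = -1, peak = -1)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  # genome
  p$genome_fasta <- file.path(out_dir, "genome.fa")
  writeLines(unlist(lapply(names(sim$genome$genome), function(ch) {
    c(paste0(">", ch), sim$genome$genome[[ch]])
  })), p$genome_fasta)
  p$chrom_sizes <- file.path(out_dir, "chrom.sizes")
  utils::write.table(
    data.frame(names(sim$config$chrom_sizes),
               as.integer(sim$config$chrom_sizes)),
    p$chrom_sizes, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  p$tss <- file.path(out_dir, "genes.tsv")
  write_tss(sim$genes, p$tss)
  # peaks + tracks + spike counts
  for (st in sim$config$stages) {
    p[[paste0("peaks_", st)]] <- file.path(out_dir,
                                           paste0("k4me3_", st, ".narrowPeak"))
    write_narrowpeak(sim$peaks$peaks[[st]], p[[paste0("peaks_", st)]])
    p[[paste0("track_", st)]] <- file.path(out_dir,
                                           paste0("k4me3_", st, ".bedGraph"))
    write_bedgraph(sim$peaks$tracks[[st]], p[[paste0("track_", st)]])
    p[[paste0("seg_", st)]] <- file.path(out_dir,
                                         paste0("segments_", st, ".bed"))
    write_segmentation(sim$segs$segs[[st]], p[[paste0("seg_", st)]])
    p[[paste0("biv_k4_", st)]] <- file.path(out_dir,
                                            paste0("biv_k4me3_", st, ".bed"))
    write_bed(sim$biv$stage_peaks[[st]]$k4, p[[paste0("biv_k4_", st)]])
    p[[paste0("biv_k27_", st)]] <- file.path(out_dir,
                                             paste0("biv_k27me3_", st, ".bed"))
    write_bed(sim$biv$stage_peaks[[st]]$k27, p[[paste0("biv_k27_", st)]])
  }
  p$spike <- file.path(out_dir, "spike_counts.tsv")
  utils::write.table(
    data.frame(stage = names(sim$peaks$spike_counts),
               count = as.numeric(sim$peaks$spike_counts)),
    p$spike, sep = "\t", quote = FALSE, row.names = FALSE)
  # NOMe
  p$cytosine_calls <- file.path(out_dir, "cytosine_calls.tsv")
  write_cytosine_calls(sim$nome$calls, p$cytosine_calls)
  # expression
  p$fpkm_control <- file.path(out_dir, "fpkm_control.tsv")
  write_fpkm(sim$expr$control, p$fpkm_control)
  p$fpkm_ko <- file.path(out_dir, "fpkm_ko.tsv")
  write_fpkm(sim$expr$ko, p$fpkm_ko)
  for (st in names(sim$expr$de_by_stage)) {
    p[[paste0("de_", st)]] <- file.path(out_dir, paste0("de_", st, ".tsv"))
    utils::write.table(sim$expr$de_by_stage[[st]], p[[paste0("de_", st)]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # ground truth
  p$truth <- file.path(out_dir, "ground_truth.json")
  truth <- list(
    broad = gr_to_bed_list(sim$peaks$truth$broad),
    regular = gr_to_bed_list(sim$peaks$truth$regular),
    broad_stages = sim$peaks$truth$broad_stages,
    ndrs = gr_to_bed_list(sim$nome$truth),
    segmentation = sim$segs$truth,
    expression = sim$expr$truth,
    expected_timing_counts = as.list(sim$expr$expected_counts),
    bivalency = sim$biv$truth
  )
  jsonlite::write_json(truth, p$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  p
}
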