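#' Default pipeline run configuration
#'
#' All thresholds named across the analysis live in one schema, so a
#' sensitivity analysis is a one-field change. Defaults are the values used
#' throughout the package documentation.
#'
#' @param seed Integer seed.
#' @param sim_dir Directory of simulated (or real, same formats) inputs.
#' @param out_dir Output directory.
#' @param stages Stage subset present in `sim_dir`.
#' @param domain_stage Stage analysed for broad/super domains (defaults to
#'   the last configured stage).
#' @param params Named list of parameter overrides (see the field defaults
#'   in the implementation; every threshold of the analysis is available).
#' @return List of class `spermepi_run_config`.
#' @export
run_config <- function(seed = 1L, sim_dir = "sim", out_dir = "out",
                       stages = c("A1", "B", "Z", "mP", "RS4"),
                       domain_stage = NULL, params = list()) {
  defaults <- list(
    merge_gap = 500, broad_min = 5000, promoter_flank = 2000,
    sharp_n = 500, stitch = 12500,
    min_depth = 3, ndr_window = 100, ndr_step = 20, ndr_p_max = 1e-10,
    ndr_min_sites = 5, ndr_min_width = 140, ndr_flank = 1500,
    ndr_merge_gap = 10, level_bin = 1000, min_sites = 3,
    n_states = 15, score_bin = 5000,
    fpkm_threshold = 0.5, lfc_min = 0.5, p_adj_max = 0.05,
    min_peak_fpkm = 1.0, specificity_ratio = 2.0, assign_max_dist = 100000
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(params)] <- params
  cfg <- list(seed = as.integer(seed), sim_dir = sim_dir, out_dir = out_dir,
              stages = order_stages(stages), domain_stage = domain_stage,
              params = defaults)
  if (is.null(cfg$domain_stage)) {
    cfg$domain_stage <- cfg$stages[length(cfg$stages)]
  }
  class(cfg) <- "spermepi_run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of the fields of [run_config()].
#' @return `spermepi_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  c("seed", "sim_dir", "out_dir", "stages",
                                    "domain_stage", "params"))])
}

sim_input <- function(cfg, name) {
  path <- file.path(cfg$sim_dir, name)
  if (!file.exists(path)) stop("missing input file: ", path)
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_domains <- function(cfg, stage) {
  assembly <- read_chrom_sizes(sim_input(cfg, "chrom.sizes"))
  tss <- read_tss(sim_input(cfg, "genes.tsv"))
  peaks <- read_peaks(sim_input(cfg, paste0("k4me3_", stage, ".narrowPeak")),
                      assembly = assembly)
  track <- read_bedgraph(sim_input(cfg, paste0("k4me3_", stage, ".bedGraph")),
                         assembly = assembly)
  p <- cfg$params
  domains <- merge_peaks(peaks, max_gap = p$merge_gap)
  domains <- classify_broad(domains, broad_min = p$broad_min)
  domains <- split_promoter_distal(domains, tss, flank = p$promoter_flank,
                                   assembly = assembly)
  list(assembly = assembly, tss = tss, peaks = peaks, track = track,
       domains = domains)
}

run_domains <- function(cfg) {
  st <- cfg$domain_stage
  x <- stage_domains(cfg, st)
  p <- cfg$params
  broad <- x$domains[x$domains$width_class == "broad"]
  regular <- x$domains[x$domains$width_class == "regular"]
  sc <- select_sharp_control(regular, track = x$track,
                             n = min(p$sharp_n, max(1L, length(regular) %/% 2L)),
                             seed = cfg$seed)
  supers <- super_domains(x$peaks, track = x$track, stitch = p$stitch)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(x$domains, file.path(cfg$out_dir, paste0("domains_", st, ".bed")),
            extra_cols = c("width_class", "location_class", "mean_signal"))
  write_bed(supers, file.path(cfg$out_dir, paste0("supers_", st, ".bed")),
            extra_cols = c("total_signal", "rank", "is_super"))
  jsonlite::write_json(
    list(cutoff = S4Vectors::metadata(supers)$cutoff),
    file.path(cfg$out_dir, paste0("supers_", st, ".json")),
    auto_unbox = TRUE, digits = NA)
  list(counts = list(
    domains = length(x$domains),
    broad = length(broad),
    broad_promoter = sum(broad$location_class == "promoter"),
    broad_distal = sum(broad$location_class == "distal"),
    regular = length(regular),
    sharp = length(sc$sharp), control = length(sc$control),
    super = sum(supers$is_super)))
}

run_ndr <- function(cfg) {
  assembly <- read_chrom_sizes(sim_input(cfg, "chrom.sizes"))
  tss <- read_tss(sim_input(cfg, "genes.tsv"))
  calls <- read_cytosine_calls(sim_input(cfg, "cytosine_calls.tsv"))
  p <- cfg$params
  res <- find_ndrs(calls, min_depth = p$min_depth, window = p$ndr_window,
                   step = p$ndr_step, p_max = p$ndr_p_max,
                   min_sites_exclusive = p$ndr_min_sites,
                   min_width_exclusive = p$ndr_min_width)
  ndrs <- classify_ndrs(res$ndrs, tss, flank = p$ndr_flank,
                        assembly = assembly)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(ndrs, file.path(cfg$out_dir, "ndrs.bed"),
            extra_cols = c("n_gch", "level", "p_value", "location_class"))
  list(counts = list(
    ndr = length(ndrs),
    ndr_proximal = sum(ndrs$location_class == "proximal"),
    ndr_distal = sum(ndrs$location_class == "distal"),
    background_rate = res$background$rate))
}

run_bivalency <- function(cfg) {
  assembly <- read_chrom_sizes(sim_input(cfg, "chrom.sizes"))
  tss <- read_tss(sim_input(cfg, "genes.tsv"))
  p <- cfg$params
  stage_peaks <- lapply(setNames(cfg$stages, cfg$stages), function(st) {
    list(k4 = read_peaks(sim_input(cfg, paste0("biv_k4me3_", st, ".bed")),
                         assembly = assembly),
         k27 = read_peaks(sim_input(cfg, paste0("biv_k27me3_", st, ".bed")),
                          assembly = assembly))
  })
  states <- promoter_state_matrix(stage_peaks, tss,
                                  flank = p$promoter_flank,
                                  assembly = assembly)
  universe <- bivalent_gene_universe(states)
  traj <- track_trajectories(universe)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(data.frame(gene_id = rownames(universe), universe,
                       check.names = FALSE),
            file.path(cfg$out_dir, "promoter_states.tsv"))
  write_tsv(traj$trajectories, file.path(cfg$out_dir, "trajectories.tsv"))
  trans_long <- do.call(rbind, lapply(names(traj$transitions), function(pr) {
    tt <- as.data.frame(traj$transitions[[pr]])
    names(tt) <- c("from", "to", "count")
    cbind(pair = pr, tt)
  }))
  write_tsv(trans_long, file.path(cfg$out_dir, "transitions.tsv"))
  list(counts = list(bivalent_universe = nrow(universe)))
}

run_states <- function(cfg) {
  p <- cfg$params
  segs <- lapply(setNames(cfg$stages, cfg$stages), function(st) {
    read_segmentation(sim_input(cfg, paste0("segments_", st, ".bed")),
                      n_states = p$n_states)
  })
  cov <- do.call(rbind, lapply(names(segs), function(st) {
    cbind(stage = st, state_coverage(segs[[st]], n_states = p$n_states))
  }))
  vb <- do.call(rbind, lapply(seq_along(segs)[-1L], function(j) {
    v <- variable_bases(segs[[j - 1L]], segs[[j]], n_states = p$n_states)
    cbind(pair = paste0(names(segs)[j - 1L], "->", names(segs)[j]),
          v$per_state,
          overall_fraction = v$overall$fraction)
  }))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cov, file.path(cfg$out_dir, "state_coverage.tsv"))
  write_tsv(vb, file.path(cfg$out_dir, "variable_bases.tsv"))
  list(counts = list(
    mean_overall_variable_fraction =
      mean(unique(vb[, c("pair", "overall_fraction")])$overall_fraction)))
}

run_timing <- function(cfg) {
  p <- cfg$params
  control <- read_fpkm(sim_input(cfg, "fpkm_control.tsv"))
  stages <- c("RS2", "RS4", "RS8", "LS")
  de_by_stage <- lapply(setNames(stages, stages), function(st) {
    read_de(sim_input(cfg, paste0("de_", st, ".tsv")))
  })
  keep <- stage_specific_filter(control, min_peak_fpkm = p$min_peak_fpkm,
                                specificity_ratio = p$specificity_ratio)
  timing <- peak_timing(control[keep, , drop = FALSE])
  shift <- timing_shift_summary(timing, de_by_stage,
                                lfc_min = p$lfc_min, p_max = p$p_adj_max)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(timing, file.path(cfg$out_dir, "peak_timing.tsv"))
  write_tsv(data.frame(signature = names(shift$counts),
                       count = as.integer(shift$counts)),
            file.path(cfg$out_dir, "timing_shift_counts.tsv"))
  list(counts = c(list(stage_specific = length(keep),
                       early = sum(timing$label == "early"),
                       late = sum(timing$label == "late")),
                  as.list(shift$counts)))
}

run_simulate <- function(cfg) {
  sim <- simulate_dataset(sim_config(seed = cfg$seed, stages = cfg$stages),
                          out_dir = cfg$sim_dir)
  list(counts = list(
    planted_broad = length(sim$peaks$truth$broad),
    planted_regular = length(sim$peaks$truth$regular),
    planted_ndr = length(sim$nome$truth),
    bivalent_genes = length(sim$biv$truth$bivalent_genes),
    affected_bivalent = length(sim$biv$truth$affected_genes),
    timed_genes = sum(sim$expr$truth$timed)))
}

#' Run one pipeline stage behind a subcommand
#'
#' Subcommands: `simulate` (write the synthetic dataset into `sim_dir`),
#' `domains`, `ndr`, `bivalency`, `states`, `timing` (each reads its inputs
#' from `sim_dir` and writes results plus counts into `out_dir`), and `all`
#' (every analysis subcommand in order). A manifest JSON recording the
#' package version, parameters, input digests and summary counts is written
#' to `out_dir/manifest_<name>.json`; reruns with identical inputs and
#' configuration reproduce identical outputs.
#'
#' @param name Subcommand name.
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, the manifest list.
#' @export
run_subcommand <- function(name, config) {
  if (is.character(config)) config <- read_run_config(config)
  runners <- list(simulate = run_simulate, domains = run_domains,
                  ndr = run_ndr, bivalency = run_bivalency,
                  states = run_states, timing = run_timing)
  if (!name %in% c(names(runners), "all")) {
    stop("unknown subcommand '", name, "'; expected one of: ",
         paste(c(names(runners), "all"), collapse = ", "))
  }
  todo <- if (name == "all") setdiff(names(runners), "simulate") else name
  counts <- list()
  for (nm in todo) {
    counts[[nm]] <- runners[[nm]](config)$counts
  }
  inputs <- list.files(config$sim_dir, full.names = TRUE)
  manifest <- list(
    package = "spermEpi",
    version = as.character(utils::packageVersion("spermEpi")),
    subcommand = name,
    seed = config$seed,
    parameters = config$params,
    stages = config$stages,
    input_digests = if (length(inputs) > 0L) {
      as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs)))
    } else list(),
    counts = counts
  )
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
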