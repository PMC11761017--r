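# End-to-end pipeline: simulate -> time SNVs -> time HLA LOH -> classify
# events -> aggregate timelines -> prevalence, driven by one JSON config
# with deterministic seeding and a manifest of thresholds and row counts.

#' Build a validated run configuration
#'
#' All thresholds default to the analysis' reference values (early/late
#' draw fraction 0.6; timeline ratio bounds 0.5 and 2; at least 5
#' determined samples; LOH p-value 0.01 and minor CN 0.5; S = 250 draws;
#' subclonal sentinel 1.01). Any override is echoed into the run manifest.
#'
#' @param config Path to a JSON config file, or a named list.
#' @param ... Field overrides (take precedence over the file).
#' @return List of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  base <- list(
    seed = 1L, S = 250L, out_dir = "escapeclock_run",
    simulate = NULL, # sim_config() overrides, or NULL to use explicit inputs
    inputs = NULL,   # list(snvs=, segments=, gains=, purity=, hla=, drivers=, gmt=)
    thresholds = list(frac_threshold = 0.6, early_ratio = 0.5, late_ratio = 2,
                      min_samples = 5, loh_p = 0.01, loh_minor_cn = 0.5,
                      loh_minor_zero_tol = 0.05, loh_major_gt_one = 1.5),
    switches = list(include_subclonal = TRUE, prior = "length",
                    subclonal_prior_weight = 0.1, subclonal_ccf = 0.5,
                    exclude_self = TRUE))
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  merge_into <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_into(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  cfg <- merge_into(base, config %||% list())
  cfg <- merge_into(cfg, list(...))
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config must request simulation or provide explicit inputs")
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' @param config A `run_config` (or anything [run_config()] accepts).
#' @return Invisibly, the run manifest list. Outputs under
#'   `config$out_dir`: `timing.tsv` (+ draws sidecar), `loh_timing.tsv`,
#'   `calls.tsv`, `timeline.tsv`, `strata.json`, `prevalence.tsv`,
#'   `mutant_matrix.tsv`, `apm_calls.tsv`, `run_manifest.json`, and (when
#'   simulating) the cohort bundle under `cohort/`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[escapeclock] ", ...)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs (simulated or provided)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    sim_args$draws_S <- sim_args$draws_S %||% config$S
    scfg <- stage("simulate", do.call(sim_config, sim_args))
    cdir <- file.path(out, "cohort")
    stage("simulate", simulate_cohort(scfg, cdir, overwrite = TRUE))
    log_stage("simulate: cohort written to ", cdir)
    sdirs <- list.dirs(file.path(cdir, "samples"), recursive = FALSE)
    gather <- function(fname) do.call(rbind, lapply(sdirs, function(d)
      read_tsv_strict(file.path(d, fname))))
    inputs <- list(snvs = gather("snvs.tsv"), segments = gather("segments.tsv"),
                   gains = gather("gains.tsv"), hla = gather("hla.tsv"),
                   purity = read_tsv_strict(file.path(cdir, "purity.tsv")),
                   drivers = readLines(file.path(cdir, "drivers.txt")),
                   gene_sets = read_gmt(file.path(cdir, "pathways.gmt")))
  } else {
    ip <- config$inputs
    inputs <- stage("load-inputs", list(
      snvs = if (is.character(ip$snvs) && grepl("\\.vcf$", ip$snvs))
        read_snv_vcf(ip$snvs) else read_tsv_strict(ip$snvs),
      segments = read_tsv_strict(ip$segments),
      gains = read_tsv_strict(ip$gains),
      hla = read_tsv_strict(ip$hla),
      purity = read_tsv_strict(ip$purity),
      drivers = readLines(ip$drivers),
      gene_sets = read_gmt(ip$gmt)))
  }
  counts$n_snvs <- nrow(inputs$snvs)
  counts$n_samples <- length(unique(inputs$purity$sample))

  sw <- config$switches; th <- config$thresholds

  # --- SNV timing
  gps <- stage("time-snvs", read_gain_posteriors(inputs$gains, inputs$segments))
  timing <- stage("time-snvs", time_all_snvs(
    inputs$snvs, inputs$segments, gps, inputs$purity, S = config$S,
    seed = config$seed, subclonal_ccf = sw$subclonal_ccf,
    subclonal_prior_weight = sw$subclonal_prior_weight, prior = sw$prior))
  write_timing(timing, file.path(out, "timing.tsv"))
  counts$n_timed <- sum(timing$timing$timed)
  counts$n_untimed <- sum(!timing$timing$timed)
  log_stage("time-snvs: ", counts$n_timed, " timed, ",
            counts$n_untimed, " untimed")

  # --- HLA LOH timing
  loh <- stage("time-loh", time_all_hla_loh(
    inputs$hla, attr(gps, "wgd_times"), S = config$S, seed = config$seed,
    p_threshold = th$loh_p, minor_cn_threshold = th$loh_minor_cn,
    minor_zero_tol = th$loh_minor_zero_tol, major_gt_one = th$loh_major_gt_one))
  write_tsv(loh$calls, file.path(out, "loh_timing.tsv"))
  counts$n_hla_loh <- sum(loh$calls$is_LOH, na.rm = TRUE)
  counts$n_loh_pre_wgd <- sum(loh$calls$status == "pre_wgd")
  log_stage("time-loh: ", counts$n_hla_loh, " LOH calls, ",
            counts$n_loh_pre_wgd, " timed pre-WGD")

  # --- classification (non-synonymous SNVs only)
  nonsyn <- is_nonsynonymous(timing$timing$class)
  timing_ns <- list(timing = timing$timing[nonsyn, , drop = FALSE],
                    draws = timing$draws[nonsyn, , drop = FALSE])
  calls <- stage("classify", build_event_calls(
    timing_ns, inputs$drivers, inputs$gene_sets,
    frac_threshold = th$frac_threshold, exclude_self = sw$exclude_self,
    include_subclonal = sw$include_subclonal))
  write_tsv(calls, file.path(out, "calls.tsv"))
  counts$n_calls <- nrow(calls)
  counts$n_excluded_samples <- length(attr(calls, "excluded_samples"))
  log_stage("classify: ", nrow(calls), " calls; ",
            counts$n_excluded_samples, " sample(s) without driver SNVs")

  # --- timeline + strata
  timeline <- stage("aggregate", aggregate_timeline(
    calls, min_samples = th$min_samples, early_ratio = th$early_ratio,
    late_ratio = th$late_ratio))
  write_tsv(timeline, file.path(out, "timeline.tsv"))
  strata <- timing_strata_export(calls)
  jsonlite::write_json(strata, file.path(out, "strata.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  counts$n_timeline <- nrow(timeline)

  # --- prevalence + APM calls
  mut <- data.frame(sample = inputs$snvs$sample, gene = inputs$snvs$gene,
                    pos = inputs$snvs$pos,
                    variant_classification = inputs$snvs$class,
                    stringsAsFactors = FALSE)
  ctypes <- unique(inputs$purity[, c("sample", "cancer_type")])
  prev <- stage("prevalence",
                prevalence_table(mut, inputs$gene_sets, cancer_types = ctypes))
  write_tsv(prev$prevalence, file.path(out, "prevalence.tsv"))
  mm <- data.frame(sample = rownames(prev$matrix), prev$matrix,
                   check.names = FALSE)
  write_tsv(mm, file.path(out, "mutant_matrix.tsv"))
  loh_by_sample <- tapply(!is.na(loh$calls$is_LOH) & loh$calls$is_LOH,
                          loh$calls$sample, any)
  apm <- data.frame(sample = ctypes$sample, stringsAsFactors = FALSE)
  apm$apm_mutant <- vapply(apm$sample, function(smp) apm_mutant_call(
    mut[mut$sample == smp, , drop = FALSE],
    isTRUE(unname(loh_by_sample[smp]))), logical(1))
  write_tsv(apm, file.path(out, "apm_calls.tsv"))
  counts$n_apm_mutant <- sum(apm$apm_mutant)
  log_stage("prevalence: ", counts$n_apm_mutant, " APM-mutant sample(s)")

  manifest <- list(package = "escapeclock",
                   seed = config$seed, S = config$S,
                   thresholds = th, switches = sw, counts = counts)
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run`. `simulate` writes a synthetic cohort
#' bundle; `run` executes the full pipeline from a JSON config. Installed
#' alongside the package as `inst/cli/escape-clock`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status: 0 success, 2 config error, 3 stage failure.
#' @export
escape_clock_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: escape-clock <simulate|run> [options]"
  if (!length(args)) {
    message(usage)
    return(2L)
  }
  cmd <- args[[1]]
  rest <- args[-1]
  res <- tryCatch({
    switch(cmd,
      simulate = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          optparse::make_option("--config", type = "character", default = NULL),
          optparse::make_option("--out", type = "character"),
          optparse::make_option("--seed", type = "integer", default = 1L))),
          args = rest)
        if (is.null(opts$out)) stop("simulate: --out is required")
        sim_args <- if (is.null(opts$config)) list()
                    else jsonlite::read_json(opts$config, simplifyVector = TRUE,
                                             simplifyDataFrame = FALSE)
        sim_args$seed <- opts$seed
        simulate_cohort(do.call(sim_config, sim_args), opts$out,
                        overwrite = TRUE)
        0L
      },
      run = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          optparse::make_option("--config", type = "character"))), args = rest)
        if (is.null(opts$config)) stop("run: --config is required")
        cfg <- tryCatch(run_config(opts$config),
                        error = function(e) e)
        if (inherits(cfg, "error")) {
          message("config error: ", conditionMessage(cfg))
          return(2L)
        }
        run_pipeline(cfg)
        0L
      },
      {
        message("unknown command: ", cmd, "\n", usage)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  res
}
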