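# Synthetic multi-cancer-type cohort generator with known ground truth.
#
# The generator emulates the statistical structure the timing analysis
# assumes: per-segment gain forests (binary gains plus optional
# whole-genome doubling shared across segments), clonal SNVs placed on
# forest edges, binomial read counts at purity- and copy-number-adjusted
# expected VAF, planted early/late pathway mutation-time distributions,
# subclonal mixtures, and HLA allelic-imbalance tables with planted LOH.
# Truth tables record every latent quantity so downstream stages can be
# scored exactly.

#' Default driver genes for simulated cohorts
#' @export
DEFAULT_DRIVERS <- c("TP53", "KRAS", "PIK3CA", "PTEN", "ARID1A", "APC",
                     "BRAF", "SMAD4", "RB1", "EGFR")

#' Default immunomodulatory pathway gene sets for simulated cohorts
#' @export
DEFAULT_PATHWAYS <- list(
  antigen_presentation = c("B2M", "NLRC5", "TAP1", "TAP2", "TAPBP",
                           "PSMB8", "PSMB9", "ERAP1"),
  tnf_signaling = c("TNF", "TNFRSF1A", "TRAF2", "RIPK1", "BIRC2", "BIRC3",
                    "MAP3K7", "IKBKB"))

#' Build and validate a simulation configuration
#'
#' Defaults describe the reference synthetic world used throughout the test
#' suite: 3 cancer types x 60 samples, mean depth 100, an early pathway
#' (mutation times ~ Beta(2, 8)) and a late pathway (~ Beta(8, 2)), drivers
#' uniform on [0, 1], 30% WGD samples, 250 timing draws.
#'
#' @param cancer_types Character vector of type labels.
#' @param samples_per_type Samples per type.
#' @param purity_range Purity interval within (0, 1].
#' @param mean_depth Expected sequencing depth (Poisson mean, min depth 1).
#' @param wgd_probability Per-sample WGD probability.
#' @param wgd_time_range WGD time interval within (0, 1).
#' @param max_gains_per_segment Cap on individual (non-WGD) gains.
#' @param gain_rate Per-segment expected number of individual gains.
#' @param n_segments Segments per sample (one per pseudo-chromosome).
#' @param driver_genes Driver gene symbols.
#' @param driver_snvs_per_sample Clonal/subclonal driver SNVs per sample.
#' @param driver_time_distribution NULL to place driver SNVs uniformly over
#'   forest edge length (uniform mutation arrival over copies and time), or
#'   a distribution spec (see `pathway_time_distributions`) for the marginal
#'   mutation-time law.
#' @param pathway_gene_sets Named list of pathway gene vectors.
#' @param pathway_time_distributions Named list (same names) of specs:
#'   `list(dist = "beta", shape1=, shape2=)`, `list(dist = "uniform",
#'   min=, max=)`, or `list(dist = "point", value=)`.
#' @param pathway_mutation_prob Per-sample probability each pathway is hit.
#' @param pathway_snvs_per_event SNVs per pathway hit.
#' @param passenger_snvs_per_sample Filler SNVs (mixed classes, genes in no
#'   set) exercising the non-synonymous filter.
#' @param subclonal_fraction Probability any SNV is subclonal.
#' @param subclonal_ccf_range CCF interval for subclonal SNVs, within (0,1).
#' @param hla_loh_probability Per-sample probability of HLA LOH (whole
#'   haplotype: all three class I genes).
#' @param gain_posterior_jitter_sd Truncated-normal sd for emitted gain-time
#'   posterior draws.
#' @param draws_S Posterior draws per segment (default 250).
#' @param seed Cohort seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(cancer_types = c("adenoca_A", "adenoca_B", "squamous_C"),
                       samples_per_type = 60L,
                       purity_range = c(0.4, 0.9),
                       mean_depth = 100,
                       wgd_probability = 0.3,
                       wgd_time_range = c(0.2, 0.8),
                       max_gains_per_segment = 2L,
                       gain_rate = 0.7,
                       n_segments = 20L,
                       driver_genes = DEFAULT_DRIVERS,
                       driver_snvs_per_sample = 8L,
                       driver_time_distribution = list(dist = "uniform",
                                                       min = 0, max = 1),
                       pathway_gene_sets = DEFAULT_PATHWAYS,
                       pathway_time_distributions = list(
                         antigen_presentation = list(dist = "beta",
                                                     shape1 = 2, shape2 = 8),
                         tnf_signaling = list(dist = "beta",
                                              shape1 = 8, shape2 = 2)),
                       pathway_mutation_prob = 0.6,
                       pathway_snvs_per_event = 2L,
                       passenger_snvs_per_sample = 4L,
                       subclonal_fraction = 0.1,
                       subclonal_ccf_range = c(0.2, 0.6),
                       hla_loh_probability = 0.25,
                       gain_posterior_jitter_sd = 0.02,
                       draws_S = 250L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(samples_per_type >= 1, n_segments >= 1, mean_depth > 0,
            draws_S >= 1, max_gains_per_segment >= 0,
            gain_posterior_jitter_sd >= 0)
  .check_interval <- function(x, lo, hi, nm, lo_open = TRUE, hi_open = FALSE) {
    ok <- length(x) == 2 && x[1] <= x[2] &&
      (if (lo_open) x[1] > lo else x[1] >= lo) &&
      (if (hi_open) x[2] < hi else x[2] <= hi)
    if (!ok) stop(nm, " must be an interval within ",
                  if (lo_open) "(" else "[", lo, ",", hi,
                  if (hi_open) ")" else "]")
  }
  .check_interval(cfg$purity_range, 0, 1, "purity_range")
  .check_interval(cfg$subclonal_ccf_range, 0, 1, "subclonal_ccf_range",
                  hi_open = TRUE)
  for (p in c("wgd_probability", "subclonal_fraction",
              "pathway_mutation_prob", "hla_loh_probability"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0,1]")
  if (!setequal(names(pathway_gene_sets), names(pathway_time_distributions)))
    stop("pathway_gene_sets and pathway_time_distributions must name the ",
         "same pathways")
  for (p in names(pathway_gene_sets))
    if (!length(pathway_gene_sets[[p]]))
      stop("pathway gene set is empty: ", p)
  # shared-membership audit: genes in more than one set are allowed but recorded
  all_genes <- unlist(pathway_gene_sets, use.names = FALSE)
  cfg$shared_genes <- sort(unique(all_genes[duplicated(all_genes)]))
  structure(cfg, class = "sim_config")
}

# Draw one value from a distribution spec on [0,1].
.draw_time <- function(spec, n = 1L) {
  switch(spec$dist,
         beta = stats::rbeta(n, spec$shape1, spec$shape2),
         uniform = stats::runif(n, spec$min %||% 0, spec$max %||% 1),
         point = rep(spec$value, n),
         stop("unknown time distribution: ", spec$dist))
}

# Forward-simulate a gain forest for one segment: `n_gains` individual
# binary gains at uniform times, plus (optionally) WGD duplicating every
# extant copy at t_wgd. Returns gain-node records plus realized CN.
.simulate_forest <- function(n_gains, t_wgd = NULL, id_prefix = "n") {
  gain_times <- sort(stats::runif(n_gains))
  events <- data.frame(time = gain_times,
                       is_wgd = rep(FALSE, n_gains))
  if (!is.null(t_wgd))
    events <- rbind(events, data.frame(time = t_wgd, is_wgd = TRUE))
  events <- events[order(events$time), , drop = FALSE]
  # extant lineages: allele + node id of the gain that opened them (NA = root)
  lin <- data.frame(allele = c("major", "minor"),
                    parent = NA_character_, stringsAsFactors = FALSE)
  nodes <- list()
  ctr <- 0L
  new_id <- function() {
    ctr <<- ctr + 1L
    paste0(id_prefix, ctr)
  }
  split_lineage <- function(i, time, is_wgd) {
    id <- new_id()
    nodes[[length(nodes) + 1L]] <<- data.frame(
      node_id = id, parent_id = lin$parent[i], allele = lin$allele[i],
      time = time, is_wgd = is_wgd, stringsAsFactors = FALSE)
    rbind(data.frame(allele = lin$allele[i], parent = id),
          data.frame(allele = lin$allele[i], parent = id))
  }
  for (e in seq_len(nrow(events))) {
    if (events$is_wgd[e]) {
      lin <- do.call(rbind, lapply(seq_len(nrow(lin)), function(i)
        split_lineage(i, events$time[e], TRUE)))
    } else {
      i <- sample.int(nrow(lin), 1L)
      lin <- rbind(lin[-i, , drop = FALSE],
                   split_lineage(i, events$time[e], FALSE))
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes)
           else data.frame(node_id = character(), parent_id = character(),
                           allele = character(), time = numeric(),
                           is_wgd = logical(), stringsAsFactors = FALSE)
  list(nodes = nodes,
       cn = c(major = sum(lin$allele == "major"),
              minor = sum(lin$allele == "minor")))
}

# Place one clonal SNV on a forest. With t = NULL the edge is chosen with
# probability proportional to its time-length and the time is uniform on the
# edge (uniform arrival over the whole forest); with a planted time t the
# SNV hits one of the copies extant at t, chosen uniformly.
.place_snv <- function(forest, t = NULL) {
  e <- forest$edges
  if (is.null(t)) {
    len <- e$t_end - e$t_start
    i <- sample.int(nrow(e), 1L, prob = len)
    t <- stats::runif(1, e$t_start[i], e$t_end[i])
  } else {
    cand <- which(e$t_start <= t & t < e$t_end)
    if (!length(cand)) cand <- which.max(e$t_end) # t == 1 boundary
    i <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }
  list(t = t, m = e$leaf_count[i], edge = e[i, , drop = FALSE])
}

#' Simulate one sample with ground truth
#'
#' @param config A `sim_config`.
#' @param cancer_type Type label for the sample.
#' @param sample_id Sample identifier.
#' @param seed Integer seed for this sample's substream.
#' @return List with `bundle` (data.frames `snvs`, `segments`, `purity`,
#'   `hla`) and `truth` (forests per segment, per-SNV truth, WGD time, HLA
#'   truth, purity, ploidy).
#' @export
simulate_sample <- function(config, cancer_type, sample_id, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, .simulate_sample_impl(config, cancer_type, sample_id))
}

.simulate_sample_impl <- function(config, cancer_type, sample_id) {
  rho <- stats::runif(1, config$purity_range[1], config$purity_range[2])
  has_wgd <- stats::runif(1) < config$wgd_probability
  t_wgd <- if (has_wgd)
    stats::runif(1, config$wgd_time_range[1], config$wgd_time_range[2])
  else NA_real_

  # segments and forests (one pseudo-chromosome per segment)
  forests <- list()
  seg_rows <- list()
  for (k in seq_len(config$n_segments)) {
    n_gains <- min(stats::rpois(1, config$gain_rate),
                   config$max_gains_per_segment)
    sim <- .simulate_forest(n_gains, if (has_wgd) t_wgd else NULL,
                            id_prefix = paste0("seg", k, "_n"))
    sid <- paste0("seg", k)
    forests[[sid]] <- list(nodes = sim$nodes, cn = sim$cn)
    seg_rows[[k]] <- data.frame(
      sample = sample_id, segment_id = sid, chrom = paste0("chr", k),
      start = 0L, end = 1000000L,
      major = unname(sim$cn["major"]), minor = unname(sim$cn["minor"]),
      stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_rows)
  ploidy <- mean(segments$major + segments$minor)

  # gene layout: deterministic round-robin across segments
  genes <- unique(c(config$driver_genes,
                    unlist(config$pathway_gene_sets, use.names = FALSE)))
  gene_seg <- ((seq_along(genes) - 1L) %% config$n_segments) + 1L
  gene_pos <- integer(length(genes))
  for (k in seq_len(config$n_segments)) {
    idx <- which(gene_seg == k)
    gene_pos[idx] <- 10000L * seq_along(idx)
  }
  names(gene_seg) <- names(gene_pos) <- genes

  # SNV emission
  snv_rows <- list()
  truth_rows <- list()
  snv_ctr <- 0L
  emit_snv <- function(gene, origin, planted_spec, class_pool) {
    snv_ctr <<- snv_ctr + 1L
    known_gene <- gene %in% genes
    seg_k <- if (known_gene) gene_seg[[gene]]
             else (snv_ctr %% config$n_segments) + 1L
    sid <- paste0("seg", seg_k)
    fr <- forest_from_records(forests[[sid]]$nodes, forests[[sid]]$cn, sid)
    pos <- (if (known_gene) gene_pos[[gene]] else 900000L) + snv_ctr
    n_t <- fr$major + fr$minor
    subclonal <- stats::runif(1) < config$subclonal_fraction
    if (subclonal) {
      ccf <- stats::runif(1, config$subclonal_ccf_range[1],
                          config$subclonal_ccf_range[2])
      t_true <- NA_real_; m_true <- 1L
      f <- expected_vaf(NULL, rho, n_t, ccf = ccf)
    } else {
      ccf <- NA_real_
      t_planted <- if (is.null(planted_spec)) NULL else .draw_time(planted_spec)
      pl <- .place_snv(fr, t_planted)
      t_true <- pl$t; m_true <- pl$m
      f <- expected_vaf(m_true, rho, n_t)
    }
    d <- stats::rpois(1, config$mean_depth)
    tries <- 0L
    while (d < 1L) {
      tries <- tries + 1L
      if (tries > 100L)
        stop("zero-depth resampling exhausted (mean_depth = ",
             config$mean_depth, ")")
      d <- stats::rpois(1, config$mean_depth)
    }
    a <- stats::rbinom(1, d, f)
    ra <- sample(c("A", "C", "G", "T"), 2L)
    cls <- sample(class_pool, 1L)
    snv_rows[[length(snv_rows) + 1L]] <<- data.frame(
      sample = sample_id, cancer_type = cancer_type,
      chrom = paste0("chr", seg_k), pos = pos, ref = ra[1], alt = ra[2],
      gene = gene, class = cls, ref_count = d - a, alt_count = a,
      stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      sample = sample_id, cancer_type = cancer_type,
      chrom = paste0("chr", seg_k), pos = pos, gene = gene, origin = origin,
      segment_id = sid, n_t = n_t, subclonal = subclonal, ccf = ccf,
      t_true = t_true, m_true = m_true, expected_vaf = f,
      stringsAsFactors = FALSE)
  }

  nonsyn_pool <- c(rep("Missense_Mutation", 6), "Nonsense_Mutation",
                   "Frame_Shift_Del", "Splice_Site", "In_Frame_Ins")
  # drivers
  for (g in sample(config$driver_genes, config$driver_snvs_per_sample,
                   replace = TRUE))
    emit_snv(g, "driver", config$driver_time_distribution, nonsyn_pool)
  # planted pathway events
  for (p in names(config$pathway_gene_sets)) {
    if (stats::runif(1) >= config$pathway_mutation_prob) next
    gs <- sample(config$pathway_gene_sets[[p]], config$pathway_snvs_per_event,
                 replace = TRUE)
    for (g in gs)
      emit_snv(g, p, config$pathway_time_distributions[[p]], nonsyn_pool)
  }
  # passengers in genes outside every set, mixed classes
  if (config$passenger_snvs_per_sample > 0)
    for (j in seq_len(config$passenger_snvs_per_sample))
      emit_snv(paste0("PSG", j), "passenger", NULL,
               c("Silent", "Missense_Mutation", "Intron", "3'UTR"))

  snvs <- do.call(rbind, snv_rows)
  snv_truth <- do.call(rbind, truth_rows)

  # HLA allelic imbalance: whole-haplotype LOH hits all three class I genes
  hla_genes <- c("HLA-A", "HLA-B", "HLA-C")
  has_loh <- stats::runif(1) < config$hla_loh_probability
  loh_pre_wgd <- has_wgd && has_loh && stats::runif(1) < 0.8
  t_loh <- if (!has_loh) NA_real_
           else if (loh_pre_wgd) stats::runif(1, 0, t_wgd)
           else if (has_wgd) stats::runif(1, t_wgd, 1)
           else stats::runif(1)
  hla <- do.call(rbind, lapply(hla_genes, function(g) {
    if (has_loh) {
      data.frame(sample = sample_id, hla_gene = g,
                 ai_p_value = stats::runif(1, 1e-6, 0.009),
                 minor_cn = stats::runif(1, 0, 0.04),
                 major_cn = if (loh_pre_wgd) 2 +  stats::runif(1, -0.1, 0.1)
                            else 1 + stats::runif(1, -0.1, 0.1),
                 stringsAsFactors = FALSE)
    } else {
      base <- if (has_wgd) 2 else 1
      data.frame(sample = sample_id, hla_gene = g,
                 ai_p_value = stats::runif(1, 0.05, 1),
                 minor_cn = base + stats::runif(1, -0.15, 0.15),
                 major_cn = base + stats::runif(1, -0.15, 0.15),
                 stringsAsFactors = FALSE)
    }
  }))
  hla_truth <- data.frame(sample = sample_id, loh = has_loh,
                          pre_wgd = loh_pre_wgd, t_loh = t_loh,
                          stringsAsFactors = FALSE)

  purity <- data.frame(sample = sample_id, cancer_type = cancer_type,
                       purity = rho, ploidy = ploidy,
                       wgd_status = has_wgd, stringsAsFactors = FALSE)
  truth <- list(sample = sample_id, cancer_type = cancer_type,
                forests = forests, wgd_time = t_wgd, snvs = snv_truth,
                hla = hla_truth, purity = rho, ploidy = ploidy)
  list(bundle = list(snvs = snvs, segments = segments, purity = purity,
                     hla = hla),
       truth = truth)
}

#' Emit jittered gain-timing posterior draws for one sample's truth
#'
#' Each draw perturbs every true gain time with truncated-normal noise
#' (clipped to [0, 1]); ancestral ordering (parent time <= child time) is
#' enforced topologically and WGD nodes share one jittered time across all
#' segments within a draw.
#'
#' @param truth `truth` element from [simulate_sample()].
#' @param jitter_sd Noise sd (0 reproduces the truth exactly in every draw).
#' @param S Number of draws.
#' @param seed Integer seed.
#' @return Long data.frame: `sample`, `segment_id`, `draw`, `node_id`,
#'   `parent_id`, `allele`, `time`, `is_wgd`.
#' @export
emit_gain_posterior <- function(truth, jitter_sd, S, seed = 1L) {
  stopifnot(S >= 1, jitter_sd >= 0)
  with_seed(seed, .emit_gain_posterior_impl(truth, jitter_sd, S))
}

.emit_gain_posterior_impl <- function(truth, jitter_sd, S) {
  has_wgd <- !is.na(truth$wgd_time %||% NA_real_)
  wgd_jit <- if (has_wgd)
    pmin(pmax(truth$wgd_time + stats::rnorm(S, 0, jitter_sd), 0), 1)
  else NULL
  out <- list()
  for (sid in names(truth$forests)) {
    nd <- truth$forests[[sid]]$nodes
    if (nrow(nd) == 0L) next
    n <- nrow(nd)
    tm <- matrix(NA_real_, n, S)
    ord <- order(nd$time)
    pidx <- match(nd$parent_id, nd$node_id)
    for (i in ord) {
      if (nd$is_wgd[i]) {
        tm[i, ] <- wgd_jit
        next
      }
      v <- pmin(pmax(nd$time[i] + stats::rnorm(S, 0, jitter_sd), 0), 1)
      lb <- if (is.na(pidx[i])) 0 else tm[pidx[i], ]
      # every node predating the WGD is an ancestor of WGD copies
      ub <- if (has_wgd && nd$time[i] < truth$wgd_time) wgd_jit else 1
      tm[i, ] <- pmin(pmax(v, lb), ub)
    }
    out[[sid]] <- data.frame(
      sample = truth$sample, segment_id = sid,
      draw = rep(seq_len(S), each = n),
      node_id = rep(nd$node_id, S), parent_id = rep(nd$parent_id, S),
      allele = rep(nd$allele, S), time = as.vector(tm),
      is_wgd = rep(nd$is_wgd, S), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample = character(), segment_id = character(),
                      draw = integer(), node_id = character(),
                      parent_id = character(), allele = character(),
                      time = numeric(), is_wgd = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a cohort and write it to disk
#'
#' Deterministic given the config seed: the same config yields a
#' byte-identical bundle. A `.incomplete` marker guards against reading a
#' partially written directory.
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if absent).
#' @param overwrite Allow writing into a directory holding a previous
#'   (possibly corrupt) bundle.
#' @return Invisibly, the manifest list. Files written: per-sample
#'   `samples/<id>/{snvs.tsv,snvs.vcf,segments.tsv,gains.tsv,hla.tsv}`;
#'   cohort-level `purity.tsv`, `drivers.txt`, `pathways.gmt`,
#'   `truth_snvs.tsv`, `truth_samples.tsv`, `truth_hla.tsv`,
#'   `manifest.json`. Coordinates are 0-based half-open (VCF output
#'   1-based, as the format requires).
#' @export
simulate_cohort <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  marker <- file.path(out_dir, ".incomplete")
  if (file.exists(marker) && !overwrite)
    stop("output directory holds a partial bundle (", marker,
         "); remove it or pass overwrite = TRUE")
  dir.create(file.path(out_dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  file.create(marker)
  files <- list()
  put <- function(x, path) {
    write_tsv(x, file.path(out_dir, path))
    files[[path]] <<- nrow(x)
  }
  purity_all <- snv_truth_all <- hla_truth_all <- samp_truth_all <- list()
  truths <- list()
  for (ctype in config$cancer_types) {
    for (i in seq_len(config$samples_per_type)) {
      sid <- sprintf("%s_s%02d", ctype, i)
      sim <- simulate_sample(config, ctype, sid,
                             seed = derive_seed(config$seed, sid, "sim"))
      gains <- emit_gain_posterior(sim$truth,
                                   config$gain_posterior_jitter_sd,
                                   config$draws_S,
                                   seed = derive_seed(config$seed, sid, "gains"))
      sdir <- file.path("samples", sid)
      dir.create(file.path(out_dir, sdir), showWarnings = FALSE)
      put(sim$bundle$snvs, file.path(sdir, "snvs.tsv"))
      put(sim$bundle$segments, file.path(sdir, "segments.tsv"))
      put(gains, file.path(sdir, "gains.tsv"))
      put(sim$bundle$hla, file.path(sdir, "hla.tsv"))
      write_snv_vcf(sim$bundle$snvs, file.path(out_dir, sdir, "snvs.vcf"))
      files[[file.path(sdir, "snvs.vcf")]] <- nrow(sim$bundle$snvs)
      purity_all[[sid]] <- sim$bundle$purity
      snv_truth_all[[sid]] <- sim$truth$snvs
      hla_truth_all[[sid]] <- sim$truth$hla
      samp_truth_all[[sid]] <- data.frame(
        sample = sid, cancer_type = ctype, purity = sim$truth$purity,
        ploidy = sim$truth$ploidy, wgd_time = sim$truth$wgd_time,
        stringsAsFactors = FALSE)
      truths[[sid]] <- sim$truth
    }
  }
  put(do.call(rbind, purity_all), "purity.tsv")
  put(do.call(rbind, snv_truth_all), "truth_snvs.tsv")
  put(do.call(rbind, hla_truth_all), "truth_hla.tsv")
  put(do.call(rbind, samp_truth_all), "truth_samples.tsv")
  writeLines(config$driver_genes, file.path(out_dir, "drivers.txt"))
  files[["drivers.txt"]] <- length(config$driver_genes)
  write_gmt(config$pathway_gene_sets, file.path(out_dir, "pathways.gmt"))
  files[["pathways.gmt"]] <- length(config$pathway_gene_sets)
  manifest <- list(
    generator = "escapeclock::simulate_cohort",
    seed = config$seed,
    n_samples = length(config$cancer_types) * config$samples_per_type,
    cancer_types = config$cancer_types,
    draws_S = config$draws_S,
    coordinates = "0-based half-open (VCF files 1-based)",
    shared_pathway_genes = config$shared_genes,
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.remove(marker)
  invisible(structure(manifest, truths = truths))
}

#' Write / read the minimal SNV VCF dialect
#'
#' CHROM/POS/REF/ALT with `gene=` and `class=` INFO keys and a single tumor
#' sample carrying `AD` (ref,alt). Positions are converted between the
#' package's 0-based convention and VCF's 1-based one.
#'
#' @param snvs SNV data.frame (`sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `class`, `ref_count`, `alt_count`).
#' @param path File path.
#' @return `path` invisibly (writer); an SNV data.frame (reader).
#' @export
write_snv_vcf <- function(snvs, path) {
  sample_id <- unique(snvs$sample)
  stopifnot(length(sample_id) == 1L)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=escapeclock-simulate",
    "##INFO=<ID=gene,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=class,Number=1,Type=String,Description=\"Variant classification\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tgene=%s;class=%s\tAD\t%d,%d",
                  snvs$chrom, snvs$pos + 1L, snvs$ref, snvs$alt, snvs$gene,
                  snvs$class, snvs$ref_count, snvs$alt_count)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_snv_vcf
#' @export
read_snv_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("not a VCF: missing #CHROM header in ", path)
  sample_id <- utils::tail(strsplit(hdr, "\t", fixed = TRUE)[[1]], 1L)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  info <- vapply(f, `[[`, character(1), 8L)
  ad <- strsplit(vapply(f, `[[`, character(1), 10L), ",", fixed = TRUE)
  data.frame(
    sample = sample_id,
    chrom = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)) - 1L,
    ref = vapply(f, `[[`, character(1), 4L),
    alt = vapply(f, `[[`, character(1), 5L),
    gene = info_get(info, "gene"),
    class = info_get(info, "class"),
    ref_count = as.integer(vapply(ad, `[[`, character(1), 1L)),
    alt_count = as.integer(vapply(ad, `[[`, character(1), 2L)),
    stringsAsFactors = FALSE)
}
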