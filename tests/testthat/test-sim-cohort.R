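# Synthetic cohort generator: VAF model, planted truths, posterior emitter,
# on-disk bundles.

test_that("purity/copy-number VAF relation matches hand arithmetic", {
  expect_equal(expected_vaf(2, 0.5, 3), 0.4)
  expect_equal(expected_vaf(1, 1.0, 2), 0.5)
  expect_equal(expected_vaf(NULL, 0.8, 2, ccf = 0.5), 0.2)
})

test_that("subclonal_fraction boundaries drive the truth records", {
  cfg0 <- small_cfg(subclonal_fraction = 0)
  s0 <- simulate_sample(cfg0, "typeA", "t1", seed = 1)
  expect_false(any(s0$truth$snvs$subclonal))
  expect_true(all(!is.na(s0$truth$snvs$t_true)))
  cfg1 <- small_cfg(subclonal_fraction = 1)
  s1 <- simulate_sample(cfg1, "typeA", "t1", seed = 1)
  expect_true(all(s1$truth$snvs$subclonal))
  expect_true(all(s1$truth$snvs$m_true == 1L))
  expect_true(all(s1$truth$snvs$ccf < 1))
})

test_that("simulated forests agree with emitted segment copy numbers and truth times", {
  cfg <- small_cfg(wgd_probability = 0.6, gain_rate = 1.2,
                   max_gains_per_segment = 3L)
  for (seed in 1:4) {
    s <- simulate_sample(cfg, "typeA", "t", seed = seed)
    seg <- s$bundle$segments
    for (i in seq_len(nrow(seg))) {
      cn <- s$truth$forests[[seg$segment_id[i]]]$cn
      expect_equal(unname(cn["major"]), seg$major[i])
      expect_equal(unname(cn["minor"]), seg$minor[i])
    }
    # clonal multi-copy SNVs predate the gains that duplicated them: the
    # truth time lies inside an edge with that exact leaf count
    tr <- s$truth$snvs[!s$truth$snvs$subclonal, ]
    for (j in seq_len(nrow(tr))) {
      fr <- forest_from_records(s$truth$forests[[tr$segment_id[j]]]$nodes,
                                s$truth$forests[[tr$segment_id[j]]]$cn)
      e <- fr$edges
      hit <- e$t_start <= tr$t_true[j] & tr$t_true[j] <= e$t_end &
        e$leaf_count == tr$m_true[j]
      expect_true(any(hit))
    }
  }
})

test_that("clonal m=1 VAF converges to the model value at high depth", {
  cfg <- small_cfg(mean_depth = 2000, subclonal_fraction = 0, gain_rate = 0,
                   wgd_probability = 0,
                   driver_snvs_per_sample = 40L, purity_range = c(0.6, 0.6),
                   passenger_snvs_per_sample = 0L, pathway_mutation_prob = 0)
  s <- simulate_sample(cfg, "typeA", "t1", seed = 9)
  stopifnot(all(s$truth$snvs$m_true == 1L))
  f_model <- expected_vaf(1, 0.6, 2)
  d <- s$bundle$snvs$ref_count + s$bundle$snvs$alt_count
  vaf <- sum(s$bundle$snvs$alt_count) / sum(d)
  se <- sqrt(f_model * (1 - f_model) / sum(d))
  expect_lt(abs(vaf - f_model), 3 * se)
})

test_that("planted pathway time distributions are recovered from truth", {
  cfg <- small_cfg(samples_per_type = 1L, cancer_types = "t",
                   pathway_mutation_prob = 1, pathway_snvs_per_event = 300L,
                   subclonal_fraction = 0, gain_rate = 0.8)
  tr <- simulate_sample(cfg, "t", "s1", seed = 5)$truth$snvs
  a <- tr$t_true[tr$origin == "antigen_presentation"]
  b <- tr$t_true[tr$origin == "tnf_signaling"]
  expect_gte(length(a), 300L)
  # placement onto covering forest edges must preserve the planted marginal
  expect_gt(stats::ks.test(a, function(q) pbeta(q, 2, 8))$p.value, 0.01)
  expect_gt(stats::ks.test(b, function(q) pbeta(q, 8, 2))$p.value, 0.01)
})

test_that("config validation names the offending pathway and bounds", {
  expect_error(small_cfg(pathway_gene_sets = list(
    antigen_presentation = character(0),
    tnf_signaling = "TNF")), "empty: antigen_presentation")
  expect_error(small_cfg(purity_range = c(0, 0.9)), "purity_range")
  expect_error(small_cfg(wgd_probability = 1.2), "wgd_probability")
  expect_error(small_cfg(pathway_gene_sets = list(only = "G")),
               "same pathways")
  # shared gene membership is allowed but recorded
  cfg <- small_cfg(
    pathway_gene_sets = list(a = c("G1", "G2"), b = c("G2", "G3")),
    pathway_time_distributions = list(a = list(dist = "uniform"),
                                      b = list(dist = "uniform")))
  expect_equal(cfg$shared_genes, "G2")
})

test_that("zero-depth resampling exhaustion is a hard error", {
  cfg <- small_cfg(mean_depth = 1e-9)
  expect_error(simulate_sample(cfg, "typeA", "t1", seed = 1),
               "zero-depth resampling exhausted")
})

test_that("gain posterior emitter: degenerate, Monte-Carlo and WGD invariants", {
  cfg <- small_cfg(wgd_probability = 1, gain_rate = 1.2)
  s <- simulate_sample(cfg, "typeA", "t1", seed = 11)
  # jitter 0: every draw equals truth
  g0 <- emit_gain_posterior(s$truth, 0, 8, seed = 2)
  truth_times <- do.call(c, unname(lapply(s$truth$forests, function(fr)
    stats::setNames(fr$nodes$time, fr$nodes$node_id))))
  expect_equal(g0$time, unname(truth_times[g0$node_id]), tolerance = 1e-12)
  # WGD simultaneity in every draw
  gj <- emit_gain_posterior(s$truth, 0.05, 50, seed = 3)
  for (dr in split(gj[gj$is_wgd, ], gj$draw[gj$is_wgd]))
    expect_lt(diff(range(dr$time)), 1e-12)
  # ancestral ordering preserved under jitter
  gps <- read_gain_posteriors(gj, s$bundle$segments)
  expect_true(all(vapply(gps[["t1"]], function(gp)
    all(gp$starts <= gp$ends + 1e-12), logical(1))))
})

test_that("truncated-normal emitter is unbiased for an interior gain time", {
  truth <- list(sample = "mc", wgd_time = NA_real_,
                forests = list(seg1 = list(
                  nodes = data.frame(node_id = "g1", parent_id = NA_character_,
                                     allele = "major", time = 0.3,
                                     is_wgd = FALSE, stringsAsFactors = FALSE),
                  cn = c(major = 2L, minor = 1L))))
  g <- emit_gain_posterior(truth, 0.05, 10000, seed = 21)
  expect_lt(abs(mean(g$time) - 0.3), 0.01)
  expect_true(all(g$time >= 0 & g$time <= 1))
})

test_that("cohort bundles are deterministic, counted, and truth-consistent", {
  cfg <- small_cfg(samples_per_type = 2L, draws_S = 15L,
                   pathway_time_distributions = list(
                     antigen_presentation = list(dist = "point", value = 0.1),
                     tnf_signaling = list(dist = "beta", shape1 = 8,
                                          shape2 = 2)),
                   pathway_mutation_prob = 1, subclonal_fraction = 0)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- simulate_cohort(cfg, d1)
  m2 <- simulate_cohort(cfg, d2)
  expect_equal(m1$n_samples, 4L)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  # manifest row counts match files on disk
  expect_equal(m1$files[["purity.tsv"]], 4L)
  expect_equal(nrow(read.delim(file.path(d1, "truth_samples.tsv"))), 4L)
  # point-mass early pathway sits below the uniform driver clock in truth
  tr <- read.delim(file.path(d1, "truth_snvs.tsv"))
  expect_lt(mean(tr$t_true[tr$origin == "antigen_presentation"]),
            mean(tr$t_true[tr$origin == "driver"]))
  # partial-write marker blocks accidental reuse
  file.create(file.path(d1, ".incomplete"))
  expect_error(simulate_cohort(cfg, d1), "partial bundle")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the minimal VCF dialect round-trips the SNV table", {
  s <- simulate_sample(small_cfg(), "typeA", "t1", seed = 2)
  p <- tempfile(fileext = ".vcf")
  write_snv_vcf(s$bundle$snvs, p)
  back <- read_snv_vcf(p)
  expect_equal(back, s$bundle$snvs[, names(back)])
})
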