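# Hierarchical SNV timing: multiplicity posterior, draw sampling, recovery.

test_that("expected_vaf rejects impossible multiplicities and handles CCF", {
  expect_equal(expected_vaf(2, 1.0, 2), 1.0)
  expect_error(expected_vaf(3, 0.5, 2), "impossible multiplicity")
  expect_error(expected_vaf(NULL, 0.5, 2, ccf = 1.2), "ccf")
})

test_that("multiplicity posterior matches brute-force enumeration", {
  # strong doubled signal: CN (2,1), pure tumor, VAF ~ f(2)
  f21 <- forest_21(0.3)
  mp <- multiplicity_posterior(667, 1000, f21, rho = 1)
  expect_gt(mp$posterior[mp$state == "2"], 0.99)
  or <- oracle_mult_posterior(667, 1000, f21, rho = 1)
  expect_equal(stats::setNames(mp$posterior, mp$state), or, tolerance = 1e-12)

  # low-VAF SNV on diploid: subclonal state is modal
  f11 <- copy_forest(NULL, 1, 1)
  mp2 <- multiplicity_posterior(40, 200, f11, rho = 1, subclonal_ccf = 0.4)
  expect_equal(mp2$state[which.max(mp2$posterior)], "SUBCLONAL")
  or2 <- oracle_mult_posterior(40, 200, f11, rho = 1, subclonal_ccf = 0.4)
  expect_equal(stats::setNames(mp2$posterior, mp2$state), or2,
               tolerance = 1e-12)

  # a = 0 stays valid and shifts mass to the lowest-VAF state
  mp0 <- multiplicity_posterior(0, 100, f21, rho = 1, subclonal_ccf = 0.3)
  expect_equal(mp0$state[which.max(mp0$posterior)], "SUBCLONAL")
  mp0c <- multiplicity_posterior(0, 100, f21, rho = 1)
  expect_equal(mp0c$state[which.max(mp0c$posterior)], "1")
  expect_equal(sum(mp0$posterior), 1)
})

test_that("ungained diploid segments yield uniform timing draws", {
  gp <- gain_posterior(NULL, matrix(numeric(0), 0, 1), 1, 1, "dip")
  r <- sample_snv_timing(35, 100, gp, rho = 0.7, S = 250, seed = 5)
  expect_equal(r$clonal_fraction, 1)
  expect_lt(abs(mean(r$draws) - 0.5), 0.09) # 3 sigma of mean of 250 uniforms
  big <- sample_snv_timing(35, 100, gp, rho = 0.7, S = 10000, seed = 6)
  expect_gt(stats::ks.test(big$draws, "punif")$p.value, 0.01)
})

test_that("draws respect their sampled multiplicity's edge intervals", {
  gp <- gp_fixed(forest_21(0.3), S = 400L)
  r <- sample_snv_timing(55, 100, gp, rho = 1, S = 400, seed = 8,
                         subclonal_ccf = 0.5)
  expect_true(all(r$draws[!is.na(r$multiplicity) & r$multiplicity == 2] < 0.3))
  e <- gp$edges
  cl <- which(!is.na(r$multiplicity))
  expect_true(all(e$leaf_count[r$edge[cl]] == r$multiplicity[cl]))
  expect_true(all(r$draws[cl] >= e$t_start[r$edge[cl]] - 1e-12 &
                    r$draws[cl] <= e$t_end[r$edge[cl]] + 1e-12))
  expect_true(all(r$draws[is.na(r$multiplicity)] == SUBCLONAL_TIME))
  # determinism under a fixed seed
  r2 <- sample_snv_timing(55, 100, gp, rho = 1, S = 400, seed = 8,
                          subclonal_ccf = 0.5)
  expect_identical(r, r2)
})

test_that("WGD segment with doubled-VAF SNV concentrates before the WGD", {
  gp <- gp_fixed(forest_22_wgd(0.4), S = 2000L)
  r <- sample_snv_timing(1000, 2000, gp, rho = 1, S = 2000, seed = 9)
  expect_gte(mean(r$draws < 0.4), 0.99)
})

test_that("posterior sd shrinks with depth on average", {
  gp <- gp_fixed(forest_21(0.35), S = 250L)
  # common random numbers: each simulated SNV keeps its multiplicity and
  # binomial quantile across depths, so the depth comparison is paired
  mean_sd <- vapply(c(30, 100, 300), function(d) {
    sds <- vapply(1:50, function(i) {
      set.seed(1000 + i)
      m <- sample(c(1, 2), 1)
      a <- qbinom(runif(1), d, expected_vaf(m, 1, 3))
      r <- sample_snv_timing(a, d, gp, rho = 1, S = 250,
                             seed = derive_seed(77, i))
      sd(r$draws)
    }, numeric(1))
    mean(sds)
  }, numeric(1))
  expect_true(all(diff(mean_sd) <= 0))
})

test_that("time_all_snvs is deterministic and row-order invariant", {
  cfg <- small_cfg(draws_S = 25L)
  s <- simulate_sample(cfg, "typeA", "t1", seed = 14)
  g <- emit_gain_posterior(s$truth, 0.02, 25, seed = 15)
  gps <- read_gain_posteriors(g, s$bundle$segments)
  r1 <- time_all_snvs(s$bundle$snvs, s$bundle$segments, gps, s$bundle$purity,
                      S = 25, seed = 3)
  r2 <- time_all_snvs(s$bundle$snvs, s$bundle$segments, gps, s$bundle$purity,
                      S = 25, seed = 3)
  expect_identical(r1, r2)
  perm <- rev(seq_len(nrow(s$bundle$snvs)))
  r3 <- time_all_snvs(s$bundle$snvs[perm, ], s$bundle$segments, gps,
                      s$bundle$purity, S = 25, seed = 3)
  expect_equal(r3$draws, r1$draws[perm, ])
  # SNV outside any segment is untimed, not fatal
  orphan <- s$bundle$snvs[1, ]
  orphan$chrom <- "chrZ"
  r4 <- time_all_snvs(rbind(orphan, s$bundle$snvs), s$bundle$segments, gps,
                      s$bundle$purity, S = 25, seed = 3)
  expect_false(r4$timing$timed[1])
  expect_true(all(is.na(r4$draws[1, ])))
})

test_that("posterior means recover true times on gained segments", {
  cfg <- small_cfg(cancer_types = "t", samples_per_type = 8L,
                   driver_snvs_per_sample = 60L, n_segments = 10L,
                   gain_rate = 2, max_gains_per_segment = 2L,
                   wgd_probability = 0.5, subclonal_fraction = 0,
                   passenger_snvs_per_sample = 0L, pathway_mutation_prob = 0,
                   mean_depth = 100, draws_S = 100L)
  cor_pool <- t_pool <- numeric(0)
  for (i in 1:8) {
    sid <- paste0("s", i)
    s <- simulate_sample(cfg, "t", sid, seed = 100 + i)
    g <- emit_gain_posterior(s$truth, 0.02, 100, seed = 200 + i)
    gps <- read_gain_posteriors(g, s$bundle$segments)
    r <- time_all_snvs(s$bundle$snvs, s$bundle$segments, gps, s$bundle$purity,
                       S = 100, seed = 300 + i)
    gained <- r$timing$n_t > 2
    cor_pool <- c(cor_pool, r$timing$mean_time_clonal[gained])
    t_pool <- c(t_pool, s$truth$snvs$t_true[gained])
  }
  expect_gte(length(cor_pool), 300L)
  expect_gt(stats::cor(cor_pool, t_pool, use = "complete.obs"), 0.6)
})

test_that("truth-subclonal SNVs are flagged subclonal in the posterior", {
  cfg <- small_cfg(cancer_types = "t", samples_per_type = 4L,
                   subclonal_fraction = 1, subclonal_ccf_range = c(0.2, 0.5),
                   mean_depth = 200, driver_snvs_per_sample = 30L,
                   passenger_snvs_per_sample = 0L, pathway_mutation_prob = 0,
                   draws_S = 60L)
  frac <- numeric(0)
  for (i in 1:4) {
    s <- simulate_sample(cfg, "t", paste0("s", i), seed = 400 + i)
    g <- emit_gain_posterior(s$truth, 0.02, 60, seed = 500 + i)
    gps <- read_gain_posteriors(g, s$bundle$segments)
    r <- time_all_snvs(s$bundle$snvs, s$bundle$segments, gps, s$bundle$purity,
                       S = 60, seed = 600 + i)
    frac <- c(frac, r$timing$clonal_fraction)
  }
  expect_gte(mean(frac < 0.2), 0.9)
})

test_that("timing tables round-trip through the TSV writer", {
  cfg <- small_cfg(draws_S = 10L)
  s <- simulate_sample(cfg, "typeA", "t1", seed = 1)
  g <- emit_gain_posterior(s$truth, 0, 10, seed = 2)
  gps <- read_gain_posteriors(g, s$bundle$segments)
  r <- time_all_snvs(s$bundle$snvs, s$bundle$segments, gps, s$bundle$purity,
                     S = 10, seed = 3)
  p <- tempfile(fileext = ".tsv")
  write_timing(r, p)
  back <- read_timing(p)
  expect_equal(back$draws, r$draws)
  expect_equal(back$timing$mean_time, r$timing$mean_time)
})
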