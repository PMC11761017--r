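# Background clock, early/late calls, timeline ratios, strata export.

const_draws <- function(vals, S = 250L) {
  matrix(rep(vals, each = S), length(vals), S, byrow = TRUE)
}

test_that("background clock is the per-draw mean of driver SNV draws", {
  one <- matrix(runif(250), 1)
  expect_equal(background_timing(one)$B, drop(one))
  two <- const_draws(c(0.2, 0.6))
  expect_equal(background_timing(two)$B, rep(0.4, 250))
  # linearity: shifting every SNV draw shifts the clock by the same constant
  expect_equal(background_timing(two + 0.05)$B,
               background_timing(two)$B + 0.05)
  expect_error(background_timing(matrix(numeric(0), 0, 10)), "at least one")
})

test_that("the 60% rule uses strict inequalities on draw fractions", {
  S <- 250L
  clock <- background_timing(matrix(0.5, 1, S))
  # 160/250 = 64% negative -> early
  ev <- matrix(c(rep(0.4, 160), rep(0.6, 90)), 1)
  expect_equal(classify_event(ev, clock)$label, "early")
  # 150/250 = exactly 60% negative, rest positive -> undetermined
  ev2 <- matrix(c(rep(0.4, 150), rep(0.6, 100)), 1)
  cl2 <- classify_event(ev2, clock)
  expect_equal(cl2$frac_early, 0.6)
  expect_equal(cl2$label, "undetermined")
  # event identical to clock: all deltas zero, ties count to neither
  cl3 <- classify_event(matrix(0.5, 1, S), clock)
  expect_equal(cl3$frac_early + cl3$frac_late, 0)
  expect_equal(cl3$label, "undetermined")
})

test_that("classification is shift-invariant and sign-symmetric", {
  set.seed(99)
  S <- 200L
  drivers <- matrix(runif(3 * S), 3)
  event <- matrix(runif(2 * S), 2)
  clock <- background_timing(drivers)
  base <- classify_event(event, clock)
  shifted <- classify_event(event + 0.13, background_timing(drivers + 0.13))
  expect_equal(shifted$delta, base$delta)
  expect_equal(shifted$label, base$label)
  # swapping event and clock negates every delta and swaps the fractions
  swapped <- classify_event(drivers, background_timing(event))
  expect_equal(swapped$delta, -base$delta)
  expect_equal(swapped$frac_early, base$frac_late)
  expect_equal(swapped$frac_late, base$frac_early)
})

test_that("timeline ratio arithmetic and eligibility match the stated rules", {
  mk_calls <- function(n_early, n_late, n_und = 0) {
    data.frame(sample = paste0("s", seq_len(n_early + n_late + n_und)),
               cancer_type = "ct", event = "ev", event_type = "pathway",
               n_snvs = 1, frac_early = 0, frac_late = 0,
               label = c(rep("early", n_early), rep("late", n_late),
                         rep("undetermined", n_und)))
  }
  t1 <- aggregate_timeline(mk_calls(9, 1))
  expect_equal(t1$ratio, 0.2)
  expect_equal(t1$label, "early")
  t2 <- aggregate_timeline(mk_calls(4, 9))
  expect_equal(t2$ratio, 2.0)
  expect_equal(t2$label, "undetermined") # strict "> 2"
  t3 <- aggregate_timeline(mk_calls(0, 0, 3))
  expect_false(t3$eligible)
  expect_true(is.na(t3$label))
  # threshold override changes eligibility
  t4 <- aggregate_timeline(mk_calls(2, 1), min_samples = 3)
  expect_true(t4$eligible)
})

test_that("strata lists are disjoint and empty for undetermined-only groups", {
  calls <- data.frame(
    sample = c("s1", "s2", "s3", "s4"), cancer_type = "ct",
    event = c("ev", "ev", "ev", "other"), event_type = "pathway", n_snvs = 1,
    frac_early = 0, frac_late = 0,
    label = c("early", "late", "early", "undetermined"))
  st <- timing_strata_export(calls)
  expect_setequal(st$ct$ev$early, c("s1", "s3"))
  expect_equal(st$ct$ev$late, "s2")
  expect_length(intersect(st$ct$ev$early, st$ct$ev$late), 0)
  expect_length(st$ct$other$early, 0)
  expect_length(st$ct$other$late, 0)
})

test_that("build_event_calls pools pathway SNVs and excludes self-background", {
  S <- 100L
  timing <- data.frame(
    sample = "s1", cancer_type = "ct",
    gene = c("TP53", "KRAS", "B2M", "TAP1"),
    timed = TRUE, clonal_fraction = 1)
  # TP53 and KRAS are drivers; B2M/TAP1 form a pathway planted early
  draws <- rbind(matrix(0.5, 1, S), matrix(0.7, 1, S),
                 matrix(0.1, 1, S), matrix(0.2, 1, S))
  res <- build_event_calls(list(timing = timing, draws = draws),
                           drivers = c("TP53", "KRAS"),
                           gene_sets = list(apm = c("B2M", "TAP1")))
  apm <- res[res$event == "apm", ]
  expect_equal(apm$n_snvs, 2L)
  expect_equal(apm$label, "early") # 0.15 vs clock 0.6
  # with exclude_self, TP53 (0.5) is compared to KRAS alone (0.7) -> early
  expect_equal(res$label[res$event == "TP53"], "early")
  # without exclusion it is compared to mean(0.5, 0.7) = 0.6 -> still early
  res2 <- build_event_calls(list(timing = timing, draws = draws),
                            drivers = c("TP53", "KRAS"),
                            gene_sets = list(apm = c("B2M", "TAP1")),
                            exclude_self = FALSE)
  expect_equal(res2$label[res2$event == "TP53"], "early")
  # samples with no driver SNVs are excluded and reported
  timing2 <- timing
  timing2$gene <- c("GENEX", "GENEY", "B2M", "TAP1")
  res3 <- build_event_calls(list(timing = timing2, draws = draws),
                            drivers = c("TP53", "KRAS"),
                            gene_sets = list(apm = c("B2M", "TAP1")))
  expect_equal(nrow(res3), 0L)
  expect_equal(attr(res3, "excluded_samples"), "s1")
})

test_that("subclonal sentinel handling follows the include_subclonal switch", {
  S <- 50L
  timing <- data.frame(sample = "s1", cancer_type = "ct",
                       gene = c("TP53", "B2M", "TAP1"),
                       timed = TRUE, clonal_fraction = c(1, 1, 0))
  draws <- rbind(matrix(0.5, 1, S), matrix(0.2, 1, S),
                 matrix(SUBCLONAL_TIME, 1, S))
  with_sub <- build_event_calls(list(timing = timing, draws = draws),
                                drivers = "TP53",
                                gene_sets = list(apm = c("B2M", "TAP1")))
  # mean(0.2, 1.01) = 0.605 > 0.5 -> late when sentinels count
  expect_equal(with_sub$label[with_sub$event == "apm"], "late")
  no_sub <- build_event_calls(list(timing = timing, draws = draws),
                              drivers = "TP53",
                              gene_sets = list(apm = c("B2M", "TAP1")),
                              include_subclonal = FALSE)
  expect_equal(no_sub$label[no_sub$event == "apm"], "early")
})
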