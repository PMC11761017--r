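# HLA loss-of-heterozygosity calls from allelic-imbalance summaries, and
# timing of LOH relative to whole-genome doubling (WGD).
#
# Call rule: allelic imbalance (AI) when the AI p-value is below 0.01; LOH
# when additionally the minor-allele copy number is below 0.5. Timing rule:
# in a WGD tumor, an LOH with minor copy number 0 and major copy number
# above 1 must predate the WGD (the lost allele is unlikely to be lost
# twice), so its time is uniform on (0, t_WGD) per paired WGD draw; all
# other configurations are left undetermined (losses cannot be timed
# quantitatively without a WGD reference clock).

#' Call HLA allelic imbalance and LOH
#'
#' @param ai_p_value AI p-value(s) in [0, 1].
#' @param minor_cn Minor-allele copy number(s), nonnegative real.
#' @param p_threshold AI significance threshold (default 0.01).
#' @param minor_cn_threshold LOH minor-CN threshold (default 0.5).
#' @return data.frame with logical `is_AI`, `is_LOH` (NA where inputs are
#'   missing; such rows are no-calls).
#' @export
call_hla_loh <- function(ai_p_value, minor_cn, p_threshold = 0.01,
                         minor_cn_threshold = 0.5) {
  stopifnot(length(ai_p_value) == length(minor_cn))
  bad <- !is.na(ai_p_value) & (ai_p_value < 0 | ai_p_value > 1)
  if (any(bad)) stop("ai_p_value outside [0,1]")
  if (any(!is.na(minor_cn) & minor_cn < 0)) stop("negative minor_cn")
  is_AI <- ai_p_value < p_threshold
  is_LOH <- is_AI & minor_cn < minor_cn_threshold
  n_nocall <- sum(is.na(is_AI) | is.na(is_LOH))
  if (n_nocall) warning(n_nocall, " row(s) with missing values left as no-calls")
  data.frame(is_AI = is_AI, is_LOH = is_LOH)
}

#' Time one HLA LOH event relative to WGD
#'
#' @param minor_cn,major_cn LOH copy numbers (the event must already be an
#'   LOH call).
#' @param wgd_draws Numeric vector of S WGD-time draws, or NULL for a
#'   non-WGD sample.
#' @param S Number of timing draws (defaults to `length(wgd_draws)`);
#'   LOH draw s pairs with WGD draw s (recycled if needed).
#' @param minor_zero_tol Tolerance for "minor copy number equal to 0" on
#'   real-valued estimates (default 0.05).
#' @param major_gt_one Threshold for "major copy number greater than 1" on
#'   real-valued estimates (default 1.5; use 1 for integer calls).
#' @param seed Optional integer for reproducible draws.
#' @return List with `status` ("pre_wgd" or "undetermined") and `draws`
#'   (length S, each <= its paired WGD draw; empty when undetermined).
#' @export
time_loh_vs_wgd <- function(minor_cn, major_cn, wgd_draws,
                            S = if (is.null(wgd_draws)) 0L else length(wgd_draws),
                            minor_zero_tol = 0.05, major_gt_one = 1.5,
                            seed = NULL) {
  if (is.null(wgd_draws))
    return(list(status = "undetermined", draws = numeric(0)))
  if (!length(wgd_draws)) stop("WGD-flagged sample has no WGD draws")
  if (!(minor_cn < minor_zero_tol && major_cn > major_gt_one))
    return(list(status = "undetermined", draws = numeric(0)))
  wt <- wgd_draws[((seq_len(S) - 1L) %% length(wgd_draws)) + 1L]
  run <- function() stats::runif(S, 0, wt)
  draws <- if (is.null(seed)) run() else with_seed(seed, run())
  list(status = "pre_wgd", draws = draws)
}

#' Call and time HLA LOH for a whole cohort table
#'
#' @param hla data.frame with `sample`, `hla_gene`, `ai_p_value`,
#'   `minor_cn`, `major_cn` (the HLA TSV dialect; a path is accepted).
#' @param wgd_times Named list of per-sample WGD draw vectors (NULL entries
#'   for non-WGD samples), e.g. `attr(read_gain_posteriors(...), "wgd_times")`.
#' @param S Timing draws per event (default 250).
#' @param seed Cohort seed; per-event substreams derived from
#'   (sample, hla_gene).
#' @param ... Thresholds passed to [call_hla_loh()] and [time_loh_vs_wgd()].
#' @return List with `calls` (input plus `is_AI`, `is_LOH`, `status`,
#'   `mean_time`) and `draws` (matrix rows = LOH rows of `calls`, NA rows
#'   where undetermined).
#' @export
time_all_hla_loh <- function(hla, wgd_times, S = 250L, seed = 1L, ...) {
  if (is.character(hla))
    hla <- read_tsv_strict(hla, c("sample", "hla_gene", "ai_p_value",
                                  "minor_cn", "major_cn"))
  hla <- as.data.frame(hla, stringsAsFactors = FALSE)
  dots <- list(...)
  cl <- call_hla_loh(hla$ai_p_value, hla$minor_cn,
                     p_threshold = dots$p_threshold %||% 0.01,
                     minor_cn_threshold = dots$minor_cn_threshold %||% 0.5)
  hla$is_AI <- cl$is_AI
  hla$is_LOH <- cl$is_LOH
  hla$status <- "not_loh"
  hla$mean_time <- NA_real_
  draws <- matrix(NA_real_, nrow(hla), S)
  for (i in which(!is.na(hla$is_LOH) & hla$is_LOH)) {
    smp <- hla$sample[i]
    res <- time_loh_vs_wgd(hla$minor_cn[i], hla$major_cn[i],
                           wgd_draws = wgd_times[[smp]], S = S,
                           minor_zero_tol = dots$minor_zero_tol %||% 0.05,
                           major_gt_one = dots$major_gt_one %||% 1.5,
                           seed = derive_seed(seed, smp, hla$hla_gene[i], "loh"))
    hla$status[i] <- res$status
    if (res$status == "pre_wgd") {
      draws[i, ] <- res$draws
      hla$mean_time[i] <- mean(res$draws)
    }
  }
  list(calls = hla, draws = draws)
}
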