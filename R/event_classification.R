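# Early/late classification of mutation events against a per-sample
# driver-gene background clock, and cancer-type-level timeline aggregation.
#
# Background clock: B_s = mean over the sample's driver-gene SNVs of their
# draw-s timing values. An event (a driver gene or a pathway gene set) has
# per-draw mean E_s over its SNVs; the relative timing draws are
# Delta_s = E_s - B_s. A patient-level event is "early" when more than 60%
# of draws have Delta_s < 0, "late" when more than 60% have Delta_s > 0,
# otherwise "undetermined". At the cancer-type level the smoothed ratio
# R = (n_late + 1) / (n_early + 1) labels the event early when R < 0.5 and
# late when R > 2, among events with at least five determined samples.

#' Per-sample background timing from driver-gene SNVs
#'
#' @param driver_draws Numeric matrix, one row per driver-gene SNV of the
#'   sample, one column per draw (1.01 subclonal sentinels included as
#'   values unless the caller filtered them).
#' @return List (`background_clock`) with `B` (per-draw means, length S) and
#'   `n_driver_snvs`.
#' @export
background_timing <- function(driver_draws) {
  driver_draws <- rbind(driver_draws)
  if (nrow(driver_draws) < 1L)
    stop("background timing needs at least one timed driver SNV")
  structure(list(B = colMeans(driver_draws), n_driver_snvs = nrow(driver_draws)),
            class = "background_clock")
}

#' Classify one event in one sample as early / late / undetermined
#'
#' @param event_draws Numeric matrix, one row per SNV of the event, one
#'   column per draw.
#' @param clock A `background_clock` for the same sample (same S).
#' @param frac_threshold Fraction of draws that must agree (default 0.6,
#'   strict inequality).
#' @return List with `delta` (Delta_s vector), `frac_early`, `frac_late`
#'   (ties at exactly 0 count to neither), `label`.
#' @export
classify_event <- function(event_draws, clock, frac_threshold = 0.6) {
  stopifnot(inherits(clock, "background_clock"))
  event_draws <- rbind(event_draws)
  if (ncol(event_draws) != length(clock$B))
    stop("event and clock draw counts differ")
  delta <- colMeans(event_draws) - clock$B
  frac_early <- mean(delta < 0)
  frac_late <- mean(delta > 0)
  label <- if (frac_early > frac_threshold) "early"
           else if (frac_late > frac_threshold) "late"
           else "undetermined"
  list(delta = delta, frac_early = frac_early, frac_late = frac_late,
       label = label)
}

#' Build per-sample event calls for a cohort timing result
#'
#' Events are the individual driver genes plus each pathway gene set
#' (pooling all timed SNVs in the set's genes). Only timed SNVs contribute;
#' samples without any timed driver SNV are excluded (and counted).
#'
#' @param timing_result Output of [time_all_snvs()] (needs `timing$sample`,
#'   `timing$gene`, `timing$cancer_type` if present, `timing$timed`, and
#'   `draws`). Rows failing the non-synonymous filter should be removed
#'   beforehand if desired.
#' @param drivers Character vector of driver gene symbols.
#' @param gene_sets Named list of pathway gene vectors.
#' @param cancer_types Optional data.frame `sample`, `cancer_type`; if
#'   absent a `cancer_type` column on `timing` is used, else "all".
#' @param frac_threshold See [classify_event()].
#' @param exclude_self When TRUE (default) a driver-gene event's own SNVs
#'   are excluded from its background clock; when FALSE the clock always
#'   uses all driver SNVs.
#' @param include_subclonal When TRUE (default) 1.01 sentinels enter the
#'   per-draw means verbatim; when FALSE subclonal-majority SNV rows
#'   (clonal_fraction < 0.5) are dropped before averaging.
#' @return data.frame of calls: `sample`, `cancer_type`, `event`,
#'   `event_type` ("gene"/"pathway"), `n_snvs`, `frac_early`, `frac_late`,
#'   `label`. Attribute `excluded_samples` lists samples without driver SNVs.
#' @export
build_event_calls <- function(timing_result, drivers, gene_sets,
                              cancer_types = NULL, frac_threshold = 0.6,
                              exclude_self = TRUE, include_subclonal = TRUE) {
  tm <- timing_result$timing
  dr <- timing_result$draws
  keep <- tm$timed
  if (!include_subclonal) keep <- keep & tm$clonal_fraction >= 0.5
  tm <- tm[keep, , drop = FALSE]
  dr <- dr[keep, , drop = FALSE]
  ct <- function(smp) {
    if (!is.null(cancer_types))
      return(cancer_types$cancer_type[match(smp, cancer_types$sample)])
    if ("cancer_type" %in% names(tm))
      return(tm$cancer_type[match(smp, tm$sample)])
    "all"
  }
  match_gene <- function(g, set) tolower(trimws(g)) %in% tolower(trimws(set))
  calls <- list()
  excluded <- character(0)
  for (smp in unique(tm$sample)) {
    rows <- which(tm$sample == smp)
    is_drv <- match_gene(tm$gene[rows], drivers)
    if (!any(is_drv)) {
      excluded <- c(excluded, smp)
      next
    }
    drv_rows <- rows[is_drv]
    clock_all <- background_timing(dr[drv_rows, , drop = FALSE])
    events <- c(stats::setNames(as.list(drivers), drivers),
                lapply(gene_sets, identity))
    types <- c(rep("gene", length(drivers)), rep("pathway", length(gene_sets)))
    names(types) <- c(drivers, names(gene_sets))
    for (ev in names(events)) {
      ev_rows <- rows[match_gene(tm$gene[rows], events[[ev]])]
      if (!length(ev_rows)) next
      clock <- clock_all
      if (exclude_self && types[[ev]] == "gene") {
        bg_rows <- setdiff(drv_rows, ev_rows)
        if (!length(bg_rows)) next # no background left for this event
        clock <- background_timing(dr[bg_rows, , drop = FALSE])
      }
      cl <- classify_event(dr[ev_rows, , drop = FALSE], clock,
                           frac_threshold = frac_threshold)
      calls[[length(calls) + 1L]] <- data.frame(
        sample = smp, cancer_type = ct(smp), event = ev,
        event_type = types[[ev]], n_snvs = length(ev_rows),
        frac_early = cl$frac_early, frac_late = cl$frac_late,
        label = cl$label, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(sample = character(), cancer_type = character(),
                         event = character(), event_type = character(),
                         n_snvs = integer(), frac_early = numeric(),
                         frac_late = numeric(), label = character())
  attr(out, "excluded_samples") <- excluded
  out
}

#' Aggregate per-sample calls into a cancer-type timeline
#'
#' @param calls data.frame from [build_event_calls()].
#' @param min_samples Minimum determined (early or late) samples for an
#'   event to be labeled (default 5).
#' @param early_ratio,late_ratio Cutoffs on R = (n_late+1)/(n_early+1)
#'   (defaults 0.5 and 2; strict inequalities).
#' @return data.frame: `cancer_type`, `event`, `n_early`, `n_late`,
#'   `n_undetermined`, `ratio`, `eligible`, `label` (NA when ineligible).
#' @export
aggregate_timeline <- function(calls, min_samples = 5, early_ratio = 0.5,
                               late_ratio = 2) {
  if (!nrow(calls))
    return(data.frame(cancer_type = character(), event = character(),
                      n_early = integer(), n_late = integer(),
                      n_undetermined = integer(), ratio = numeric(),
                      eligible = logical(), label = character()))
  sp <- split(calls, list(calls$cancer_type, calls$event), drop = TRUE)
  rows <- lapply(sp, function(g) {
    n_early <- sum(g$label == "early")
    n_late <- sum(g$label == "late")
    ratio <- (n_late + 1) / (n_early + 1)
    eligible <- (n_early + n_late) >= min_samples
    label <- if (!eligible) NA_character_
             else if (ratio < early_ratio) "early"
             else if (ratio > late_ratio) "late"
             else "undetermined"
    data.frame(cancer_type = g$cancer_type[1L], event = g$event[1L],
               n_early = n_early, n_late = n_late,
               n_undetermined = sum(g$label == "undetermined"),
               ratio = ratio, eligible = eligible, label = label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cancer_type, out$event), , drop = FALSE]
}

#' Export early/late sample strata per (cancer type, event)
#'
#' Produces the disjoint sample lists downstream expression comparisons
#' consume (the comparison itself is out of scope here).
#'
#' @param calls data.frame from [build_event_calls()].
#' @return Nested named list: `[[cancer_type]][[event]]$early` / `$late`.
#' @export
timing_strata_export <- function(calls) {
  out <- list()
  if (!nrow(calls)) return(out)
  for (g in split(calls, list(calls$cancer_type, calls$event), drop = TRUE)) {
    ctype <- g$cancer_type[1L]; ev <- g$event[1L]
    out[[ctype]][[ev]] <- list(
      early = sort(unique(g$sample[g$label == "early"])),
      late = sort(unique(g$sample[g$label == "late"])))
  }
  out
}
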