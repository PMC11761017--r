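# Per-segment posterior over gain histories: one shared topology, S draws of
# gain-event times (the upstream gain-timing tool emits time uncertainty;
# route/topology uncertainty is out of scope and documented as such).

#' Construct a gain posterior for one segment
#'
#' @param nodes Gain-node topology (as in [copy_forest()]); 0 rows for an
#'   ungained segment.
#' @param times Numeric matrix, `nrow(nodes)` x S: node times per draw, rows
#'   in `nodes` order. For an ungained segment use a 0 x S matrix.
#' @param major,minor Final allele-specific copy numbers.
#' @param segment_id Segment label.
#' @return A `gain_posterior`: the validated draw-1 `copy_forest` plus
#'   per-draw edge geometry (`starts`, `ends`, `lengths`, all n_edges x S),
#'   multiplicity classes and their per-draw total lengths (`classes`,
#'   `len_by_m`), the WGD time per draw (`wgd_times`, NULL if no WGD node),
#'   and `S`.
#' @export
gain_posterior <- function(nodes, times, major, minor, segment_id = "segment") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  times <- as.matrix(times)
  if (nrow(nodes) != nrow(times))
    stop("segment ", segment_id, ": times matrix has ", nrow(times),
         " rows for ", nrow(nodes), " gain nodes")
  S <- ncol(times)
  if (nrow(nodes) > 0L && S < 1L) stop("need at least one draw")
  if (nrow(nodes) == 0L && S == 0L) S <- 1L # ungained segment: draws trivial
  nd1 <- nodes
  if (nrow(nd1) > 0L) nd1$time <- times[, 1L]
  forest <- copy_forest(nd1, major = major, minor = minor,
                        segment_id = segment_id)
  e <- forest$edges
  end_idx <- ifelse(e$is_leaf, NA_integer_, match(e$node_id, nodes$node_id))
  start_idx <- match(e$parent_id, nodes$node_id) # NA -> root, starts at 0
  ends <- matrix(1, nrow(e), S)
  ok <- !is.na(end_idx)
  ends[ok, ] <- times[end_idx[ok], , drop = FALSE]
  starts <- matrix(0, nrow(e), S)
  ok <- !is.na(start_idx)
  starts[ok, ] <- times[start_idx[ok], , drop = FALSE]
  if (any(starts > ends + 1e-12))
    stop("segment ", segment_id, ": a draw violates parent<=child time ordering")
  lengths <- pmax(ends - starts, 0)
  classes <- sort(unique(e$leaf_count))
  len_by_m <- t(vapply(classes, function(m)
    colSums(lengths[e$leaf_count == m, , drop = FALSE]), numeric(S)))
  wgd_times <- NULL
  if (any(nodes$is_wgd %||% logical(0))) {
    wrow <- which(nodes$is_wgd)
    wgd_times <- times[wrow[1L], ]
    if (length(wrow) > 1L &&
        any(abs(sweep(times[wrow, , drop = FALSE], 2, wgd_times)) > 1e-9))
      stop("segment ", segment_id, ": WGD nodes disagree on time within a draw")
  }
  structure(list(segment_id = segment_id, nodes = nodes, times = times,
                 forest = forest, edges = e, S = S,
                 starts = starts, ends = ends, lengths = lengths,
                 classes = classes, len_by_m = len_by_m,
                 wgd_times = wgd_times,
                 major = forest$major, minor = forest$minor),
            class = "gain_posterior")
}

#' Extract one posterior draw as a copy forest
#'
#' @param gp A `gain_posterior`.
#' @param s Draw index in 1..S.
#' @return A `copy_forest` with that draw's node times.
#' @export
forest_draw <- function(gp, s) {
  stopifnot(inherits(gp, "gain_posterior"), s >= 1, s <= gp$S)
  nd <- gp$nodes
  if (nrow(nd) > 0L) nd$time <- gp$times[, s]
  copy_forest(nd, gp$major, gp$minor, gp$segment_id)
}

#' @export
print.gain_posterior <- function(x, ...) {
  cat("gain_posterior", x$segment_id, sprintf("CN (%d,%d)", x$major, x$minor),
      "-", nrow(x$nodes), "gain node(s),", x$S, "draws\n")
  invisible(x)
}

#' Read per-sample gain posteriors from the long TSV dialect
#'
#' The dialect has one row per (sample, segment, draw, node):
#' `sample`, `segment_id`, `draw`, `node_id`, `parent_id`, `allele`, `time`,
#' `is_wgd`. Extra columns are tolerated. Segments absent from the gains
#' table but present in `segments` are included as ungained forests (their
#' CN must then be (1,1)).
#'
#' @param gains Path to the gains TSV, or an equivalent data.frame.
#' @param segments data.frame with `sample`, `segment_id`, `major`, `minor`
#'   (the segments TSV).
#' @return Named list (by sample) of named lists (by segment_id) of
#'   `gain_posterior` objects, with per-sample WGD simultaneity validated.
#'   Attribute `wgd_times` holds a named list of per-sample WGD draw vectors
#'   (NULL entries for non-WGD samples).
#' @export
read_gain_posteriors <- function(gains, segments) {
  if (is.character(gains))
    gains <- read_tsv_strict(gains, c("sample", "segment_id", "draw",
                                      "node_id", "parent_id", "allele",
                                      "time", "is_wgd"))
  gains <- as.data.frame(gains, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  out <- list()
  wgd_out <- list()
  for (smp in unique(segments$sample)) {
    seg_s <- segments[segments$sample == smp, , drop = FALSE]
    g_s <- gains[gains$sample == smp, , drop = FALSE]
    S <- if (nrow(g_s)) max(g_s$draw) else 1L
    gps <- list()
    for (i in seq_len(nrow(seg_s))) {
      sid <- seg_s$segment_id[i]
      g <- g_s[g_s$segment_id == sid, , drop = FALSE]
      if (nrow(g) == 0L) {
        gps[[sid]] <- gain_posterior(NULL, matrix(numeric(0), 0, S),
                                     seg_s$major[i], seg_s$minor[i], sid)
        next
      }
      nodes <- unique(g[, c("node_id", "parent_id", "allele", "is_wgd")])
      nodes$parent_id[nodes$parent_id %in% c("", "NA")] <- NA_character_
      d1 <- g[g$draw == 1L, ]
      nodes <- nodes[match(d1$node_id, nodes$node_id), , drop = FALSE]
      tm <- matrix(NA_real_, nrow(nodes), S)
      idx <- match(g$node_id, nodes$node_id)
      tm[cbind(idx, g$draw)] <- g$time
      if (anyNA(tm))
        stop("sample ", smp, " segment ", sid,
             ": incomplete draws in gain posterior table")
      nodes$time <- tm[, 1L]
      gps[[sid]] <- gain_posterior(nodes, tm, seg_s$major[i], seg_s$minor[i], sid)
    }
    # WGD simultaneity across segments within each draw
    wt <- Filter(Negate(is.null), lapply(gps, `[[`, "wgd_times"))
    if (length(wt)) {
      ref <- wt[[1L]]
      for (v in wt) if (any(abs(v - ref) > 1e-9))
        stop("sample ", smp, ": WGD times differ across segments within a draw")
      wgd_out[[smp]] <- ref
    } else wgd_out[smp] <- list(NULL)
    out[[smp]] <- gps
  }
  attr(out, "wgd_times") <- wgd_out
  out
}
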