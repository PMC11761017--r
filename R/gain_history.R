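# Copy-number gain histories as rooted forests of final DNA copies.
#
# A clonal copy-number segment with allele-specific copy number (major, minor)
# is represented as two rooted trees, one per parental allele. Each internal
# node is a gain event with a time t_g on mutation time [0, 1] (0 =
# conception, 1 = end of the clonal period); each leaf is a final DNA copy.
# A gain duplicates exactly one extant copy, so every gain node has exactly
# two descendant lineages; whole-genome doubling (WGD) duplicates all extant
# copies at one shared time, appearing as is_wgd nodes with identical times.
# The edge above a node spans (parent time, own time); leaf edges end at 1.

#' Build a copy forest from gain-event records
#'
#' @param nodes data.frame with columns `node_id`, `parent_id` (NA for the
#'   root gain of an allele), `allele` ("major"/"minor"), `time` in [0,1],
#'   `is_wgd` logical. Gain events only; leaves are implied (each gain node
#'   has two descendant lineages, unclaimed lineages terminate as leaves).
#'   May have zero rows for an ungained allele.
#' @param major,minor Final allele-specific copy numbers the forest must
#'   realize (both >= 1; losses are not representable).
#' @param segment_id Optional label used in error messages.
#' @return A `copy_forest`: list with `nodes`, `edges` (one row per edge:
#'   `edge_id`, `allele`, `t_start`, `t_end`, `leaf_count`, `is_leaf`,
#'   `node_id`, `parent_id`), `major`, `minor`, `segment_id`.
#' @export
copy_forest <- function(nodes = NULL, major = 1L, minor = 1L, segment_id = "segment") {
  if (is.null(nodes) || nrow(as.data.frame(nodes)) == 0L) {
    nodes <- data.frame(node_id = character(), parent_id = character(),
                        allele = character(), time = numeric(),
                        is_wgd = logical(), stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("node_id", "parent_id", "allele", "time", "is_wgd")
  if (!all(req %in% names(nodes)))
    stop("gain node records need columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id in segment ", segment_id)
  if (any(nodes$time < 0 | nodes$time > 1))
    stop("gain times outside [0,1] in segment ", segment_id)
  if (!all(nodes$allele %in% c("major", "minor")))
    stop("allele must be 'major' or 'minor' in segment ", segment_id)
  if (major < 1L || minor < 1L)
    stop("segment ", segment_id, ": allele copy numbers must be >= 1 ",
         "(losses are not representable as gain forests)")

  edges <- .forest_edges(nodes, segment_id)
  n_major <- sum(edges$is_leaf & edges$allele == "major")
  n_minor <- sum(edges$is_leaf & edges$allele == "minor")
  if (n_major != major || n_minor != minor)
    stop("segment ", segment_id, ": forest realizes CN (", n_major, ",",
         n_minor, ") but segment table says (", major, ",", minor, ")")
  structure(list(nodes = nodes, edges = edges, major = as.integer(major),
                 minor = as.integer(minor), segment_id = segment_id),
            class = "copy_forest")
}

# Expand gain nodes into the full edge table (gain edges + implied leaf
# edges) with leaf counts, validating ancestry times along the way.
.forest_edges <- function(nodes, segment_id) {
  out <- list()
  for (al in c("major", "minor")) {
    nd <- nodes[nodes$allele == al, , drop = FALSE]
    if (nrow(nd) == 0L) {
      # single untouched copy: one leaf edge spanning the whole clonal period
      out[[al]] <- data.frame(
        allele = al, node_id = paste0(al, "_leaf1"), parent_id = NA_character_,
        t_start = 0, t_end = 1, is_leaf = TRUE, is_wgd = FALSE,
        leaf_count = 1L, stringsAsFactors = FALSE)
      next
    }
    roots <- which(is.na(nd$parent_id) | !(nd$parent_id %in% nd$node_id))
    if (any(!is.na(nd$parent_id[roots]) & nd$parent_id[roots] != ""))
      stop("segment ", segment_id, ": parent_id ",
           nd$parent_id[roots[which(!is.na(nd$parent_id[roots]))[1]]],
           " not found on allele ", al)
    if (length(roots) != 1L)
      stop("segment ", segment_id, ": allele ", al, " must have exactly one ",
           "root gain lineage, found ", length(roots))
    kids <- split(seq_len(nrow(nd)), factor(nd$parent_id, levels = nd$node_id))
    n_child <- vapply(kids, length, integer(1))
    if (any(n_child > 2L))
      stop("segment ", segment_id, ": gain node ",
           nd$node_id[which(n_child > 2L)[1]],
           " has more than two descendant gain lineages")
    # time monotonicity parent -> child
    pidx <- match(nd$parent_id, nd$node_id)
    bad <- which(!is.na(pidx) & nd$time[pidx] > nd$time)
    if (length(bad))
      stop("segment ", segment_id, ": time inversion between nodes ",
           nd$node_id[pidx[bad[1]]], " and ", nd$node_id[bad[1]])
    # leaf counts: each gain node has 2 lineages; leaves = 2 - (#child gains)
    # accumulate bottom-up in topological (depth) order — time order is not
    # safe because clamped posterior draws may tie parent and child times
    depth <- rep(0L, nrow(nd))
    for (i in seq_len(nrow(nd))) {
      j <- i; guard <- 0L
      while (!is.na(pj <- match(nd$parent_id[j], nd$node_id))) {
        depth[i] <- depth[i] + 1L
        j <- pj
        if ((guard <- guard + 1L) > nrow(nd))
          stop("segment ", segment_id, ": cyclic parent pointers")
      }
    }
    leaf_count <- rep(0L, nrow(nd))
    ord <- order(depth, decreasing = TRUE)
    for (i in ord) {
      ch <- kids[[nd$node_id[i]]]
      leaf_count[i] <- sum(leaf_count[ch]) + (2L - length(ch))
    }
    gain_edges <- data.frame(
      allele = al, node_id = nd$node_id, parent_id = nd$parent_id,
      t_start = ifelse(is.na(pidx), 0, nd$time[pidx]), t_end = nd$time,
      is_leaf = FALSE, is_wgd = nd$is_wgd, leaf_count = leaf_count,
      stringsAsFactors = FALSE)
    leaf_rows <- lapply(seq_len(nrow(nd)), function(i) {
      n_leaves <- 2L - length(kids[[nd$node_id[i]]])
      if (n_leaves <= 0L) return(NULL)
      data.frame(allele = al,
                 node_id = paste0(nd$node_id[i], "_leaf", seq_len(n_leaves)),
                 parent_id = nd$node_id[i], t_start = nd$time[i], t_end = 1,
                 is_leaf = TRUE, is_wgd = FALSE, leaf_count = 1L,
                 stringsAsFactors = FALSE)
    })
    out[[al]] <- rbind(gain_edges, do.call(rbind, leaf_rows))
  }
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  edges$edge_id <- seq_len(nrow(edges))
  edges[, c("edge_id", "allele", "node_id", "parent_id", "t_start", "t_end",
            "is_leaf", "is_wgd", "leaf_count")]
}

#' @export
print.copy_forest <- function(x, ...) {
  cat("copy_forest", x$segment_id, sprintf("CN (%d,%d)", x$major, x$minor),
      "-", nrow(x$nodes), "gain(s),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Construct a copy forest from flat per-node records
#'
#' Convenience wrapper matching the gain-posterior TSV dialect
#' (`node_id`, `parent_id`, `allele`, `time`, `is_wgd`).
#'
#' @param records data.frame of gain node records (possibly 0 rows).
#' @param cn Integer vector `c(major, minor)`.
#' @param segment_id Label for error messages.
#' @return A `copy_forest`.
#' @export
forest_from_records <- function(records, cn, segment_id = "segment") {
  copy_forest(records, major = cn[[1]], minor = cn[[2]], segment_id = segment_id)
}

#' Edges carrying a given SNV multiplicity
#'
#' An SNV present on `m` final copies must have arisen on an edge whose
#' subtree contains exactly `m` leaves.
#'
#' @param forest A `copy_forest`.
#' @param m Multiplicity (positive integer).
#' @return The subset of the edge table with `leaf_count == m` (may be empty).
#' @export
edges_with_multiplicity <- function(forest, m) {
  stopifnot(inherits(forest, "copy_forest"), m >= 1)
  forest$edges[forest$edges$leaf_count == m, , drop = FALSE]
}

#' Total edge time-length per multiplicity class
#'
#' @param forest A `copy_forest`.
#' @return Named numeric vector mapping multiplicity m to the summed
#'   time-length of edges with that leaf count. Sums to the total forest
#'   edge length.
#' @export
total_length_by_multiplicity <- function(forest) {
  stopifnot(inherits(forest, "copy_forest"))
  e <- forest$edges
  len <- tapply(e$t_end - e$t_start, e$leaf_count, sum)
  out <- as.numeric(len)
  names(out) <- names(len)
  out
}

#' Serialize a copy forest back to flat gain-node records
#'
#' Inverse of [forest_from_records()]: returns the gain-node table (leaves
#' are implied and not emitted), so parse -> serialize round-trips exactly.
#'
#' @param forest A `copy_forest`.
#' @return data.frame of node records.
#' @export
forest_to_records <- function(forest) {
  stopifnot(inherits(forest, "copy_forest"))
  forest$nodes
}
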