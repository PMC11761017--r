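# Shared fixtures: canonical small forests and compact simulation configs.

# CN (2,1): one gain on the major allele at time t.
forest_21 <- function(t = 0.3) {
  forest_from_records(
    data.frame(node_id = "g1", parent_id = NA_character_, allele = "major",
               time = t, is_wgd = FALSE, stringsAsFactors = FALSE),
    cn = c(2, 1), segment_id = "seg21")
}

# CN (2,2): whole-genome doubling at time t (one WGD node per allele).
forest_22_wgd <- function(t = 0.4) {
  forest_from_records(
    data.frame(node_id = c("w1", "w2"), parent_id = NA_character_,
               allele = c("major", "minor"), time = t, is_wgd = TRUE,
               stringsAsFactors = FALSE),
    cn = c(2, 2), segment_id = "seg22")
}

# Degenerate gain posterior: every draw identical to `forest`.
gp_fixed <- function(forest, S = 250L) {
  nd <- forest$nodes
  gain_posterior(nd, matrix(rep(nd$time, S), nrow(nd), S),
                 forest$major, forest$minor, forest$segment_id)
}

# Small cohort configuration for fast end-to-end tests.
small_cfg <- function(...) {
  args <- list(cancer_types = c("typeA", "typeB"), samples_per_type = 3L,
               n_segments = 6L, draws_S = 40L, seed = 42L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Brute-force multiplicity posterior by direct enumeration (independent of
# multiplicity_posterior's vectorized path).
oracle_mult_posterior <- function(a, d, forest, rho, subclonal_ccf = NULL,
                                  subclonal_prior_weight = 0.1) {
  e <- forest$edges
  n_t <- forest$major + forest$minor
  ms <- sort(unique(e$leaf_count))
  w <- numeric(0)
  lab <- character(0)
  for (m in ms) {
    L <- sum((e$t_end - e$t_start)[e$leaf_count == m])
    f <- m * rho / (n_t * rho + 2 * (1 - rho))
    w <- c(w, L * dbinom(a, d, f))
    lab <- c(lab, as.character(m))
  }
  if (!is.null(subclonal_ccf)) {
    f <- subclonal_ccf * rho / (n_t * rho + 2 * (1 - rho))
    w <- c(w, subclonal_prior_weight * sum(e$t_end - e$t_start) *
             dbinom(a, d, f))
    lab <- c(lab, "SUBCLONAL")
  }
  stats::setNames(w / sum(w), lab)
}

# Brute-force joint (multiplicity, time) law on an n_bins grid for a fixed
# forest: P(m, bin) = P(m) * overlap(bin, multiplicity-m edges) / L_m.
oracle_joint_law <- function(a, d, forest, rho, n_bins = 200L) {
  post <- oracle_mult_posterior(a, d, forest, rho)
  e <- forest$edges
  brk <- seq(0, 1, length.out = n_bins + 1L)
  out <- matrix(0, length(post), n_bins,
                dimnames = list(names(post), NULL))
  for (m in names(post)) {
    em <- e[e$leaf_count == as.integer(m), , drop = FALSE]
    L <- sum(em$t_end - em$t_start)
    for (b in seq_len(n_bins)) {
      ov <- sum(pmax(0, pmin(em$t_end, brk[b + 1L]) - pmax(em$t_start, brk[b])))
      out[m, b] <- post[[m]] * ov / L
    }
  }
  out
}
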