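# Posterior timing of somatic SNVs by hierarchical sampling over segment
# timing states (gain-posterior draws), SNV multiplicity states, and uniform
# times within the implied gain interval.
#
# Mutation time runs on [0, 1]: 0 = conception, 1 = end of the tumor's
# clonal evolutionary period. Draws that land in the subclonal state are
# marked with the sentinel value 1.01.

#' Subclonal timing sentinel
#'
#' Timing draws assigned to the subclonal state carry this marker instead of
#' a mutation time in [0, 1].
#' @export
SUBCLONAL_TIME <- 1.01

#' Expected variant allele fraction for a multiplicity or CCF state
#'
#' For a clonal SNV on m of n_t tumor copies at purity rho,
#' f = m * rho / (n_t * rho + 2 * (1 - rho)); a subclonal SNV (one copy in a
#' fraction CCF of tumor cells) replaces m with CCF.
#'
#' @param m Clonal multiplicity (1..n_t); ignored when `ccf` is given.
#' @param rho Tumor purity in (0, 1].
#' @param n_t Total tumor copy number of the segment (>= 1).
#' @param ccf Cancer cell fraction in (0, 1) for the subclonal state, or NULL.
#' @return Expected VAF in (0, 1].
#' @export
expected_vaf <- function(m, rho, n_t, ccf = NULL) {
  stopifnot(rho > 0, rho <= 1, n_t >= 1)
  denom <- n_t * rho + 2 * (1 - rho)
  if (!is.null(ccf)) {
    stopifnot(all(ccf > 0), all(ccf < 1))
    return(ccf * rho / denom)
  }
  if (any(m < 1) || any(m > n_t))
    stop("impossible multiplicity: m must lie in 1..n_t (n_t = ", n_t, ")")
  m * rho / denom
}

#' Posterior over SNV multiplicity states for one timing state
#'
#' P(state) is proportional to prior(state) * Binomial(a | d, f(state)).
#' With the default length prior, prior(m) is the total edge time-length of
#' the forest's multiplicity-m class (uniform mutation arrival over copies
#' and time), and prior(SUBCLONAL) = subclonal_prior_weight * total forest
#' length. A flat prior over available states is available via
#' `prior = "uniform"`.
#'
#' @param a Alt read count (0 <= a <= d).
#' @param d Depth (>= 1).
#' @param forest A `copy_forest` for the SNV's segment.
#' @param rho Tumor purity.
#' @param subclonal_ccf CCF used for the subclonal state's expected VAF, or
#'   NULL to omit the subclonal state.
#' @param subclonal_prior_weight Scalar weight on the subclonal state
#'   relative to the total clonal edge length (default 0.1).
#' @param prior "length" (default) or "uniform".
#' @return data.frame with `state` ("1","2",... or "SUBCLONAL"), `m`
#'   (NA for subclonal), `f`, `prior`, `posterior` (sums to 1).
#' @export
multiplicity_posterior <- function(a, d, forest, rho, subclonal_ccf = NULL,
                                   subclonal_prior_weight = 0.1,
                                   prior = c("length", "uniform")) {
  stopifnot(d >= 1, a >= 0, a <= d)
  prior <- match.arg(prior)
  len <- total_length_by_multiplicity(forest)
  ms <- as.integer(names(len))
  n_t <- forest$major + forest$minor
  f <- expected_vaf(ms, rho, n_t)
  pri <- if (prior == "length") as.numeric(len) else rep(1, length(ms))
  state <- as.character(ms)
  mm <- ms
  if (!is.null(subclonal_ccf)) {
    f <- c(f, expected_vaf(NULL, rho, n_t, ccf = subclonal_ccf))
    pri <- c(pri, if (prior == "length") subclonal_prior_weight * sum(len)
             else subclonal_prior_weight)
    state <- c(state, "SUBCLONAL")
    mm <- c(mm, NA_integer_)
  }
  if (all(pri == 0)) stop("degenerate forest: all multiplicity priors zero")
  w <- pri * stats::dbinom(a, d, f)
  if (sum(w) == 0) w <- pri # data impossible under all states: fall back to prior
  data.frame(state = state, m = mm, f = f, prior = pri / sum(pri),
             posterior = w / sum(w), stringsAsFactors = FALSE)
}

#' Sample the timing posterior of one SNV
#'
#' For each draw s: (1) take gain-posterior draw s as the segment's timing
#' state; (2) form the multiplicity posterior under that state and sample a
#' state; (3) a subclonal state emits the 1.01 sentinel; (4) otherwise an
#' edge of the sampled multiplicity class is chosen with probability
#' proportional to its time-length and the SNV time is uniform on that
#' edge's interval — bounded by the preceding and subsequent gains, with 0
#' and 1 used where no gain precedes/follows.
#'
#' @param a,d Alt count and depth.
#' @param gp A `gain_posterior` for the SNV's segment.
#' @param rho Tumor purity.
#' @param S Number of timing draws (default 250). Gain-posterior draws are
#'   paired one-to-one (draw s uses gain draw s, recycled if S exceeds the
#'   gain posterior's draw count).
#' @param subclonal_ccf,subclonal_prior_weight,prior Passed to the
#'   multiplicity posterior (see [multiplicity_posterior()]).
#' @param seed Optional integer; when given, draws are reproducible and the
#'   caller's RNG state is untouched.
#' @return List with `draws` (numeric length S, values in [0,1] or 1.01),
#'   `multiplicity` (integer length S, NA where subclonal), `edge` (row
#'   index into the forest edge table per clonal draw), `gain_draw` (paired
#'   gain-posterior draw per timing draw), `mean_time`
#'   (mean over all draws including sentinels), `mean_time_clonal` (mean
#'   over clonal draws only, NA if none), `clonal_fraction`.
#' @export
sample_snv_timing <- function(a, d, gp, rho, S = 250L, subclonal_ccf = NULL,
                              subclonal_prior_weight = 0.1,
                              prior = c("length", "uniform"), seed = NULL) {
  stopifnot(inherits(gp, "gain_posterior"), S >= 1)
  prior <- match.arg(prior)
  run <- function() .sample_snv_timing_impl(a, d, gp, rho, as.integer(S),
                                            subclonal_ccf,
                                            subclonal_prior_weight, prior)
  if (is.null(seed)) run() else with_seed(seed, run())
}

.sample_snv_timing_impl <- function(a, d, gp, rho, S, subclonal_ccf,
                                    subclonal_prior_weight, prior) {
  sg <- ((seq_len(S) - 1L) %% gp$S) + 1L # paired gain draw per timing draw
  n_t <- gp$major + gp$minor
  f_m <- expected_vaf(gp$classes, rho, n_t)
  lik_m <- stats::dbinom(a, d, f_m)
  # weight matrix: states x S
  if (prior == "length") {
    W <- gp$len_by_m[, sg, drop = FALSE] * lik_m
  } else {
    W <- matrix(lik_m, length(gp$classes), S)
    W <- W * (gp$len_by_m[, sg, drop = FALSE] > 0) # unavailable states stay 0
  }
  if (!is.null(subclonal_ccf)) {
    f_sub <- expected_vaf(NULL, rho, n_t, ccf = subclonal_ccf)
    w_sub <- if (prior == "length")
      subclonal_prior_weight * colSums(gp$len_by_m)[sg] * stats::dbinom(a, d, f_sub)
    else rep(subclonal_prior_weight * stats::dbinom(a, d, f_sub), S)
    W <- rbind(W, w_sub)
  }
  tot <- colSums(W)
  if (any(tot == 0)) {
    # likelihood zero under every state (e.g. a = d with all f < 1 at d huge):
    # fall back to the prior for those draws
    zero <- tot == 0
    P0 <- if (prior == "length") gp$len_by_m[, sg[zero], drop = FALSE]
          else matrix(1, length(gp$classes), sum(zero))
    if (!is.null(subclonal_ccf))
      P0 <- rbind(P0, subclonal_prior_weight *
                    (if (prior == "length") colSums(gp$len_by_m)[sg[zero]] else 1))
    W[, zero] <- P0
    tot <- colSums(W)
  }
  P <- sweep(W, 2, tot, "/")
  # categorical sample per draw via inverse CDF
  u <- stats::runif(S)
  if (nrow(P) == 1L) {
    state_idx <- rep(1L, S)
  } else {
    cum <- apply(P, 2, cumsum)
    state_idx <- colSums(cum < rep(u, each = nrow(P))) + 1L
  }
  n_clonal_states <- length(gp$classes)
  is_sub <- state_idx > n_clonal_states
  draws <- rep(SUBCLONAL_TIME, S)
  mult <- rep(NA_integer_, S)
  edge_pick <- rep(NA_integer_, S) # row index into gp$edges, for diagnostics
  for (k in seq_len(n_clonal_states)) {
    sel <- which(!is_sub & state_idx == k)
    if (!length(sel)) next
    m <- gp$classes[k]
    eidx <- which(gp$edges$leaf_count == m)
    mult[sel] <- m
    if (length(eidx) == 1L) {
      s0 <- gp$starts[eidx, sg[sel]]
      e0 <- gp$ends[eidx, sg[sel]]
      draws[sel] <- stats::runif(length(sel), s0, e0)
      edge_pick[sel] <- eidx
    } else {
      L <- gp$lengths[eidx, sg[sel], drop = FALSE] # edges x draws-in-class
      cl <- colSums(L)
      # zero-length classes (all candidate edges degenerate): uniform tie-break
      zz <- cl == 0
      if (any(zz)) L[, zz] <- 1
      cumL <- apply(L, 2, cumsum)
      uu <- stats::runif(length(sel)) * colSums(L)
      pick <- colSums(cumL < rep(uu, each = nrow(L))) + 1L
      ed <- eidx[pick]
      s0 <- gp$starts[cbind(ed, sg[sel])]
      e0 <- gp$ends[cbind(ed, sg[sel])]
      draws[sel] <- stats::runif(length(sel), s0, e0)
      edge_pick[sel] <- ed
    }
  }
  clonal <- !is_sub
  list(draws = draws, multiplicity = mult, edge = edge_pick,
       gain_draw = sg,
       mean_time = mean(draws),
       mean_time_clonal = if (any(clonal)) mean(draws[clonal]) else NA_real_,
       clonal_fraction = mean(clonal))
}

#' Time every SNV in a sample bundle
#'
#' @param snvs data.frame with `sample`, `chrom`, `pos` (0-based), `gene`,
#'   `class`, `ref_count`, `alt_count`.
#' @param segments data.frame with `sample`, `segment_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `major`, `minor`.
#' @param gain_posteriors Output of [read_gain_posteriors()] (or the gains
#'   TSV path / data.frame, in which case it is read here).
#' @param purity data.frame with `sample`, `purity`.
#' @param S Timing draws per SNV (default 250).
#' @param seed Cohort-level integer seed; per-SNV substreams are derived by
#'   hashing (sample, chrom, pos) so row order never changes results.
#' @param subclonal_ccf CCF for the subclonal state (default 0.5).
#' @param subclonal_prior_weight,prior See [multiplicity_posterior()].
#' @return List with `timing` (one row per SNV: inputs plus `timed`, `n_t`,
#'   `mean_time`, `mean_time_clonal`, `clonal_fraction`) and `draws`
#'   (matrix n_snv x S; NA rows for untimed SNVs).
#' @export
time_all_snvs <- function(snvs, segments, gain_posteriors, purity, S = 250L,
                          seed = 1L, subclonal_ccf = 0.5,
                          subclonal_prior_weight = 0.1,
                          prior = c("length", "uniform")) {
  prior <- match.arg(prior)
  snvs <- as.data.frame(snvs, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  purity <- as.data.frame(purity, stringsAsFactors = FALSE)
  if (!inherits(gain_posteriors, "list") || is.data.frame(gain_posteriors))
    gain_posteriors <- read_gain_posteriors(gain_posteriors, segments)
  n <- nrow(snvs)
  draws <- matrix(NA_real_, n, S)
  timed <- logical(n)
  n_t <- integer(n)
  mean_time <- mean_clonal <- clonal_fraction <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    smp <- snvs$sample[i]
    seg <- segments[segments$sample == smp & segments$chrom == snvs$chrom[i] &
                      segments$start <= snvs$pos[i] & segments$end > snvs$pos[i], ,
                    drop = FALSE]
    if (nrow(seg) == 0L) next # untimed: no segment coverage
    gp <- gain_posteriors[[smp]][[seg$segment_id[1L]]]
    if (is.null(gp)) next
    rho <- purity$purity[match(smp, purity$sample)]
    d <- snvs$ref_count[i] + snvs$alt_count[i]
    if (is.na(d) || d < 1) next
    res <- sample_snv_timing(snvs$alt_count[i], d, gp, rho, S = S,
                             subclonal_ccf = subclonal_ccf,
                             subclonal_prior_weight = subclonal_prior_weight,
                             prior = prior,
                             seed = derive_seed(seed, smp, snvs$chrom[i],
                                                snvs$pos[i]))
    draws[i, ] <- res$draws
    timed[i] <- TRUE
    n_t[i] <- gp$major + gp$minor
    mean_time[i] <- res$mean_time
    mean_clonal[i] <- res$mean_time_clonal
    clonal_fraction[i] <- res$clonal_fraction
  }
  timing <- cbind(snvs,
                  data.frame(timed = timed, n_t = n_t, mean_time = mean_time,
                             mean_time_clonal = mean_clonal,
                             clonal_fraction = clonal_fraction))
  list(timing = timing, draws = draws)
}

#' Write / read a timing result as TSV (summary + wide draws sidecar)
#'
#' @param result Output of [time_all_snvs()].
#' @param path Summary TSV path; draws go to `<path>.draws.tsv`.
#' @return `path`, invisibly (writer); a `time_all_snvs()`-shaped list (reader).
#' @export
write_timing <- function(result, path) {
  write_tsv(result$timing, path)
  dr <- as.data.frame(result$draws)
  names(dr) <- paste0("draw_", seq_len(ncol(dr)))
  write_tsv(dr, paste0(path, ".draws.tsv"))
  invisible(path)
}

#' @rdname write_timing
#' @export
read_timing <- function(path) {
  timing <- read_tsv_strict(path, c("sample", "gene", "timed"))
  draws <- as.matrix(read_tsv_strict(paste0(path, ".draws.tsv")))
  dimnames(draws) <- NULL
  list(timing = timing, draws = draws)
}
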