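# MAP-EM engine for one genomic segment across k samples.
#
# This is the readable reference implementation of the E and M steps used by
# run_em(); cnvmix() fits all segments at once through a numerically
# equivalent vectorized engine (see engine.R), and the two paths are checked
# against each other in the test suite.

# clamp beta away from {0, 1} so all log terms stay finite during iteration
.clamp_beta <- function(beta) pmin(pmax(beta, 1e-6), 1 - 1e-6)

#' Initialize mixture parameters for EM
#'
#' `lambda` is initialized from the expected number of reads a diploid
#' segment generates: with fold-coverage c, read length l and segment length
#' L, reads whose start falls in a window of length L + l overlap the
#' segment on each of the two haplotypes, giving
#' `lambda = 2 c (L + l) / l` (5x coverage, 100 bp reads and 100 bp segments
#' give 20). The state proportions start heavily diploid
#' (`alpha_2 = 0.90`, remaining mass spread evenly) and the insert
#' probabilities start at their idealized values
#' `beta = (0, 0.5, 1, ..., 1)`: homozygous deletions yield only aberrant
#' spanning pairs, heterozygous deletions an even mix, and all other states
#' only library-like pairs. (The EM engine clamps beta into
#' `[1e-6, 1 - 1e-6]` before iterating.)
#'
#' @param coverage fold sequencing coverage c (> 0).
#' @param read_length read length l in bp (> 0).
#' @param segment_length segment length L in bp (> 0).
#' @param max_copy maximum copy number m.
#' @param epsilon state-0 rate multiplier.
#' @param alpha,beta,lambda optional overrides of the defaults above.
#' @return A [mixture_params()] object.
#' @examples
#' em_initialize(coverage = 5, read_length = 100, segment_length = 100)$lambda
#' @export
em_initialize <- function(coverage, read_length = 100, segment_length = 150,
                          max_copy = 5L, epsilon = 0.01,
                          alpha = NULL, beta = NULL, lambda = NULL) {
  if (coverage <= 0 || read_length <= 0 || segment_length <= 0)
    stop("`coverage`, `read_length` and `segment_length` must be > 0")
  st <- cnv_states(max_copy, epsilon)
  m <- st$max_copy
  if (is.null(lambda))
    lambda <- 2 * coverage * (segment_length + read_length) / read_length
  if (is.null(alpha)) {
    alpha <- rep(0.1 / m, m + 1L)
    alpha[3L] <- 0.9
  }
  if (is.null(beta)) beta <- c(0, 0.5, rep(1, m - 1L))
  mixture_params(alpha, beta, lambda, st)
}

# core E-step arithmetic shared by em_e_step(); obs/splits already unpacked
.seg_responsibilities <- function(f, n1, n2, params) {
  st <- params$states
  m1 <- st$max_copy + 1L
  k <- length(f)
  beta <- .clamp_beta(params$beta)
  lcoef <- lgamma(n1 + n2 + 1) - lgamma(n1 + 1) - lgamma(n2 + 1)
  lc <- matrix(-Inf, k, m1)
  for (i in seq_len(m1)) {
    la <- if (params$alpha[i] > 0) log(params$alpha[i]) else -Inf
    lc[, i] <- la +
      stats::dpois(f, st$theta[i] * params$lambda, log = TRUE) +
      lcoef + n1 * log(beta[i]) + n2 * log1p(-beta[i])
  }
  logmix <- apply(lc, 1L, .logsumexp)
  bad <- !is.finite(logmix)
  r <- exp(lc - logmix)
  if (any(bad)) {
    warning("all mixture components vanished for ", sum(bad),
            " sample(s); assigning uniform responsibilities")
    r[bad, ] <- 1 / m1
    logmix[bad] <- log(.Machine$double.xmin)
  }
  list(responsibilities = r, logmix = logmix)
}

#' E-step: state responsibilities for one segment
#'
#' Computes, per sample, the posterior probability of each copy-number state
#' given the current parameters:
#' `r_ji` proportional to `alpha_i * Pois(f_j; theta_i lambda) *
#' Binom(E[n_j1], E[n_j2]; beta_i)`, normalized in log space. When
#' `prev_resp` is supplied, the insert-split weights are first refreshed with
#' the per-sample library prior `pi_j = sum_i r_ji beta_i` (the
#' state-averaged library probability implied by the current fit); before
#' the first E-step the splits are formed at `pi = 0.5`.
#'
#' @param observations list of k [segment_observation()]s (one per sample).
#' @param splits list of k [split_counts()] results.
#' @param params current [mixture_params()].
#' @param prev_resp optional k x (m+1) responsibility matrix from the
#'   previous iteration, used to refresh the splits.
#' @return List with `responsibilities` (k x (m+1) matrix, rows summing to
#'   1), `loglik` (sum over samples of the log mixture density) and the
#'   (possibly refreshed) `splits`.
#' @export
em_e_step <- function(observations, splits, params, prev_resp = NULL) {
  k <- length(observations)
  stopifnot(length(splits) == k, inherits(params, "cnv_params"))
  if (!is.null(prev_resp)) {
    pi_j <- as.numeric(prev_resp %*% .clamp_beta(params$beta))
    pi_j <- pmin(pmax(pi_j, 1e-12), 1 - 1e-12)
    splits <- lapply(seq_len(k), function(j) .refresh_split(splits[[j]], pi_j[j]))
  }
  f  <- vapply(observations, function(o) o$read_count, numeric(1))
  n1 <- vapply(splits, function(s) s$n1_expected, numeric(1))
  n2 <- vapply(splits, function(s) s$n2_expected, numeric(1))
  es <- .seg_responsibilities(f, n1, n2, params)
  list(responsibilities = es$responsibilities, loglik = sum(es$logmix),
       splits = splits)
}

#' M-step: MAP parameter updates for one segment
#'
#' Closed-form maximizers of the expected complete-data log posterior:
#' `alpha_i = (sum_j r_ji + gamma_i - 1) / (k + gamma_s - (m+1))` with
#' negative numerators clamped to 1e-8 and the vector renormalized;
#' `beta_i = (sum_j r_ji E[n_j1] + nu_i1 - 1) /
#' (sum_j r_ji n_j + nu_i1 + nu_i2 - 2)`, clamped into `[1e-6, 1 - 1e-6]`
#' (kept unchanged if the denominator is not positive, i.e. no spanning
#' pairs anywhere under a flat prior);
#' `lambda = sum_j f_j / sum_j sum_i r_ji theta_i`, truncated to
#' `(1e-6, lambda_upper)`.
#'
#' @param observations list of k [segment_observation()]s.
#' @param splits list of k insert splits.
#' @param resp k x (m+1) responsibility matrix.
#' @param priors a [cnv_priors()] object.
#' @param params current [mixture_params()] (source of the state space and
#'   fallback beta values).
#' @param lambda_fixed if `TRUE`, `lambda` is held at its current value
#'   (global-lambda mode).
#' @return Updated [mixture_params()].
#' @export
em_m_step <- function(observations, splits, resp, priors, params,
                      lambda_fixed = FALSE) {
  st <- params$states
  m1 <- st$max_copy + 1L
  stopifnot(ncol(resp) == m1, inherits(priors, "cnv_priors"))
  f  <- vapply(observations, function(o) o$read_count, numeric(1))
  n  <- vapply(observations, function(o) o$n, numeric(1))
  n1 <- vapply(splits, function(s) s$n1_expected, numeric(1))

  a_num <- colSums(resp) + priors$gamma - 1
  if (any(a_num <= 0)) a_num[a_num <= 0] <- 1e-8
  alpha <- a_num / sum(a_num)

  b_num <- colSums(resp * n1) + priors$nu1 - 1
  b_den <- colSums(resp * n)  + priors$nu1 + priors$nu2 - 2
  beta <- ifelse(b_den > 0, pmax(b_num, 0) / b_den, params$beta)
  beta <- .clamp_beta(beta)

  if (lambda_fixed) {
    lambda <- params$lambda
  } else {
    lambda <- sum(f) / sum(resp %*% st$theta)
    lambda <- min(max(lambda, 1e-6), priors$lambda_upper * (1 - 1e-9))
  }
  mixture_params(alpha, beta, lambda, st)
}

#' Fit the per-segment mixture by MAP-EM
#'
#' Alternates [em_e_step()] and [em_m_step()] for the k samples of one
#' genomic segment until the relative change of the MAP objective
#' (log-likelihood plus log-prior) falls below `tol`, or `max_iter`
#' iterations. The EM is deterministic given its inputs.
#'
#' @param observations list of k [segment_observation()]s.
#' @param lib an [insert_library()] model (may be `NULL` if no observation
#'   carries spanning pairs).
#' @param priors a [cnv_priors()] object.
#' @param init initial [mixture_params()], e.g. from [em_initialize()].
#' @param tol relative-change convergence tolerance on the MAP objective.
#' @param max_iter maximum EM iterations.
#' @param shift optional [shift_model()]; estimated from the pooled spanning
#'   inserts of the segment via [estimate_shift()] when `NULL`.
#' @param lambda_fixed hold `lambda` at its initial value (global mode).
#' @return An object of class `"cnv_em_fit"`: `params` (final
#'   [mixture_params()]), `responsibilities` (k x (m+1)), `splits`, and
#'   `trace` (`iterations`, per-iteration `objective`, `converged`,
#'   `final_rel_change`).
#' @export
run_em <- function(observations, lib = NULL, priors = cnv_priors(),
                   init = NULL, tol = 1e-6, max_iter = 200L,
                   shift = NULL, lambda_fixed = FALSE) {
  stopifnot(tol > 0, max_iter >= 1L)
  if (is.null(init))
    stop("supply `init`, e.g. em_initialize(coverage, read_length, segment_length)")
  params <- init
  params$beta <- .clamp_beta(params$beta)
  k <- length(observations)
  pooled <- unlist(lapply(observations, function(o) o$insert_sizes))
  if (length(pooled) > 0 && is.null(lib))
    stop("`lib` is required when observations carry spanning pairs")
  if (is.null(shift) && length(pooled) > 0) shift <- estimate_shift(pooled, lib)
  splits <- lapply(observations, function(o) {
    if (o$n == 0L) split_counts(o, insert_library(1, 1), shift_model("normal_shift", delta = 1))
    else split_counts(o, lib, shift, pi_lib = 0.5)
  })

  objective <- numeric(0)
  resp <- NULL
  converged <- FALSE
  rel <- NA_real_
  for (it in seq_len(max_iter)) {
    es <- em_e_step(observations, splits, params,
                    prev_resp = if (it > 1L) resp else NULL)
    resp <- es$responsibilities
    splits <- es$splits
    obj <- es$loglik + log_prior_density(params, priors)
    if (!is.finite(obj))
      stop("non-finite MAP objective at iteration ", it,
           " (segment ", observations[[1L]]$segment, ")")
    objective <- c(objective, obj)
    if (it > 1L) {
      rel <- abs(obj - objective[it - 1L]) / (abs(objective[it - 1L]) + 1e-8)
      if (rel < tol) { converged <- TRUE; break }
    }
    params <- em_m_step(observations, splits, resp, priors, params,
                        lambda_fixed = lambda_fixed)
  }
  if (!converged) {  # sync responsibilities with the final M-step parameters
    es <- em_e_step(observations, splits, params, prev_resp = resp)
    resp <- es$responsibilities
    splits <- es$splits
  }
  structure(list(params = params, responsibilities = resp, splits = splits,
                 trace = list(iterations = length(objective),
                              objective = objective, converged = converged,
                              final_rel_change = rel)),
            class = "cnv_em_fit")
}
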