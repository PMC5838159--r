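# Probability model: copy-number state space, emission terms, per-segment
# mixture density and prior densities. All inference elsewhere runs in log
# space; the linear-scale variants exist for interactive use and testing.

#' Copy-number state space
#'
#' The digitized copy-number states are 0..m: 0 = homozygous deletion,
#' 1 = heterozygous deletion, 2 = diploid, 3..m = duplications. The read-count
#' rate of state i is `theta_i * lambda`, where `theta_0 = epsilon` (a small
#' leakage rate absorbing mismapped reads in homozygously deleted regions)
#' and `theta_i = i/2` for i >= 1, so the diploid state has rate `lambda`.
#'
#' @param max_copy integer >= 2, the maximum modelled copy number m.
#' @param epsilon rate multiplier for state 0, in (0, 0.5).
#' @return An object of class `"cnv_states"` with elements `max_copy`,
#'   `states` (0..m), `epsilon` and `theta` (length m+1 rate multipliers).
#' @examples
#' st <- cnv_states()
#' st$theta  # 0.01 0.5 1.0 1.5 2.0 2.5
#' @export
cnv_states <- function(max_copy = 5L, epsilon = 0.01) {
  max_copy <- as.integer(max_copy)
  if (is.na(max_copy) || max_copy < 2L)
    stop("`max_copy` must be an integer >= 2")
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("`epsilon` must lie in (0, 0.5)")
  structure(
    list(max_copy = max_copy, states = 0:max_copy, epsilon = epsilon,
         theta = c(epsilon, seq_len(max_copy) / 2)),
    class = "cnv_states")
}

#' Mixture parameters for one genomic segment
#'
#' @param alpha numeric vector of length m+1; `alpha[i+1]` is the proportion
#'   of samples carrying i copies of the segment. Must sum to 1.
#' @param beta numeric vector of length m+1; `beta[i+1]` is the probability
#'   that a mate pair spanning the segment has a clone-library (non-aberrant)
#'   insert size given the sample is in state i.
#' @param lambda expected diploid read count per segment (> 0).
#' @param states a [cnv_states()] object.
#' @return An object of class `"cnv_params"`.
#' @export
mixture_params <- function(alpha, beta, lambda, states = cnv_states()) {
  stopifnot(inherits(states, "cnv_states"))
  d <- states$max_copy + 1L
  if (length(alpha) != d || length(beta) != d)
    stop("`alpha` and `beta` must have length max_copy + 1 = ", d)
  if (any(alpha < 0) || abs(sum(alpha) - 1) > 1e-9)
    stop("`alpha` must be non-negative and sum to 1")
  if (any(beta < 0 | beta > 1)) stop("`beta` entries must lie in [0, 1]")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive number")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 lambda = as.numeric(lambda), states = states),
            class = "cnv_params")
}

#' Prior configuration for MAP estimation
#'
#' A Dirichlet prior on the state proportions alpha (pseudo-counts `gamma`;
#' the diploid pseudo-count is much larger than the rest, encoding that most
#' segments in most samples are diploid), independent Beta(nu1, nu2) priors
#' on each per-state insert probability beta_i, and a uniform prior on
#' lambda over (0, `lambda_upper`).
#'
#' Defaults (for m = 5): `gamma = (2, 2, 100, 2, 2, 2)`;
#' `(nu1, nu2) = (1, 9)` for state 0 (spanning pairs in homozygous deletions
#' are almost all aberrant), `(5, 5)` for state 1, `(9, 1)` for states >= 2.
#'
#' @param max_copy maximum copy number m.
#' @param gamma Dirichlet pseudo-counts, length m+1, all > 0.
#' @param nu1,nu2 Beta parameters, length m+1, all > 0.
#' @param lambda_upper upper bound of the uniform prior on lambda.
#' @return An object of class `"cnv_priors"` (with `gamma_sum` derived).
#' @export
cnv_priors <- function(max_copy = 5L, gamma = NULL, nu1 = NULL, nu2 = NULL,
                       lambda_upper = 1e6) {
  max_copy <- as.integer(max_copy)
  if (max_copy < 2L) stop("`max_copy` must be >= 2")
  d <- max_copy + 1L
  if (is.null(gamma)) gamma <- c(2, 2, 100, rep(2, max_copy - 2L))
  if (is.null(nu1))   nu1   <- c(1, 5, rep(9, max_copy - 1L))
  if (is.null(nu2))   nu2   <- c(9, 5, rep(1, max_copy - 1L))
  if (length(gamma) != d || length(nu1) != d || length(nu2) != d)
    stop("`gamma`, `nu1`, `nu2` must have length max_copy + 1 = ", d)
  if (any(gamma <= 0) || any(nu1 <= 0) || any(nu2 <= 0))
    stop("all prior parameters must be > 0")
  if (!is.numeric(lambda_upper) || lambda_upper <= 0)
    stop("`lambda_upper` must be > 0")
  structure(list(max_copy = max_copy, gamma = as.numeric(gamma),
                 gamma_sum = sum(gamma), nu1 = as.numeric(nu1),
                 nu2 = as.numeric(nu2), lambda_upper = lambda_upper),
            class = "cnv_priors")
}

#' Per-sample observation at one segment
#'
#' Bundles the read count `f` of one sample at one segment with the insert
#' sizes of the mate pairs whose insert region spans the segment.
#'
#' @param read_count non-negative integer read count.
#' @param insert_sizes numeric vector of spanning mate-pair insert sizes (bp).
#' @param sample,segment optional indices carried along for bookkeeping.
#' @return An object of class `"segment_observation"` with fields
#'   `read_count`, `insert_sizes`, `n` (number of spanning pairs), `sample`,
#'   `segment`.
#' @export
segment_observation <- function(read_count, insert_sizes = numeric(),
                                sample = NA_integer_, segment = NA_integer_) {
  if (length(read_count) != 1L || is.na(read_count) || read_count < 0 ||
      read_count != floor(read_count))
    stop("`read_count` must be a single non-negative integer")
  if (any(insert_sizes < 0)) stop("insert sizes must be >= 0")
  structure(list(read_count = as.numeric(read_count),
                 insert_sizes = as.numeric(insert_sizes),
                 n = length(insert_sizes),
                 sample = sample, segment = segment),
            class = "segment_observation")
}

#' Poisson read-count emission
#'
#' Probability of observing `f` reads in a segment for a sample in state `i`:
#' a Poisson pmf with rate `theta_i * lambda` where `theta_0 = epsilon` and
#' `theta_i = i/2` for i >= 1.
#'
#' @param f non-negative integer read count(s); vectorized.
#' @param state a single state in 0..m.
#' @param params a [mixture_params()] object.
#' @param log return the log pmf?
#' @return Emission probability (or log probability), same length as `f`.
#' @examples
#' p <- mixture_params(c(.02,.02,.9,.02,.02,.02), c(0,.5,1,1,1,1), lambda = 2)
#' poisson_emission(0, 2, p)  # exp(-2)
#' @export
poisson_emission <- function(f, state, params, log = FALSE) {
  stopifnot(inherits(params, "cnv_params"))
  if (any(f < 0) || any(f != floor(f)))
    stop("`f` must contain non-negative integers")
  st <- params$states
  if (length(state) != 1L || !(state %in% st$states))
    stop("`state` must be one of 0..", st$max_copy)
  stats::dpois(f, lambda = st$theta[state + 1L] * params$lambda, log = log)
}

# x * log(y) with the limit convention 0 * log(0) = 0
.xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

#' Binomial insert-aberration emission
#'
#' Probability that, of `n1 + n2` spanning mate pairs, `n1` have clone-library
#' insert sizes and `n2` have aberrant (shifted) ones, given the per-state
#' library probability `beta_i`. During EM the latent counts are replaced by
#' their expectations, so `n1` and `n2` may be non-integer; the binomial
#' coefficient is generalized through the gamma function.
#'
#' @param n1,n2 non-negative (possibly non-integer) counts; vectorized.
#' @param beta_i library-insert probability in \[0, 1\].
#' @param log return the log term?
#' @return The (generalized) Binomial pmf value; 1 when `n1 + n2 == 0`.
#' @export
binomial_insert_term <- function(n1, n2, beta_i, log = FALSE) {
  if (any(n1 < 0) || any(n2 < 0)) stop("`n1` and `n2` must be >= 0")
  if (length(beta_i) != 1L || beta_i < 0 || beta_i > 1)
    stop("`beta_i` must be a single probability in [0, 1]")
  lcoef <- lgamma(n1 + n2 + 1) - lgamma(n1 + 1) - lgamma(n2 + 1)
  lg <- lcoef + .xlogy(n1, beta_i) + .xlogy(n2, 1 - beta_i)
  if (log) lg else exp(lg)
}

# numerically stable log(sum(exp(x))); returns -Inf for all--Inf input
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Mixture density of one sample's segment data
#'
#' The marginal probability of observing read count `f` together with
#' `n1` library-like and `n2` aberrant spanning pairs, summed over the
#' copy-number states weighted by the state proportions `alpha`.
#'
#' @param f non-negative integer read count (scalar).
#' @param n1,n2 expected library-like / aberrant spanning-pair counts.
#' @param params a [mixture_params()] object.
#' @param log return the log density?
#' @return Scalar mixture density (or its log).
#' @export
mixture_density <- function(f, n1, n2, params, log = FALSE) {
  stopifnot(inherits(params, "cnv_params"))
  st <- params$states
  lc <- vapply(st$states, function(i) {
    la <- if (params$alpha[i + 1L] > 0) log(params$alpha[i + 1L]) else -Inf
    la + poisson_emission(f, i, params, log = TRUE) +
      binomial_insert_term(n1, n2, params$beta[i + 1L], log = TRUE)
  }, numeric(1))
  out <- .logsumexp(lc)
  if (log) out else exp(out)
}

#' Log prior density of the mixture parameters
#'
#' Sum of the Dirichlet log density over `alpha`, the Beta log densities over
#' each `beta_i`, and the uniform log prior on `lambda`, all up to additive
#' constants. Returns `-Inf` when `lambda` falls outside `(0, lambda_upper)`
#' or when some `alpha_i = 0` while `gamma_i > 1`. The limit convention
#' `0 * log(0) = 0` applies to vanishing exponents.
#'
#' @param params a [mixture_params()] object.
#' @param priors a [cnv_priors()] object.
#' @return Scalar log prior contribution (possibly `-Inf`).
#' @export
log_prior_density <- function(params, priors) {
  stopifnot(inherits(params, "cnv_params"), inherits(priors, "cnv_priors"))
  if (priors$max_copy != params$states$max_copy)
    stop("prior and parameter state spaces disagree")
  if (params$lambda <= 0 || params$lambda >= priors$lambda_upper) return(-Inf)
  dir_term  <- sum(.xlogy(priors$gamma - 1, params$alpha))
  beta_term <- sum(.xlogy(priors$nu1 - 1, params$beta) +
                   .xlogy(priors$nu2 - 1, 1 - params$beta))
  dir_term + beta_term  # log-uniform(lambda) is constant on (0, t)
}
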