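# Clone-library insert-size model and per-insert membership weights.
#
# A mate pair spanning a deleted segment maps to the reference further apart
# than the library insert size (the apparent insert is stretched by the
# deleted length). Each observed spanning insert o is scored against the
# library density and a shifted density, giving the probability
# w = P(library | o) used to form the expected counts E[n1], E[n2] that feed
# the Binomial emission.

#' Clone-library insert-size model
#'
#' Constructs the library model directly from a known mean and standard
#' deviation. To estimate it from data, use [fit_insert_library()].
#'
#' @param mu mean insert size (bp), > 0.
#' @param sigma standard deviation (bp); floored at 1 bp to avoid degenerate
#'   densities.
#' @param quantiles optional named numeric vector of empirical quantiles of
#'   the genome-wide insert sizes (monotone non-decreasing).
#' @param n number of insert sizes the model was fitted on (0 if specified
#'   directly).
#' @return An object of class `"insert_library"`.
#' @export
insert_library <- function(mu, sigma, quantiles = NULL, n = 0L) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("`mu` must be a single positive number")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  if (!is.null(quantiles) && is.unsorted(quantiles))
    stop("`quantiles` must be monotone non-decreasing")
  structure(list(mu = mu, sigma = max(sigma, 1), quantiles = quantiles,
                 n = as.integer(n)),
            class = "insert_library")
}

#' Fit the clone-library insert-size model from genome-wide insert sizes
#'
#' Location and spread are estimated robustly -- median and 1.4826 x MAD of
#' the central 99% of the values -- so that the minority of aberrant
#' (CNV-stretched) inserts present genome-wide does not inflate the library
#' spread. An empirical quantile grid is stored alongside.
#'
#' @param sizes numeric vector of genome-wide insert sizes (bp), length >= 100.
#' @param min_n minimum number of values required.
#' @return An [insert_library()] object.
#' @examples
#' lib <- fit_insert_library(rnorm(1000, 500, 50))
#' @export
fit_insert_library <- function(sizes, min_n = 100L) {
  sizes <- as.numeric(sizes[!is.na(sizes)])
  if (length(sizes) < min_n)
    stop("need at least ", min_n, " insert sizes to fit the library model; ",
         "supply the library mean/sd explicitly via insert_library()")
  if (any(sizes < 0)) stop("insert sizes must be >= 0")
  q <- stats::quantile(sizes, c(0.005, 0.995), names = FALSE, type = 7)
  core <- sizes[sizes >= q[1] & sizes <= q[2]]
  grid <- stats::quantile(sizes, probs = seq(0, 1, length.out = 201))
  insert_library(mu = stats::median(core),
                 sigma = max(stats::mad(core), 1),
                 quantiles = grid, n = length(sizes))
}

#' Shifted insert-size model for aberrant mate pairs
#'
#' Two modes: `"normal_shift"` places the aberrant component at
#' `mu + delta` with the library spread (`delta` is in effect the unknown
#' deleted length); `"tail_uniform"` spreads the aberrant mass uniformly over
#' a right tail `[tail_lo, tail_hi]`, used when no outlying inserts are
#' available to locate the shift.
#'
#' @param mode `"normal_shift"` or `"tail_uniform"`.
#' @param delta shift magnitude in bp (> 0), normal-shift mode.
#' @param tail_lo,tail_hi support bounds in bp, tail-uniform mode.
#' @return An object of class `"shift_model"`.
#' @export
shift_model <- function(mode = c("normal_shift", "tail_uniform"),
                        delta = NULL, tail_lo = NULL, tail_hi = NULL) {
  mode <- match.arg(mode)
  if (mode == "normal_shift") {
    if (is.null(delta) || delta <= 0)
      stop("`delta` must be > 0 in normal_shift mode")
  } else {
    if (is.null(tail_lo) || is.null(tail_hi) || tail_lo >= tail_hi)
      stop("need tail_lo < tail_hi in tail_uniform mode")
  }
  structure(list(mode = mode, delta = delta,
                 tail_lo = tail_lo, tail_hi = tail_hi),
            class = "shift_model")
}

#' Estimate the shift model from one segment's spanning inserts
#'
#' The shift equals the (unknown) deleted length, so it is estimated from the
#' data: `delta` is the mean excess over `mu` of inserts exceeding
#' `mu + 3 sigma`, floored at `4 sigma` to keep the components separated.
#' When no such outliers exist the tail-uniform fallback covers
#' `[mu + 3 sigma, mu + 3 sigma + tail_width]`.
#'
#' @param sizes spanning insert sizes of the segment (pooled across samples).
#' @param lib an [insert_library()] object.
#' @param tail_width width (bp) of the tail-uniform fallback support.
#' @return A [shift_model()] object.
#' @export
estimate_shift <- function(sizes, lib, tail_width = 1e5) {
  stopifnot(inherits(lib, "insert_library"))
  out <- sizes[sizes > lib$mu + 3 * lib$sigma]
  if (length(out) > 0) {
    shift_model("normal_shift",
                delta = max(mean(out) - lib$mu, 4 * lib$sigma))
  } else {
    lo <- lib$mu + 3 * lib$sigma
    shift_model("tail_uniform", tail_lo = lo, tail_hi = lo + tail_width)
  }
}

# log densities of the two insert-size components
.lib_log_density <- function(o, lib) {
  stats::dnorm(o, mean = lib$mu, sd = lib$sigma, log = TRUE)
}

.shift_log_density <- function(o, lib, shift) {
  if (shift$mode == "normal_shift") {
    stats::dnorm(o, mean = lib$mu + shift$delta, sd = lib$sigma, log = TRUE)
  } else {
    ifelse(o >= shift$tail_lo & o <= shift$tail_hi,
           -log(shift$tail_hi - shift$tail_lo), -Inf)
  }
}

# weight from precomputed component log densities; pi may be scalar or
# per-insert. Where both densities underflow to 0 the prior pi is returned.
.weight_from_logdens <- function(lg1, lg2, pi_lib) {
  a <- log(pi_lib) + lg1
  b <- log1p(-pi_lib) + lg2
  m <- pmax(a, b)
  w <- ifelse(is.finite(m),
              exp(a - (m + log(exp(a - m) + exp(b - m)))),
              pi_lib)
  pmin(pmax(w, 1e-12), 1 - 1e-12)
}

#' Membership probability of a library-like insert
#'
#' Posterior probability that a spanning insert of size `o` was drawn from
#' the clone-library distribution rather than the shifted one, under prior
#' library weight `pi_lib`. Clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param o insert size(s) in bp; vectorized.
#' @param lib an [insert_library()] object.
#' @param shift a [shift_model()] object.
#' @param pi_lib prior probability of the library component, in \[0, 1\].
#' @return Weight(s) in (0, 1).
#' @export
membership_weight <- function(o, lib, shift, pi_lib) {
  stopifnot(inherits(lib, "insert_library"), inherits(shift, "shift_model"))
  if (any(pi_lib < 0 | pi_lib > 1)) stop("`pi_lib` must lie in [0, 1]")
  .weight_from_logdens(.lib_log_density(o, lib),
                       .shift_log_density(o, lib, shift), pi_lib)
}

#' Split one observation's spanning pairs into expected counts
#'
#' Applies [membership_weight()] to every spanning insert of a
#' [segment_observation()]; the expected library-like count is the sum of the
#' weights and the aberrant count is the remainder, so totals are conserved
#' exactly.
#'
#' @param obs a [segment_observation()].
#' @param lib an [insert_library()] object.
#' @param shift a [shift_model()] object.
#' @param pi_lib prior library weight.
#' @return An object of class `"insert_split"` with fields `weights`,
#'   `n1_expected`, `n2_expected` and the per-insert component log densities
#'   `lg1`, `lg2` (kept so EM can refresh the weights as `pi_lib` evolves).
#' @export
split_counts <- function(obs, lib, shift, pi_lib = 0.5) {
  stopifnot(inherits(obs, "segment_observation"))
  if (obs$n == 0L) {
    return(structure(list(weights = numeric(), n1_expected = 0,
                          n2_expected = 0, lg1 = numeric(), lg2 = numeric()),
                     class = "insert_split"))
  }
  lg1 <- .lib_log_density(obs$insert_sizes, lib)
  lg2 <- .shift_log_density(obs$insert_sizes, lib, shift)
  w <- .weight_from_logdens(lg1, lg2, pi_lib)
  structure(list(weights = w, n1_expected = sum(w),
                 n2_expected = obs$n - sum(w), lg1 = lg1, lg2 = lg2),
            class = "insert_split")
}

# refresh an insert_split at a new library prior without re-evaluating the
# component densities
.refresh_split <- function(split, pi_lib) {
  if (length(split$weights) == 0L) return(split)
  w <- .weight_from_logdens(split$lg1, split$lg2, pi_lib)
  split$weights <- w
  split$n1_expected <- sum(w)
  split$n2_expected <- length(w) - sum(w)
  split
}
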