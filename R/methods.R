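# S3 methods for fitted cnvmix objects.

#' @export
print.cnvmix <- function(x, ...) {
  cat("Multi-sample CNV mixture fit (MAP-EM)\n")
  cat(sprintf("  samples: %d   segments: %d   max copy number: %d\n",
              nrow(x$counts), ncol(x$counts), x$state_space$max_copy))
  cat(sprintf("  EM: %d iteration(s), %s (final max relative change %.2e)\n",
              x$trace$iterations,
              if (x$trace$converged) "converged" else "not converged",
              x$trace$final_rel_change))
  cat(sprintf("  non-diploid segment calls: %d of %d cells\n",
              sum(x$states != 2L), length(x$states)))
  cat(sprintf("  merged CNV calls (>= %g bp): %d\n",
              x$settings$min_size, nrow(x$calls)))
  invisible(x)
}

#' Summarize a fitted cnvmix model
#'
#' @param object a fitted [cnvmix()] object.
#' @param ... unused.
#' @return An object of class `"summary.cnvmix"`: per-state segment-call
#'   counts, per-sample deletion/duplication call counts and total sizes,
#'   and the lambda distribution across segments.
#' @export
summary.cnvmix <- function(object, ...) {
  states <- 0:object$state_space$max_copy
  state_counts <- vapply(states, function(i) sum(object$states == i),
                         integer(1))
  names(state_counts) <- paste0("CN", states)
  calls <- object$calls
  per_sample <- NULL
  if (nrow(calls) > 0) {
    per_sample <- do.call(rbind, lapply(split(calls, calls$sample), function(d)
      data.frame(sample = d$sample[1L],
                 deletions = sum(d$class == "deletion"),
                 deletion_bp = sum(d$size[d$class == "deletion"]),
                 duplications = sum(d$class == "duplication"),
                 duplication_bp = sum(d$size[d$class == "duplication"]))))
    rownames(per_sample) <- NULL
  }
  structure(list(state_counts = state_counts, per_sample = per_sample,
                 lambda = summary(object$params$lambda),
                 trace = object$trace,
                 threshold = object$settings$posterior_threshold,
                 min_size = object$settings$min_size),
            class = "summary.cnvmix")
}

#' @export
print.summary.cnvmix <- function(x, ...) {
  cat("Segment calls by digitized copy number:\n")
  print(x$state_counts)
  cat(sprintf("\nPosterior threshold %.2f; reported calls >= %g bp\n",
              x$threshold, x$min_size))
  if (!is.null(x$per_sample)) {
    cat("\nMerged calls per sample:\n")
    print(x$per_sample, row.names = FALSE)
  } else {
    cat("\nNo merged CNV calls.\n")
  }
  cat("\nPer-segment diploid rate (lambda):\n")
  print(x$lambda)
  invisible(x)
}

#' Extract fitted mixture parameters
#'
#' @param object a fitted [cnvmix()] object.
#' @param ... unused.
#' @return List with `alpha` and `beta` (T x (m+1) matrices, one row per
#'   segment) and `lambda` (length-T vector of per-segment diploid rates).
#' @export
coef.cnvmix <- function(object, ...) object$params

#' Fitted read counts under the called states
#'
#' @param object a fitted [cnvmix()] object.
#' @param ... unused.
#' @return k x T matrix of expected read counts `theta_state * lambda`
#'   (scaled for partial final segments).
#' @export
fitted.cnvmix <- function(object, ...) {
  theta <- object$state_space$theta
  L <- attr(object$segmentation, "segment_length")
  scale <- object$segmentation$length / L
  rate <- matrix(theta[object$states + 1L], nrow(object$counts)) *
    rep(object$params$lambda * scale, each = nrow(object$counts))
  dimnames(rate) <- dimnames(object$counts)
  rate
}

#' Pearson residuals of the read counts
#'
#' @param object a fitted [cnvmix()] object.
#' @param ... unused.
#' @return k x T matrix `(f - mu) / sqrt(mu)` with `mu` the fitted Poisson
#'   rate under the called state.
#' @export
residuals.cnvmix <- function(object, ...) {
  mu <- fitted(object)
  (object$counts - mu) / sqrt(mu)
}

#' Plot called copy-number profiles
#'
#' Draws each sample's called digitized copy number along the genome
#' (step profile), with non-diploid calls highlighted.
#'
#' @param x a fitted [cnvmix()] object.
#' @param samples which samples to draw (indices or names; default first 6).
#' @param ... passed to [graphics::plot()].
#' @return The object, invisibly.
#' @export
plot.cnvmix <- function(x, samples = NULL, ...) {
  if (is.null(samples)) samples <- seq_len(min(6L, nrow(x$counts)))
  if (is.character(samples)) samples <- match(samples, x$samples)
  mid <- (x$segmentation$start + x$segmentation$end) / 2
  old <- graphics::par(mfrow = c(length(samples), 1L),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (j in samples) {
    st <- x$states[j, ]
    graphics::plot(mid, st, type = "s", ylim = c(0, x$state_space$max_copy),
                   xlab = "", ylab = x$samples[j], yaxt = "n", ...)
    graphics::axis(2, at = 0:x$state_space$max_copy)
    graphics::abline(h = 2, col = "grey70", lty = 2)
    nd <- st != 2L
    if (any(nd)) graphics::points(mid[nd], st[nd], col = "firebrick",
                                  pch = 16, cex = 0.4)
  }
  invisible(x)
}

#' Simulate read counts from a fitted model
#'
#' Parametric draws of the read-count matrix given the fitted per-segment
#' parameters and called states (a posterior-predictive check for depth;
#' insert sizes are not re-simulated).
#'
#' @param object a fitted [cnvmix()] object.
#' @param nsim number of replicate matrices.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of `nsim` k x T count matrices.
#' @export
simulate.cnvmix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  replicate(nsim, {
    m <- matrix(stats::rpois(length(mu), mu), nrow(mu))
    dimnames(m) <- dimnames(mu)
    m
  }, simplify = FALSE)
}
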