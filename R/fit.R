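# Main fitting interface: cnvmix() runs the per-segment MAP-EM across the
# genome, applies the posterior filter and merges per-segment states into
# reportable CNV calls.

# preference order for ties at equal posteriors: closest to diploid first,
# then the smaller copy number (conservative calling)
.state_preference <- function(m) order(abs(0:m - 2L), 0:m) - 1L

# vectorized MAP state per (sample, segment) cell with the tie-break above;
# resp: k x T x (m+1) array
.map_states <- function(resp, m) {
  k <- dim(resp)[1L]; n_seg <- dim(resp)[2L]
  best <- matrix(-1, k, n_seg)
  state <- matrix(0L, k, n_seg)
  for (i in .state_preference(m)) {
    p <- resp[, , i + 1L, drop = FALSE]
    dim(p) <- c(k, n_seg)
    upd <- p > best
    best[upd] <- p[upd]
    state[upd] <- i
  }
  list(state = state, posterior = best)
}

#' Per-sample segment calls from state responsibilities
#'
#' Takes the MAP state per sample; a non-diploid MAP state whose posterior
#' falls below `threshold` is filtered out, i.e. the call reverts to diploid
#' (with the diploid posterior recorded). Ties at equal posteriors prefer
#' the state closest to diploid, then the smaller copy number.
#'
#' @param resp k x (m+1) responsibility matrix for one segment (rows =
#'   samples), e.g. from [run_em()].
#' @param threshold posterior filter threshold in (0, 1\]; default 0.5.
#' @param samples optional sample names.
#' @return data.frame with columns `sample`, `state`, `posterior`.
#' @examples
#' r <- rbind(c(.6,.1,.3,0,0,0), c(0,0,1,0,0,0))
#' call_segment(r)  # state 0 with posterior 0.6; diploid with posterior 1
#' @export
call_segment <- function(resp, threshold = 0.5, samples = NULL) {
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]")
  resp <- as.matrix(resp)
  m <- ncol(resp) - 1L
  arr <- array(resp, dim = c(nrow(resp), 1L, ncol(resp)))
  mp <- .map_states(arr, m)
  state <- mp$state[, 1L]
  post <- mp$posterior[, 1L]
  revert <- state != 2L & post < threshold
  post[revert] <- resp[cbind(which(revert), 3L)]
  state[revert] <- 2L
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(resp)))
  data.frame(sample = samples, state = state, posterior = post)
}

#' Merge adjacent same-state segment calls into CNV calls
#'
#' Maximal runs of adjacent segments with identical sample, contig and
#' non-diploid digitized copy number become one call; merged calls shorter
#' than `min_size` bp are dropped from the report (set `min_size = 0` to
#' keep everything). Merging requires the identical copy number, not merely
#' the same deletion/duplication class.
#'
#' @param segment_calls data.frame with columns `sample`, `contig`,
#'   `segment`, `start`, `end`, `state`, `posterior`, sorted by
#'   (sample, contig, segment).
#' @param min_size minimum reported call size in bp (default 1000).
#' @return data.frame with columns `sample`, `contig`, `start`, `end`,
#'   `size`, `state`, `class` (deletion/duplication), `posterior` (mean over
#'   merged segments) and `n_segments`.
#' @export
merge_segments <- function(segment_calls, min_size = 1000) {
  req <- c("sample", "contig", "segment", "start", "end", "state", "posterior")
  if (!all(req %in% names(segment_calls)))
    stop("`segment_calls` needs columns ", paste(req, collapse = ", "))
  o <- order(segment_calls$sample, segment_calls$contig, segment_calls$segment)
  if (any(o != seq_along(o)))
    stop("`segment_calls` must be sorted by (sample, contig, segment)")
  x <- segment_calls
  new_run <- c(TRUE, x$sample[-1L] != x$sample[-nrow(x)] |
                 x$contig[-1L] != x$contig[-nrow(x)] |
                 x$state[-1L] != x$state[-nrow(x)] |
                 x$segment[-1L] != x$segment[-nrow(x)] + 1L)
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1L] - 1L, nrow(x))
  out <- data.frame(sample = x$sample[first], contig = x$contig[first],
                    start = x$start[first], end = x$end[last],
                    state = x$state[first],
                    posterior = as.numeric(rowsum(x$posterior, run) /
                                             (last - first + 1L)),
                    n_segments = last - first + 1L)
  out$size <- out$end - out$start
  out <- out[out$state != 2L, , drop = FALSE]
  if (min_size > 0) out <- out[out$size >= min_size, , drop = FALSE]
  out$class <- ifelse(out$state < 2L, "deletion", "duplication")
  rownames(out) <- NULL
  out[, c("sample", "contig", "start", "end", "size", "state", "class",
          "posterior", "n_segments")]
}

#' Fit the multi-sample CNV mixture and call copy numbers
#'
#' The central fitting function. For every genomic segment, the read counts
#' and spanning mate-pair insert sizes of all k samples are modelled by a
#' mixture over digitized copy-number states 0..m, with a Poisson read-count
#' emission (state i has rate `theta_i * lambda`; `theta_0 = epsilon`,
#' `theta_i = i/2`) and a Binomial emission for the number of library-like
#' spanning inserts (state-specific probability `beta_i`). Parameters are
#' estimated per segment by MAP-EM under a Dirichlet prior on the state
#' proportions, Beta priors on `beta`, and a uniform prior on `lambda`;
#' every segment's EM is independent and deterministic, so results do not
#' depend on execution order. Each sample's digitized copy number per
#' segment is the MAP state of the posterior (non-diploid calls below
#' `posterior_threshold` revert to diploid), and adjacent same-state
#' segments are merged into reportable CNV calls of at least `min_size` bp.
#'
#' `lambda` is initialized from `coverage` via
#' `2 * coverage * (L + read_length) / read_length` when the coverage is
#' known (either passed or recorded in a simulated [cnv_obs()]), otherwise
#' from the median per-segment mean read count. With
#' `lambda_mode = "global"` that genome-wide value is held fixed in every
#' segment instead of being re-estimated per segment (guards against
#' instability at very small k).
#'
#' @param counts a [cnv_obs()] object, or a k x T read-count matrix
#'   (samples in rows).
#' @param inserts spanning-insert table (see [cnv_obs()]); ignored when
#'   `counts` is a `cnv_obs`.
#' @param segmentation a [segment_genome()] result; when `NULL` and
#'   `counts` is a bare matrix, a single-contig segmentation with
#'   `segment_length` is assumed.
#' @param segment_length segment length used to build a default
#'   segmentation.
#' @param library an [insert_library()] model; fitted from the
#'   observation's `library_sample` (or, failing that, robustly from all
#'   spanning inserts) when `NULL`.
#' @param priors a [cnv_priors()]; defaults to `cnv_priors(max_copy)`.
#' @param max_copy maximum copy number m.
#' @param epsilon state-0 rate multiplier.
#' @param coverage,read_length sequencing coverage and read length used for
#'   the lambda initialization rule.
#' @param lambda_init explicit initial diploid rate (overrides `coverage`).
#' @param lambda_mode `"per_segment"` (re-estimate lambda in every segment,
#'   the model default) or `"global"` (hold the genome-wide value fixed).
#' @param posterior_threshold posterior filter for non-diploid calls.
#' @param min_size minimum reported merged-call size (bp).
#' @param tol,max_iter EM convergence controls.
#' @param verbose print per-iteration objectives.
#' @return An object of class `"cnvmix"` with components `states` (k x T
#'   called copy numbers), `posterior` (k x T posterior of the called
#'   state), `responsibilities` (k x T x (m+1) array), `params` (list of
#'   `alpha`, `beta` (T x (m+1)) and `lambda` (T)), `segment_calls`,
#'   `calls` (merged), `trace`, plus the inputs needed by the methods.
#' @seealso [summary.cnvmix()], [cnv_confusion()], [simulate_cnv_dataset()]
#' @examples
#' sim <- simulate_cnv_dataset(sim_config(k = 6, genome_length = 6e4,
#'                                        cnv_count = 8, seed = 42))
#' fit <- cnvmix(sim$obs)
#' fit$calls[, c("sample", "start", "end", "state")]
#' @export
cnvmix <- function(counts, inserts = NULL, segmentation = NULL,
                   segment_length = 150, library = NULL, priors = NULL,
                   max_copy = 5L, epsilon = 0.01,
                   coverage = NULL, read_length = NULL, lambda_init = NULL,
                   lambda_mode = c("per_segment", "global"),
                   posterior_threshold = 0.5, min_size = 1000,
                   tol = 1e-6, max_iter = 200L, verbose = FALSE) {
  lambda_mode <- match.arg(lambda_mode)
  lib_sample <- NULL
  meta <- list()
  if (inherits(counts, "cnv_obs")) {
    obs <- counts
    counts <- obs$counts
    inserts <- obs$inserts
    segmentation <- obs$segmentation
    samples <- obs$samples
    lib_sample <- obs$library_sample
    meta <- obs$meta
  } else {
    counts <- as.matrix(counts)
    samples <- rownames(counts)
    if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(counts)))
  }
  k <- nrow(counts); n_seg <- ncol(counts)
  if (k < 2L)
    warning("k = 1 sample: the multi-sample model degenerates; ",
            "state proportions are driven by the prior")
  if (is.null(segmentation))
    segmentation <- segment_genome(
      stats::setNames(n_seg * segment_length, "genome"), segment_length)
  if (nrow(segmentation) != n_seg)
    stop("segmentation has ", nrow(segmentation), " segments but counts has ",
         n_seg, " columns")
  L <- attr(segmentation, "segment_length")

  states <- cnv_states(max_copy, epsilon)
  if (is.null(priors)) priors <- cnv_priors(max_copy)
  if (is.null(coverage)) coverage <- meta$coverage
  if (is.null(read_length)) read_length <- meta$read_length
  if (is.null(read_length)) read_length <- 100

  have_inserts <- !is.null(inserts) && nrow(inserts) > 0L
  if (have_inserts && is.null(library)) {
    src <- if (!is.null(lib_sample) && length(lib_sample) >= 100)
      lib_sample else inserts$size
    library <- fit_insert_library(src)
  }

  scale <- segmentation$length / L
  if (is.null(lambda_init)) {
    if (!is.null(coverage)) {
      lambda_init <- 2 * coverage * (L + read_length) / read_length
    } else {
      seg_means <- colMeans(counts) / scale
      lambda_init <- stats::median(seg_means)
      if (lambda_init <= 0)
        stop("cannot initialize lambda from all-zero counts; supply ",
             "`lambda_init` or `coverage`")
    }
  }

  init <- em_initialize(coverage = 1, read_length = read_length,
                        segment_length = L, max_copy = max_copy,
                        epsilon = epsilon, lambda = lambda_init)
  init_all <- list(
    alpha = matrix(init$alpha, n_seg, max_copy + 1L, byrow = TRUE),
    beta = matrix(init$beta, n_seg, max_copy + 1L, byrow = TRUE),
    lambda = rep(lambda_init, n_seg))

  eng <- .fit_all_segments(counts, if (have_inserts) inserts else NULL,
                           library, priors, states, init_all, scale = scale,
                           tol = tol, max_iter = max_iter,
                           lambda_fixed = (lambda_mode == "global"),
                           verbose = verbose)

  mp <- .map_states(eng$responsibilities, max_copy)
  state <- mp$state; post <- mp$posterior
  revert <- state != 2L & post < posterior_threshold
  if (any(revert)) {
    dip <- eng$responsibilities[, , 3L, drop = FALSE]
    dim(dip) <- dim(state)
    post[revert] <- dip[revert]
    state[revert] <- 2L
  }
  dimnames(state) <- dimnames(post) <- list(samples, NULL)

  segment_calls <- data.frame(
    sample = rep(samples, times = n_seg),
    contig = rep(segmentation$contig, each = k),
    segment = rep(segmentation$segment, each = k),
    start = rep(segmentation$start, each = k),
    end = rep(segmentation$end, each = k),
    state = as.integer(state), posterior = as.numeric(post))
  segment_calls <- segment_calls[order(segment_calls$sample,
                                       segment_calls$contig,
                                       segment_calls$segment), ]
  rownames(segment_calls) <- NULL
  calls <- merge_segments(segment_calls, min_size = min_size)

  structure(list(states = state, posterior = post,
                 responsibilities = eng$responsibilities,
                 params = list(alpha = eng$alpha, beta = eng$beta,
                               lambda = eng$lambda),
                 segment_calls = segment_calls, calls = calls,
                 trace = eng$trace, segmentation = segmentation,
                 samples = samples, counts = counts, library = library,
                 state_space = states, priors = priors,
                 settings = list(posterior_threshold = posterior_threshold,
                                 min_size = min_size,
                                 lambda_mode = lambda_mode,
                                 lambda_init = lambda_init, tol = tol,
                                 max_iter = max_iter),
                 call = match.call()),
            class = "cnvmix")
}
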