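# Vectorized MAP-EM over all segments at once.
#
# The mixture of model.R is independent across segments, so the per-segment
# EM of em.R can be run for every segment simultaneously with matrix
# arithmetic: parameters live in T x (m+1) matrices (alpha, beta) and a
# length-T vector (lambda), responsibilities in a k x T x (m+1) array, and
# the spanning inserts in one long table indexed into the k x T cell grid.
# A segment whose MAP objective has converged freezes (its parameters and
# responsibilities stop updating, exactly as the per-segment EM of em.R
# would have stopped there) and drops out of the active set, so late
# iterations only touch the few segments still moving. The test suite
# asserts numerical agreement between this path and run_em().

# per-segment shift-model quantities from the pooled spanning inserts:
# delta (normal-shift) where outliers exist, tail-uniform bounds otherwise
.segment_shift_table <- function(seg_idx, size, n_seg, lib, tail_width = 1e5) {
  delta <- rep(NA_real_, n_seg)
  has_insert <- tabulate(seg_idx, n_seg) > 0L
  out <- size > lib$mu + 3 * lib$sigma
  if (any(out)) {
    ex <- rowsum(size[out] - lib$mu, seg_idx[out])
    cnt <- rowsum(rep(1, sum(out)), seg_idx[out])
    idx <- as.integer(rownames(ex))
    delta[idx] <- pmax(ex[, 1L] / cnt[, 1L], 4 * lib$sigma)
  }
  list(delta = delta,
       tail_uniform = has_insert & is.na(delta),
       tail_lo = lib$mu + 3 * lib$sigma,
       tail_hi = lib$mu + 3 * lib$sigma + tail_width)
}

# inserts: data.frame(sample, segment, size); init: list(alpha TxM, beta TxM,
# lambda T); scale: length-T multiplier on the Poisson rate (partial final
# segments). Returns parameters, responsibility array and the EM trace.
.fit_all_segments <- function(counts, inserts, lib, priors, states, init,
                              scale = NULL, tol = 1e-6, max_iter = 200L,
                              lambda_fixed = FALSE, verbose = FALSE) {
  k <- nrow(counts); n_seg <- ncol(counts)
  m1 <- states$max_copy + 1L
  theta <- states$theta
  gm1 <- priors$gamma - 1
  if (is.null(scale)) scale <- rep(1, n_seg)

  has_ins <- !is.null(inserts) && nrow(inserts) > 0L
  if (has_ins) {
    if (is.null(lib))
      stop("an insert library model is required when spanning pairs are present")
    sh <- .segment_shift_table(inserts$segment, inserts$size, n_seg, lib)
    ins_lg1 <- stats::dnorm(inserts$size, lib$mu, lib$sigma, log = TRUE)
    seg_of <- inserts$segment
    ins_lg2 <- ifelse(sh$tail_uniform[seg_of],
                      ifelse(inserts$size >= sh$tail_lo &
                               inserts$size <= sh$tail_hi,
                             -log(sh$tail_hi - sh$tail_lo), -Inf),
                      stats::dnorm(inserts$size, lib$mu + sh$delta[seg_of],
                                   lib$sigma, log = TRUE))
  }

  ## full-genome state, kept current for frozen and active segments alike
  alpha_full <- init$alpha
  beta_full <- .clamp_beta(init$beta)
  lambda_full <- init$lambda
  resp_full <- array(NA_real_, dim = c(k, n_seg, m1))
  obj_full <- rep(NA_real_, n_seg)
  converged_at <- rep(NA_integer_, n_seg)
  forced_stop <- FALSE
  warned <- FALSE

  ## active-set views, rebuilt whenever segments freeze
  active <- seq_len(n_seg)
  fv <- jt <- lg1 <- lg2 <- nv <- NULL
  reindex <- function(act) {
    fv <<- as.numeric(counts[, act, drop = FALSE])
    if (has_ins) {
      pos <- integer(n_seg); pos[act] <- seq_along(act)
      keep <- pos[inserts$segment] > 0L
      jt <<- (pos[inserts$segment[keep]] - 1L) * k + inserts$sample[keep]
      lg1 <<- ins_lg1[keep]
      lg2 <<- ins_lg2[keep]
      nv <<- tabulate(jt, nbins = k * length(act))
    } else {
      nv <<- numeric(k * length(act))
    }
  }
  reindex(active)

  resp <- NULL        # list of m1 vectors over the k x length(active) cells
  n1v <- NULL
  obj_prev <- NULL
  obj_trace <- numeric(0)
  max_rel <- NA_real_

  for (it in seq_len(max_iter)) {
    ta <- length(active)
    al <- alpha_full[active, , drop = FALSE]
    be <- beta_full[active, , drop = FALSE]
    la <- lambda_full[active]
    sc <- scale[active]

    ## refresh insert membership weights at pi_j = sum_i r_ji beta_i
    if (has_ins) {
      if (is.null(resp)) {
        piv <- rep(0.5, length(jt))
      } else {
        pim <- numeric(k * ta)
        for (i in seq_len(m1)) pim <- pim + resp[[i]] * rep(be[, i], each = k)
        piv <- pmin(pmax(pim[jt], 1e-12), 1 - 1e-12)
      }
      w <- .weight_from_logdens(lg1, lg2, piv)
      agg <- rowsum(w, jt, reorder = FALSE)
      n1v <- numeric(k * ta)
      n1v[as.integer(rownames(agg))] <- agg[, 1L]
    } else {
      n1v <- numeric(k * ta)
    }
    n2v <- nv - n1v
    lcoef <- lgamma(nv + 1) - lgamma(n1v + 1) - lgamma(n2v + 1)

    ## E-step in log space
    lc <- vector("list", m1)
    for (i in seq_len(m1)) {
      lc[[i]] <- rep(log(al[, i]), each = k) +
        stats::dpois(fv, rep(theta[i] * la * sc, each = k), log = TRUE) +
        lcoef + n1v * rep(log(be[, i]), each = k) +
        n2v * rep(log1p(-be[, i]), each = k)
    }
    mx <- do.call(pmax, lc)
    acc <- numeric(k * ta)
    for (i in seq_len(m1)) acc <- acc + exp(lc[[i]] - mx)
    logmix <- mx + log(acc)
    resp <- lapply(lc, function(x) exp(x - logmix))
    bad <- !is.finite(logmix)
    if (any(bad)) {
      if (!warned) {
        warning("all mixture components vanished for ", sum(bad),
                " sample-segment cell(s); assigning uniform responsibilities")
        warned <- TRUE
      }
      for (i in seq_len(m1)) resp[[i]][bad] <- 1 / m1
      logmix[bad] <- log(.Machine$double.xmin)
    }

    ## MAP objective per active segment: log-likelihood + log-prior
    pr_seg <- log(al) %*% gm1 + log(be) %*% (priors$nu1 - 1) +
      log1p(-be) %*% (priors$nu2 - 1)
    out_of_range <- la <= 0 | la >= priors$lambda_upper
    if (any(out_of_range)) pr_seg[out_of_range] <- -Inf
    obj <- colSums(matrix(logmix, k, ta)) + as.numeric(pr_seg)
    if (any(!is.finite(obj)))
      stop("non-finite MAP objective at iteration ", it, " in segment(s) ",
           paste(utils::head(active[!is.finite(obj)], 5L), collapse = ", "))
    obj_full[active] <- obj
    obj_trace <- c(obj_trace, sum(obj_full))
    if (verbose)
      message(sprintf("EM iteration %d: %d active segment(s), objective %.4f",
                      it, ta, obj_trace[it]))

    ## freeze converged segments (or everything at the iteration cap)
    if (is.null(obj_prev)) {
      done <- rep(FALSE, ta)
    } else {
      rel <- abs(obj - obj_prev) / (abs(obj_prev) + 1e-8)
      max_rel <- max(rel)
      done <- rel < tol
    }
    if (it == max_iter && !all(done)) { forced_stop <- TRUE; done[] <- TRUE }
    if (any(done)) {
      fr <- which(done)
      converged_at[active[fr]] <- it
      for (i in seq_len(m1))
        resp_full[, active[fr], i] <-
          matrix(resp[[i]], k, ta)[, fr, drop = FALSE]
      if (all(done)) break
      keep <- which(!done)
      cells <- as.integer(outer(seq_len(k), (keep - 1L) * k, `+`))
      resp <- lapply(resp, function(r) r[cells])
      n1v <- n1v[cells]
      obj_prev <- obj[keep]
      active <- active[keep]
      reindex(active)
      ta <- length(active)
    } else {
      obj_prev <- obj
    }

    ## M-step over the remaining active segments
    S <- vapply(resp, function(r) colSums(matrix(r, k, ta)), numeric(ta))
    if (ta == 1L) S <- matrix(S, 1L)
    a_num <- sweep(S, 2L, gm1, `+`)
    a_num[a_num <= 0] <- 1e-8
    al <- a_num / rowSums(a_num)

    be_old <- beta_full[active, , drop = FALSE]
    b_num <- vapply(seq_len(m1), function(i)
      colSums(matrix(resp[[i]] * n1v, k, ta)) + priors$nu1[i] - 1,
      numeric(ta))
    b_den <- vapply(seq_len(m1), function(i)
      colSums(matrix(resp[[i]] * nv, k, ta)) +
        priors$nu1[i] + priors$nu2[i] - 2, numeric(ta))
    if (ta == 1L) { b_num <- matrix(b_num, 1L); b_den <- matrix(b_den, 1L) }
    be <- .clamp_beta(ifelse(b_den > 0, pmax(b_num, 0) / b_den, be_old))

    if (!lambda_fixed) {
      la <- colSums(matrix(counts[, active, drop = FALSE], k, ta)) /
        (scale[active] * as.numeric(S %*% theta))
      la <- pmin(pmax(la, 1e-6), priors$lambda_upper * (1 - 1e-9))
      lambda_full[active] <- la
    }
    alpha_full[active, ] <- al
    beta_full[active, ] <- be
  }

  n_full <- matrix(0, k, n_seg)
  if (has_ins) {
    jt_all <- (inserts$segment - 1L) * k + inserts$sample
    n_full <- matrix(tabulate(jt_all, nbins = k * n_seg), k, n_seg)
  }
  list(alpha = alpha_full, beta = beta_full, lambda = lambda_full,
       responsibilities = resp_full, n = n_full,
       trace = list(iterations = length(obj_trace), objective = obj_trace,
                    converged = !forced_stop, converged_at = converged_at,
                    final_rel_change = max_rel))
}
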