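# Posterior filtering, segment merging and the end-to-end caller.

test_that("call_segment applies the MAP rule, the posterior filter and the tie-break", {
  r <- rbind(c(0, 0, 1, 0, 0, 0),
             c(0.6, 0.1, 0.3, 0, 0, 0),
             c(0.45, 0.1, 0.45, 0, 0, 0))
  calls <- call_segment(r, threshold = 0.5)
  expect_equal(calls$state, c(2L, 0L, 2L))
  expect_equal(calls$posterior, c(1, 0.6, 0.45))
  # sub-threshold non-diploid MAP reverts to diploid
  r2 <- rbind(c(0.4, 0.15, 0.45, 0, 0, 0))
  expect_equal(call_segment(r2)$state, 2L)
  # tie between states 1 and 3: closer-to-diploid rule cannot break it,
  # smaller copy number wins
  r3 <- rbind(c(0, 0.5, 0, 0.5, 0, 0))
  expect_equal(call_segment(r3)$state, 1L)
  expect_error(call_segment(r, threshold = 0), "\\(0, 1\\]")
})

make_segment_calls <- function(states, L = 150, sample = "s1",
                               contig = "chr1", posterior = 0.9) {
  n <- length(states)
  data.frame(sample = sample, contig = contig, segment = seq_len(n),
             start = (seq_len(n) - 1) * L, end = seq_len(n) * L,
             state = states, posterior = posterior)
}

test_that("merge_segments merges runs, applies the size filter and validates order", {
  sc <- make_segment_calls(rep(1L, 10))
  out <- merge_segments(sc, min_size = 1000)
  expect_equal(nrow(out), 1L)
  expect_equal(out$size, 1500)
  expect_equal(out$state, 1L)
  expect_equal(out$class, "deletion")
  expect_equal(out$n_segments, 10L)

  # 5 segments of 150 bp = 750 bp: below the 1 kb reporting filter
  expect_equal(nrow(merge_segments(make_segment_calls(rep(1L, 5)),
                                   min_size = 1000)), 0L)
  expect_equal(nrow(merge_segments(make_segment_calls(rep(1L, 5)),
                                   min_size = 0)), 1L)

  # run-length oracle: states (1,1,0,1) -> three calls before size filter
  sc2 <- make_segment_calls(c(1L, 1L, 0L, 1L))
  out2 <- merge_segments(sc2, min_size = 0)
  expect_equal(nrow(out2), 3L)
  expect_equal(out2$state, c(1L, 0L, 1L))
  expect_equal(out2$n_segments, c(2L, 1L, 1L))

  # diploid runs never become calls
  expect_equal(nrow(merge_segments(make_segment_calls(rep(2L, 8)),
                                   min_size = 0)), 0L)

  # non-adjacent same-state segments are separate calls
  sc3 <- make_segment_calls(c(1L, 1L, 2L, 1L, 1L))
  expect_equal(nrow(merge_segments(sc3, min_size = 0)), 2L)

  shuffled <- sc[c(2, 1, 3:10), ]
  expect_error(merge_segments(shuffled), "sorted")
})

test_that("merged call intervals are disjoint per sample and merging is idempotent", {
  set.seed(41)
  states <- sample(c(0L, 1L, 2L, 3L), 60, replace = TRUE,
                   prob = c(.1, .2, .6, .1))
  out <- merge_segments(make_segment_calls(states), min_size = 0)
  if (nrow(out) > 1) {
    o <- order(out$start)
    expect_true(all(out$end[o][-nrow(out)] <= out$start[o][-1L]))
  }
  expect_true(sum(out$size) <= 60 * 150)
  # idempotence: re-merging the merged calls (keyed by genomic position so
  # intervening diploid gaps persist) reproduces them exactly
  out <- out[order(out$start), ]
  again <- data.frame(sample = out$sample, contig = out$contig,
                      segment = as.integer(out$start / 150) + 1L,
                      start = out$start, end = out$end, state = out$state,
                      posterior = out$posterior)
  re <- merge_segments(again, min_size = 0)
  expect_equal(re$start, out$start)
  expect_equal(re$end, out$end)
  expect_equal(re$state, out$state)
})

test_that("lowering the threshold never decreases non-diploid segment calls", {
  set.seed(42)
  sim <- simulate_cnv_dataset(sim_config(k = 6, genome_length = 4.5e4,
                                         cnv_count = 6, seed = 5))
  fit <- cnvmix(sim$obs)
  counts <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(th) {
    n <- 0L
    for (t in seq_len(ncol(sim$obs$counts))) {
      calls <- call_segment(matrix(fit$responsibilities[, t, ], nrow = 6),
                            threshold = th)
      n <- n + sum(calls$state != 2L)
    }
    n
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the caller recovers an implanted homozygous deletion end to end", {
  # 10 samples x 500 segments, one 10-segment (1.5 kb) region deleted in 3
  cfg <- sim_config(k = 10, genome_length = 75000, cnv_count = 0, seed = 11)
  set.seed(11)
  seg <- segment_genome(c(sim1 = 75000), 150)
  regions <- data.frame(region = 1L, contig = "sim1", start = 30000,
                        end = 31500, length = 1500, type = "loss")
  truth <- build_truth(regions, cfg, seg)
  truth$copies[, ] <- 2L
  truth$copies[1:3, truth$region_segments[[1]]] <- 0L
  truth$region_copies[, 1] <- c(0L, 0L, 0L, rep(2L, 7))
  obs <- emit_observations(truth, cfg, seg)
  fit <- cnvmix(obs)
  calls <- fit$calls
  del <- calls[calls$state == 0L, ]
  expect_equal(sort(unique(del$sample)), sort(obs$samples[1:3]))
  for (s in obs$samples[1:3]) {
    d <- del[del$sample == s, ]
    expect_equal(nrow(d), 1L)
    expect_lte(abs(d$start - 30000), 150)
    expect_lte(abs(d$end - 31500), 150)
  }
  # no other sample gets a deletion call there
  expect_equal(nrow(calls[calls$state == 0L & !(calls$sample %in% obs$samples[1:3]), ]), 0L)
})

test_that("an all-diploid simulation yields zero CNV calls and identical reruns", {
  sim <- simulate_cnv_dataset(sim_config(k = 8, genome_length = 3e4,
                                         cnv_count = 0, seed = 13))
  fit1 <- cnvmix(sim$obs)
  expect_equal(nrow(fit1$calls), 0L)         # false-call count at 0.5
  fit2 <- cnvmix(sim$obs)
  expect_identical(fit1$states, fit2$states)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$calls, fit2$calls)
})

test_that("fitted model methods are coherent", {
  sim <- simulate_cnv_dataset(sim_config(k = 5, genome_length = 3e4,
                                         cnv_count = 4, seed = 17))
  fit <- cnvmix(sim$obs)
  expect_output(print(fit), "Multi-sample CNV mixture fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.cnvmix")
  expect_equal(sum(s$state_counts), length(fit$states))
  cf <- coef(fit)
  expect_equal(dim(cf$alpha), c(200L, 6L))
  expect_equal(rowSums(cf$alpha), rep(1, 200), tolerance = 1e-8)
  expect_true(all(cf$beta >= 0 & cf$beta <= 1))
  expect_true(all(cf$lambda > 0))
  mu <- fitted(fit)
  expect_equal(dim(mu), dim(sim$obs$counts))
  dip <- fit$states == 2L
  expect_equal(mu[dip], rep(cf$lambda, each = 5)[dip], tolerance = 1e-12)
  res <- residuals(fit)
  expect_lt(abs(mean(res[dip])), 0.2)  # centred Pearson residuals
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(mu))
})
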