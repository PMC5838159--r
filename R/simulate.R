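# Seeded summary-level simulator of multi-sample CNV datasets.
#
# The generator reproduces the statistical structure the caller consumes:
# non-overlapping CNV regions of type loss/gain/mixed are implanted into a
# single-contig genome, each sample draws a copy number per region from the
# type-specific distribution, and per (sample, segment) cell the read count
# is Poisson with a state-scaled rate while spanning mate-pair insert sizes
# come from the clone-library distribution or a deletion-shifted copy of it
# (shift = the deleted length). Everything is drawn from one seeded RNG
# stream, so a configuration plus seed reproduces the dataset exactly.

#' Simulation configuration
#'
#' Defaults describe the 10x study conditions this package's evaluation
#' harness replays at desk scale: 40 samples over a 3 Mb genome tiled into
#' 150 bp segments (T = 20,000), 100 bp reads at 10x coverage (diploid rate
#' `lambda = 2 c (L + l) / l = 50` reads/segment), 300 implanted CNV regions
#' cycling through the twelve lengths 250 bp .. 5 kb, region types drawn
#' loss/gain/mixed with probabilities 0.80/0.15/0.05, a Normal(500, 50)
#' clone-library insert distribution and 10 expected spanning pairs per
#' segment and sample.
#'
#' @param k number of samples.
#' @param genome_length genome length in bp (single contig).
#' @param segment_length segment length L in bp.
#' @param coverage fold sequencing coverage c.
#' @param read_length read length l in bp.
#' @param cnv_lengths menu of CNV lengths (bp), cycled over regions.
#' @param cnv_count number of CNV regions to implant.
#' @param type_probs probabilities of region types (loss, gain, mixed);
#'   must sum to 1.
#' @param insert_mean,insert_sd clone-library insert size mean / sd (bp).
#' @param span_rate expected spanning mate pairs per segment and sample
#'   (eta).
#' @param epsilon state-0 read-rate multiplier.
#' @param max_copy maximum copy number m.
#' @param contig contig name.
#' @param seed default RNG seed used by [simulate_cnv_dataset()].
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(k = 40L, genome_length = 3e6, segment_length = 150,
                       coverage = 10, read_length = 100,
                       cnv_lengths = c(250, 500, 750, 1000, 1500, 2000,
                                       2500, 3000, 3500, 4000, 4500, 5000),
                       cnv_count = 300L,
                       type_probs = c(loss = 0.80, gain = 0.15, mixed = 0.05),
                       insert_mean = 500, insert_sd = 50, span_rate = 10,
                       epsilon = 0.01, max_copy = 5L, contig = "sim1",
                       seed = 1L) {
  stopifnot(k >= 1, genome_length > 0, segment_length >= 10, coverage > 0,
            read_length > 0, all(cnv_lengths > 0), cnv_count >= 0,
            insert_mean > 0, insert_sd > 0, span_rate >= 0)
  if (length(type_probs) != 3L || abs(sum(type_probs) - 1) > 1e-9 ||
      any(type_probs < 0))
    stop("`type_probs` must be three non-negative values summing to 1")
  names(type_probs) <- c("loss", "gain", "mixed")
  structure(list(k = as.integer(k), genome_length = genome_length,
                 segment_length = segment_length, coverage = coverage,
                 read_length = read_length, cnv_lengths = cnv_lengths,
                 cnv_count = as.integer(cnv_count), type_probs = type_probs,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 span_rate = span_rate, epsilon = epsilon,
                 max_copy = as.integer(max_copy), contig = contig,
                 seed = seed),
            class = "sim_config")
}

# per-type copy-number distributions (copy number -> probability)
.copy_distributions <- list(
  loss  = c(`2` = 0.80, `1` = 0.15, `0` = 0.05),
  gain  = c(`2` = 0.85, `3` = 0.08, `4` = 0.06, `5` = 0.01),
  mixed = c(`0` = 0.04, `1` = 0.16, `2` = 0.67, `3` = 0.11, `4` = 0.02))

#' Draw per-sample copy numbers for one CNV region
#'
#' Loss regions: copies 2/1/0 with probabilities 0.80/0.15/0.05. Gain
#' regions: copies 2/3/4/5 with probabilities 0.85/0.08/0.06/0.01. Mixed
#' regions: copies 0/1/2/3/4 with probabilities 0.04/0.16/0.67/0.11/0.02.
#'
#' @param region_type one of `"loss"`, `"gain"`, `"mixed"`.
#' @param k number of samples.
#' @return Integer vector of k copy numbers (draws consume the current RNG
#'   stream).
#' @export
sample_copy_numbers <- function(region_type, k) {
  d <- .copy_distributions[[region_type]]
  if (is.null(d)) stop("unknown region type: ", region_type)
  as.integer(sample(names(d), k, replace = TRUE, prob = d))
}

#' Plan non-overlapping CNV regions
#'
#' Region lengths cycle through `cfg$cnv_lengths`; types are drawn from
#' `cfg$type_probs`; positions are drawn uniformly by rejection sampling so
#' that regions stay separated by at least one segment length (hence no
#' segment can straddle two regions). Draws consume the current RNG stream.
#'
#' @param cfg a [sim_config()].
#' @param max_attempts placement attempts per region before giving up.
#' @return data.frame with columns `region`, `contig`, `start`, `end`,
#'   `length`, `type`.
#' @export
plan_cnv_regions <- function(cfg, max_attempts = 1e4) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$cnv_count
  if (n == 0L)
    return(data.frame(region = integer(), contig = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      type = character()))
  lens <- rep_len(cfg$cnv_lengths, n)
  if (sum(lens) >= 0.5 * cfg$genome_length)
    stop("total CNV length must stay below half the genome length")
  types <- sample(names(cfg$type_probs), n, replace = TRUE,
                  prob = cfg$type_probs)
  gap <- cfg$segment_length
  starts <- numeric(n); ends <- numeric(n)
  placed <- 0L
  for (r in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      s <- floor(stats::runif(1, 0, cfg$genome_length - lens[r]))
      e <- s + lens[r]
      if (placed == 0L ||
          all(s >= ends[seq_len(placed)] + gap |
              e + gap <= starts[seq_len(placed)])) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place CNV region ", r, " after ", max_attempts,
                  " attempts; increase the genome length")
    placed <- placed + 1L
    starts[r] <- s; ends[r] <- e
  }
  ord <- order(starts)
  data.frame(region = seq_len(n), contig = cfg$contig,
             start = starts[ord], end = ends[ord],
             length = lens[ord], type = types[ord])
}

# segments whose overlap with [start, end) is >= half the segment
.region_segments <- function(seg, start, end) {
  ov <- pmin(seg$end, end) - pmax(seg$start, start)
  which(ov >= seg$length / 2)
}

#' Build the ground-truth copy-number table
#'
#' Digitizes the planned regions onto the segmentation: a segment takes a
#' region's copy number when the region covers at least half of it. Returns
#' the k x T truth matrix (2 outside regions) plus the per-region sample
#' copies.
#'
#' @param regions output of [plan_cnv_regions()].
#' @param cfg a [sim_config()].
#' @param seg the [segment_genome()] segmentation of the simulated genome.
#' @return An object of class `"cnv_truth"`: `regions` (with an added
#'   `allele_freq` column: number of samples with non-diploid copy),
#'   `copies` (k x T integer matrix), `region_copies` (k x R),
#'   `region_segments` (list of segment indices per region).
#' @export
build_truth <- function(regions, cfg, seg) {
  k <- cfg$k
  copies <- matrix(2L, k, nrow(seg))
  nr <- nrow(regions)
  region_copies <- matrix(2L, k, nr)
  seg_map <- vector("list", nr)
  for (r in seq_len(nr)) {
    cn <- sample_copy_numbers(regions$type[r], k)
    region_copies[, r] <- cn
    idx <- .region_segments(seg, regions$start[r], regions$end[r])
    seg_map[[r]] <- idx
    if (length(idx) > 0) copies[, idx] <- cn
  }
  regions$allele_freq <- colSums(region_copies != 2L)
  structure(list(regions = regions, copies = copies,
                 region_copies = region_copies, region_segments = seg_map),
            class = "cnv_truth")
}

#' Emit the observation matrix from a truth table
#'
#' Per sample j and segment t in state i: the read count is
#' `Poisson(theta_i * lambda_true)` with `lambda_true = 2 c (L + l) / l`,
#' `theta_0 = epsilon`, `theta_i = i/2`; the number of spanning mate pairs
#' is `Poisson(eta)`, of which `Binomial(n, beta*_i)` with
#' `beta* = (0, 0.5, 1, ..., 1)` carry clone-library insert sizes
#' `Normal(mu, sigma)` and the rest carry deletion-shifted sizes
#' `Normal(mu + region_length, sigma)`. Homozygous deletions still emit
#' spanning pairs (they originate from the flanking sequence), all of them
#' shifted. Draws consume the current RNG stream.
#'
#' @param truth a [build_truth()] result.
#' @param cfg a [sim_config()].
#' @param seg the segmentation.
#' @return A [cnv_obs()] object; `meta` records the generative
#'   `lambda_true`, coverage and read length, and `library_sample` holds
#'   10,000 clone-library draws.
#' @export
emit_observations <- function(truth, cfg, seg) {
  k <- cfg$k; n_seg <- nrow(seg)
  L <- cfg$segment_length
  st <- cnv_states(cfg$max_copy, cfg$epsilon)
  lambda_true <- 2 * cfg$coverage * (L + cfg$read_length) / cfg$read_length
  beta_star <- c(0, 0.5, rep(1, cfg$max_copy - 1L))
  scale <- rep(seg$length / L, each = k)

  iv <- as.integer(truth$copies) + 1L            # state index per cell
  f <- stats::rpois(k * n_seg, st$theta[iv] * lambda_true * scale)
  n <- stats::rpois(k * n_seg, cfg$span_rate)
  n1 <- stats::rbinom(k * n_seg, n, beta_star[iv])

  # shift per segment = length of the covering region (0 elsewhere)
  shift_seg <- numeric(n_seg)
  for (r in seq_len(nrow(truth$regions)))
    shift_seg[truth$region_segments[[r]]] <- truth$regions$length[r]

  n2 <- n - n1
  tot <- n1 + n2
  cell <- which(tot > 0)
  jt <- rep(cell, tot[cell])
  is_lib <- sequence(tot[cell]) <= rep(n1[cell], tot[cell])
  mu_ins <- cfg$insert_mean +
    ifelse(is_lib, 0, rep(shift_seg[(cell - 1L) %/% k + 1L], tot[cell]))
  size <- pmax(stats::rnorm(length(jt), mu_ins, cfg$insert_sd), 0)

  inserts <- data.frame(sample = (jt - 1L) %% k + 1L,
                        segment = (jt - 1L) %/% k + 1L,
                        size = size)
  counts <- matrix(as.integer(f), k, n_seg)
  rownames(counts) <- sprintf("s%02d", seq_len(k))
  cnv_obs(counts, seg, inserts = inserts,
          samples = rownames(counts),
          library_sample = stats::rnorm(10000, cfg$insert_mean, cfg$insert_sd),
          meta = list(lambda_true = lambda_true, coverage = cfg$coverage,
                      read_length = cfg$read_length,
                      insert_mean = cfg$insert_mean,
                      insert_sd = cfg$insert_sd))
}

#' Simulate a complete multi-sample CNV dataset with ground truth
#'
#' Seeds the RNG, plans regions, draws per-sample copy numbers, and emits
#' the observation matrix. Identical configuration and seed reproduce the
#' dataset exactly.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return An object of class `"cnv_sim"`: `obs` ([cnv_obs()]), `truth`
#'   ([build_truth()] result) and `manifest` (configuration + seed).
#' @examples
#' sim <- simulate_cnv_dataset(sim_config(k = 4, genome_length = 3e4,
#'                                        cnv_count = 5, seed = 7))
#' dim(sim$obs$counts)  # 4 x 200
#' @export
simulate_cnv_dataset <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  seg <- segment_genome(stats::setNames(cfg$genome_length, cfg$contig),
                        cfg$segment_length)
  regions <- plan_cnv_regions(cfg)
  truth <- build_truth(regions, cfg, seg)
  obs <- emit_observations(truth, cfg, seg)
  structure(list(obs = obs, truth = truth,
                 manifest = list(config = unclass(cfg), seed = seed,
                                 package_version =
                                   as.character(utils::packageVersion("cnvmix")))),
            class = "cnv_sim")
}

#' Write / read a simulated truth table as TSV files
#'
#' Two files are produced from `prefix`: `<prefix>.regions.tsv` (region
#' intervals, types and allele frequencies) and `<prefix>.copies.tsv`
#' (per-segment true copy numbers, one row per segment, one column per
#' sample, preceded by the interval columns).
#'
#' @param truth a `"cnv_truth"` object.
#' @param seg the matching segmentation.
#' @param prefix output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_truth_tsv <- function(truth, seg, prefix) {
  rp <- paste0(prefix, ".regions.tsv")
  cp <- paste0(prefix, ".copies.tsv")
  .write_atomic(rp, function(tmp)
    utils::write.table(truth$regions, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  df <- data.frame(contig = seg$contig, start = seg$start, end = seg$end,
                   t(truth$copies))
  .write_atomic(cp, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(c(regions = rp, copies = cp))
}

#' @rdname write_truth_tsv
#' @return `read_truth_copies()` returns the k x T integer matrix of true
#'   copy numbers stored by [write_truth_tsv()].
#' @param path path to a `.copies.tsv` file.
#' @export
read_truth_copies <- function(path) {
  df <- .read_tsv_checked(path, numeric_from = 2L)
  m <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  storage.mode(m) <- "integer"
  m
}
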