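# Evaluation harness: per-state confusion matrix with precision/recall,
# nucleotide-weighted overall accuracy, accuracy by CNV allele frequency,
# and hierarchical clustering of samples by their copy-number matrix.

#' Precision/recall statistics from a predicted-by-real confusion matrix
#'
#' The matrix layout follows the reporting convention used throughout this
#' package: rows are predicted states, columns are real states. Hence
#' precision of state i is `M[i, i] / rowSums(M)[i]` and recall is
#' `M[i, i] / colSums(M)[i]`. A pooled "duplication" aggregate treats all
#' states >= 3 as one class (a cell counts as correct if both predicted and
#' real states are amplifications).
#'
#' @param M square numeric matrix (predicted x real), states 0..m in order.
#' @return An object of class `"cnv_confusion"`: the `matrix`, a `stats`
#'   data.frame (per-state precision, recall, F-score), the `duplication`
#'   aggregate row, and the segmentwise `accuracy` (trace / total).
#' @examples
#' M <- matrix(c(5, 0, 1, 4), 2, 2)  # rows predicted, cols real
#' confusion_stats(M)$stats
#' @export
confusion_stats <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("confusion matrix must be square")
  if (any(M < 0)) stop("confusion matrix entries must be >= 0")
  states <- 0:(nrow(M) - 1L)
  dimnames(M) <- list(predicted = states, real = states)
  prec <- diag(M) / rowSums(M)
  rec <- diag(M) / colSums(M)
  f <- 2 * prec * rec / (prec + rec)
  stats <- data.frame(state = states, precision = prec, recall = rec,
                      f_score = f, row.names = NULL)
  dup <- NULL
  if (nrow(M) >= 4L) {
    amp <- states >= 3L
    tp <- sum(M[amp, amp])
    dp <- tp / sum(M[amp, ])
    dr <- tp / sum(M[, amp])
    dup <- data.frame(state = "duplication", precision = dp, recall = dr,
                      f_score = 2 * dp * dr / (dp + dr))
  }
  structure(list(matrix = M, stats = stats, duplication = dup,
                 accuracy = sum(diag(M)) / sum(M)),
            class = "cnv_confusion")
}

#' @export
print.cnv_confusion <- function(x, digits = 3, ...) {
  cat("Confusion matrix (rows = predicted, columns = real):\n")
  print(x$matrix)
  cat("\nPer-state performance:\n")
  print(cbind(x$stats[1L],
              round(x$stats[-1L], digits)), row.names = FALSE)
  if (!is.null(x$duplication))
    cat(sprintf("Duplication aggregate (states >= 3): precision %.3f, recall %.3f\n",
                x$duplication$precision, x$duplication$recall))
  cat(sprintf("Segmentwise accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

# coerce predictions/truth into k x T state matrices
.state_matrix <- function(x) {
  if (inherits(x, "cnvmix")) return(x$states)
  if (inherits(x, "cnv_truth")) return(x$copies)
  as.matrix(x)
}

#' Confusion matrix of called versus true copy-number states
#'
#' Every (sample, segment) cell contributes one count: predicted state in
#' the row, true state in the column.
#'
#' @param predicted a fitted [cnvmix()] object or a k x T matrix of called
#'   states.
#' @param truth a `"cnv_truth"` object or a k x T matrix of true states.
#' @param max_copy maximum state (default inferred).
#' @return A [confusion_stats()] object.
#' @export
cnv_confusion <- function(predicted, truth, max_copy = NULL) {
  p <- .state_matrix(predicted)
  t_ <- .state_matrix(truth)
  if (!all(dim(p) == dim(t_)))
    stop("predicted and truth matrices must have identical dimensions")
  if (is.null(max_copy)) max_copy <- max(p, t_, 2L)
  lev <- 0:max_copy
  M <- table(factor(p, levels = lev), factor(t_, levels = lev))
  confusion_stats(unclass(M))
}

#' Nucleotide-weighted overall accuracy
#'
#' Number of nucleotides whose copy-number state is predicted correctly,
#' divided by the total number of nucleotides evaluated (genome length
#' times samples): each (sample, segment) cell contributes its segment
#' length.
#'
#' @param predicted,truth as in [cnv_confusion()].
#' @param segmentation the [segment_genome()] segmentation (needed for
#'   segment lengths; equal lengths reduce this to segmentwise accuracy).
#' @return Accuracy fraction in \[0, 1\].
#' @export
overall_accuracy <- function(predicted, truth, segmentation) {
  p <- .state_matrix(predicted)
  t_ <- .state_matrix(truth)
  if (!all(dim(p) == dim(t_)))
    stop("predicted and truth matrices must have identical dimensions")
  w <- rep(segmentation$length, each = nrow(p))
  sum(w * (p == t_)) / sum(w)
}

#' Accuracy within CNV regions by allele frequency
#'
#' The allele frequency of a CNV region is the number of samples (out of k)
#' carrying a non-diploid copy there. Regions are grouped by type and
#' allele-frequency bin; within each group the nucleotide accuracy over the
#' region's (sample, segment) cells is reported.
#'
#' @param predicted a fitted [cnvmix()] object or k x T state matrix.
#' @param truth a `"cnv_truth"` object (region structure required).
#' @param segmentation the segmentation.
#' @param bin_upper upper edges of the allele-frequency bins (the first bin
#'   starts at 0); frequencies above the last edge form an open bin.
#' @return data.frame with columns `type`, `bin`, `regions`, `cells`,
#'   `accuracy`.
#' @export
accuracy_by_allele_frequency <- function(predicted, truth, segmentation,
                                         bin_upper = c(5, 10, 15, 25)) {
  stopifnot(inherits(truth, "cnv_truth"))
  p <- .state_matrix(predicted)
  regions <- truth$regions
  lo <- c(0, utils::head(bin_upper, -1L) + 1L)
  labels <- paste0(lo, "-", bin_upper)
  bin_of <- function(af) {
    i <- findInterval(af, c(lo, max(bin_upper) + 1L))
    ifelse(af > max(bin_upper), paste0(">", max(bin_upper)), labels[i])
  }
  regions$bin <- bin_of(regions$allele_freq)
  out <- list()
  for (ty in unique(regions$type)) for (b in unique(regions$bin)) {
    rs <- which(regions$type == ty & regions$bin == b)
    if (length(rs) == 0L) next
    segs <- unlist(truth$region_segments[rs])
    if (length(segs) == 0L) next
    w <- rep(segmentation$length[segs], each = nrow(p))
    correct <- p[, segs, drop = FALSE] == truth$copies[, segs, drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      type = ty, bin = b, regions = length(rs),
      cells = length(segs) * nrow(p),
      accuracy = sum(w * correct) / sum(w))
  }
  res <- do.call(rbind, out)
  res[order(res$type, match(res$bin, c(labels, paste0(">", max(bin_upper))))), ]
}

#' Hierarchically cluster samples by their copy-number matrix
#'
#' Agglomerative clustering of the samples-by-regions (or
#' samples-by-segments) copy-number matrix; by default Manhattan distance
#' with average linkage, both exposed as options. The tree is invariant to
#' column permutations of the matrix.
#'
#' @param cnv_matrix numeric matrix, samples in rows (>= 2), copy numbers
#'   in columns.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param metric distance passed to [stats::dist()].
#' @param groups number of flat clusters to cut the tree into.
#' @return An object of class `"cnv_clustering"`: `tree` (an `hclust`),
#'   `labels` (flat group memberships) and `order` (leaf order).
#' @export
cluster_samples <- function(cnv_matrix, linkage = "average",
                            metric = "manhattan", groups = 2L) {
  cnv_matrix <- as.matrix(cnv_matrix)
  if (nrow(cnv_matrix) < 2L) stop("need at least 2 samples to cluster")
  tree <- stats::hclust(stats::dist(cnv_matrix, method = metric),
                        method = linkage)
  structure(list(tree = tree,
                 labels = stats::cutree(tree, k = groups),
                 order = tree$order),
            class = "cnv_clustering")
}

#' @export
print.cnv_clustering <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$labels), "samples\n")
  for (g in sort(unique(x$labels)))
    cat(sprintf("  group %d: %s\n", g,
                paste(names(x$labels)[x$labels == g], collapse = ", ")))
  invisible(x)
}
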