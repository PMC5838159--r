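# Genome segmentation, observation containers and file I/O (TSV/BED; BAM
# ingestion lives in io-bam.R). All writers are atomic: content goes to a
# temporary file in the target directory which is then renamed into place.

#' Tile a genome into fixed-length segments
#'
#' Each contig is tiled by `ceiling(length / L)` non-overlapping segments of
#' length `L` (0-based half-open); the last segment of a contig may be
#' shorter. Segments are ordered by input contig order, then coordinate, and
#' carry a global 1-based index used throughout the package.
#'
#' @param contigs named numeric vector of contig lengths (bp), or a
#'   data.frame with columns `contig` and `length`.
#' @param segment_length segment length L in bp (>= 10).
#' @return A data.frame of class `"genome_segmentation"` with columns
#'   `segment`, `contig`, `start`, `end`, `length`; attributes
#'   `segment_length` and `contig_lengths`.
#' @examples
#' seg <- segment_genome(c(chr1 = 1000), 150)  # 7 segments, last 100 bp
#' @export
segment_genome <- function(contigs, segment_length) {
  if (is.data.frame(contigs)) {
    lens <- stats::setNames(contigs$length, contigs$contig)
  } else {
    lens <- contigs
  }
  if (is.null(names(lens)) || any(!nzchar(names(lens))))
    stop("contigs must be named")
  if (anyDuplicated(names(lens))) stop("duplicate contig names: ",
    paste(unique(names(lens)[duplicated(names(lens))]), collapse = ", "))
  if (any(lens < 1)) stop("contig lengths must be >= 1")
  if (segment_length < 10) stop("`segment_length` must be >= 10")
  L <- as.numeric(segment_length)
  pieces <- lapply(names(lens), function(cn) {
    len <- lens[[cn]]
    starts <- seq(0, len - 1, by = L)
    data.frame(contig = cn, start = starts, end = pmin(starts + L, len))
  })
  out <- do.call(rbind, pieces)
  out <- data.frame(segment = seq_len(nrow(out)), out,
                    length = out$end - out$start)
  structure(out, class = c("genome_segmentation", "data.frame"),
            segment_length = L, contig_lengths = lens)
}

#' Multi-sample observation container
#'
#' Bundles the k x T read-count matrix with the long table of spanning
#' mate-pair insert sizes, the segmentation, and an optional genome-wide
#' insert-size sample for library fitting.
#'
#' @param counts integer matrix, samples in rows, segments in columns
#'   (zero-filled where a sample has no reads).
#' @param segmentation a [segment_genome()] result with `ncol(counts)` rows.
#' @param inserts `NULL` or a data.frame with columns `sample` (row index
#'   into `counts`), `segment` (global segment index) and `size` (bp).
#' @param samples sample identifiers; defaults to `rownames(counts)`.
#' @param library_sample optional numeric vector of genome-wide insert sizes.
#' @param meta optional list of metadata (e.g. `coverage`, `read_length`).
#' @return An object of class `"cnv_obs"`.
#' @export
cnv_obs <- function(counts, segmentation, inserts = NULL,
                    samples = rownames(counts), library_sample = NULL,
                    meta = list()) {
  counts <- as.matrix(counts)
  stopifnot(inherits(segmentation, "genome_segmentation"))
  if (ncol(counts) != nrow(segmentation))
    stop("`counts` must have one column per segment (",
         nrow(segmentation), "), got ", ncol(counts))
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("`counts` must contain non-negative integers")
  k <- nrow(counts)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(k))
  if (is.null(inserts))
    inserts <- data.frame(sample = integer(), segment = integer(),
                          size = numeric())
  if (!all(c("sample", "segment", "size") %in% names(inserts)))
    stop("`inserts` needs columns sample, segment, size")
  if (nrow(inserts) > 0) {
    if (any(inserts$sample < 1L | inserts$sample > k))
      stop("insert table refers to unknown samples")
    if (any(inserts$segment < 1L | inserts$segment > ncol(counts)))
      stop("insert table refers to unknown segments")
    if (any(inserts$size < 0)) stop("insert sizes must be >= 0")
  }
  structure(list(counts = counts, inserts = inserts,
                 segmentation = segmentation, samples = samples,
                 library_sample = library_sample, meta = meta),
            class = "cnv_obs")
}

#' @export
print.cnv_obs <- function(x, ...) {
  cat("Multi-sample CNV observations\n")
  cat(sprintf("  samples:  %d\n", nrow(x$counts)))
  cat(sprintf("  segments: %d (%d contig(s), L = %g bp)\n",
              ncol(x$counts), length(attr(x$segmentation, "contig_lengths")),
              attr(x$segmentation, "segment_length")))
  cat(sprintf("  spanning inserts: %d\n", nrow(x$inserts)))
  invisible(x)
}

.write_atomic <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

# strict TSV reader: consistent column counts, numeric payload; errors carry
# the offending line number
.read_tsv_checked <- function(path, numeric_from = 1L) {
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(raw)
  lineno <- which(keep)
  lines <- raw[keep]
  if (length(lines) < 1L) stop("empty TSV file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1L]])
  bad <- which(lengths(fields) != ncol)
  if (length(bad) > 0)
    stop("malformed row in ", path, " at line ", lineno[bad[1L]],
         ": expected ", ncol, " fields, found ", lengths(fields)[bad[1L]])
  header <- fields[[1L]]
  out <- as.data.frame(do.call(rbind, fields[-1L]), stringsAsFactors = FALSE)
  names(out) <- header
  if (numeric_from <= ncol && nrow(out) > 0) {
    for (j in seq(numeric_from, ncol)) {
      v <- suppressWarnings(as.numeric(out[[j]]))
      if (anyNA(v)) stop("malformed numeric value in ", path, " at line ",
                         lineno[-1L][which(is.na(v))[1L]],
                         ", column ", header[j])
      out[[j]] <- v
    }
  }
  out
}

#' Write / read the per-segment read-count matrix as TSV
#'
#' The TSV has one row per segment with columns `contig`, `start`, `end`
#' followed by one column per sample; it round-trips losslessly through
#' [read_counts_tsv()], which rebuilds the segmentation from the interval
#' columns.
#'
#' @param obs a [cnv_obs()] object (inserts are not written; see
#'   [write_inserts_tsv()]).
#' @param path output file.
#' @return `write_counts_tsv()` returns `path` invisibly;
#'   `read_counts_tsv()` returns a [cnv_obs()] (without inserts).
#' @export
write_counts_tsv <- function(obs, path) {
  stopifnot(inherits(obs, "cnv_obs"))
  seg <- obs$segmentation
  df <- data.frame(contig = seg$contig, start = seg$start, end = seg$end,
                   t(obs$counts), check.names = FALSE)
  names(df)[-(1:3)] <- obs$samples
  .write_atomic(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- .read_tsv_checked(path, numeric_from = 2L)
  if (ncol(df) < 4L) stop("counts TSV needs contig,start,end plus >=1 sample")
  lens <- tapply(df$end, df$contig, max)
  L <- max(df$end - df$start)
  cn <- unique(df$contig)
  seg <- segment_genome(stats::setNames(as.numeric(lens[cn]), cn), L)
  if (nrow(seg) != nrow(df) || any(seg$start != df$start))
    stop("counts TSV intervals do not form a valid segmentation")
  counts <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  storage.mode(counts) <- "integer"
  rownames(counts) <- names(df)[-(1:3)]
  cnv_obs(counts, seg, samples = rownames(counts))
}

#' Write / read the spanning-insert table as TSV
#'
#' @param inserts data.frame with columns `sample`, `segment`, `size`
#'   (as in [cnv_obs()]).
#' @param path file path.
#' @return The path (write) or the insert data.frame (read).
#' @export
write_inserts_tsv <- function(inserts, path) {
  .write_atomic(path, function(tmp)
    utils::write.table(inserts[c("sample", "segment", "size")], tmp,
                       sep = "\t", quote = FALSE, row.names = FALSE))
}

#' @rdname write_inserts_tsv
#' @export
read_inserts_tsv <- function(path) {
  df <- .read_tsv_checked(path, numeric_from = 1L)
  data.frame(sample = as.integer(df$sample), segment = as.integer(df$segment),
             size = df$size)
}

#' Read a plain one-column list of genome-wide insert sizes
#'
#' @param path text file with one insert size (bp) per line; `#` comments
#'   allowed.
#' @return Numeric vector of insert sizes.
#' @export
read_insert_sizes <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  v <- suppressWarnings(as.numeric(lines))
  if (anyNA(v)) stop("malformed insert size in ", path, " at line ",
                     which(is.na(v))[1L])
  v
}

#' Write CNV calls as BED and/or TSV
#'
#' BED fields: chrom, start, end, `name = sample:CN<state>`,
#' `score = round(1000 * posterior)`. An empty call set yields a valid BED
#' containing only the header comment.
#'
#' @param calls a merged-call data.frame from [merge_segments()] (or from a
#'   fitted [cnvmix()] object's `$calls`).
#' @param bed,tsv output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_calls <- function(calls, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    .write_atomic(bed, function(tmp) {
      con <- file(tmp, "w"); on.exit(close(con))
      writeLines("#chrom\tstart\tend\tname\tscore", con)
      if (nrow(calls) > 0)
        writeLines(sprintf("%s\t%d\t%d\t%s:CN%d\t%d",
                           calls$contig, as.integer(calls$start),
                           as.integer(calls$end), calls$sample,
                           as.integer(calls$state),
                           as.integer(round(1000 * calls$posterior))), con)
    })
  }
  if (!is.null(tsv)) {
    .write_atomic(tsv, function(tmp)
      utils::write.table(calls, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }
  invisible(c(bed = bed, tsv = tsv))
}

#' @rdname write_calls
#' @param segment_calls per-segment call table (`$segment_calls` of a fit).
#' @param path output TSV path.
#' @export
write_segment_calls <- function(segment_calls, path) {
  .write_atomic(path, function(tmp)
    utils::write.table(segment_calls, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}
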