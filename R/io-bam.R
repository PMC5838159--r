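# Alignment ingestion: BAM -> per-segment observation matrix.
#
# Counting convention: a read is assigned to the segment containing its
# alignment start, so the per-sample counts partition the MAPQ-passing
# primary alignments (no read counted twice). A mate pair "spans" segment t
# when the left read ends at or before the segment start and the right read
# starts at or after the segment end, i.e. the unsequenced insert region
# covers the whole segment; such a pair contributes its outer-distance
# insert size to every segment it fully covers. Duplicate (0x400),
# secondary (0x100) and supplementary (0x800) alignments are excluded
# throughout, as are reads below the mapping-quality cutoff.

.check_bam_deps <- function() {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("BAM ingestion requires the Rsamtools and GenomicAlignments packages")
}

.bam_index_path <- function(path) {
  cand <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  cand[file.exists(cand)][1L]
}

#' Build the observation matrix from coordinate-sorted BAM files
#'
#' One BAM per sample. Per sample and segment, the read count is the number
#' of primary, non-duplicate alignments with `MAPQ >= mapq_min` whose start
#' lies in the segment; the spanning-pair insert list holds the
#' outer distances (leftmost start to rightmost end) of FR-oriented pairs
#' whose insert region covers the whole segment. A genome-wide sample of
#' insert sizes (capped at `max_library_inserts` per sample) is collected
#' for clone-library fitting.
#'
#' @param bam_files character vector of BAM paths (coordinate-sorted,
#'   indexed), one per sample.
#' @param segmentation a [segment_genome()] result; its contigs must exist
#'   in every BAM header with matching lengths.
#' @param mapq_min minimum mapping quality (default 25; reads with
#'   `MAPQ < mapq_min` are filtered out).
#' @param samples sample names; defaults to BAM basenames.
#' @param max_library_inserts cap on stored genome-wide insert sizes per
#'   sample.
#' @return A [cnv_obs()] object.
#' @export
extract_observations <- function(bam_files, segmentation, mapq_min = 25L,
                                 samples = NULL, max_library_inserts = 1e6) {
  .check_bam_deps()
  stopifnot(inherits(segmentation, "genome_segmentation"))
  if (is.null(samples))
    samples <- sub("\\.bam$", "", basename(bam_files))
  k <- length(bam_files)
  L <- attr(segmentation, "segment_length")
  clens <- attr(segmentation, "contig_lengths")
  # global index of the first segment of each contig, in segmentation order
  first_idx <- tapply(segmentation$segment, segmentation$contig, min)[names(clens)]
  nseg_per <- ceiling(as.numeric(clens) / L)

  counts <- matrix(0L, k, nrow(segmentation))
  ins_list <- vector("list", k)
  lib_list <- vector("list", k)

  for (j in seq_len(k)) {
    path <- bam_files[[j]]
    if (!file.exists(path)) stop("BAM not found: ", path)
    if (is.na(.bam_index_path(path)))
      stop("BAM index (.bai) not found for ", path,
           "; coordinate-sort and index the file first")
    hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
    missing <- setdiff(names(clens), names(hdr))
    if (length(missing) > 0)
      stop("contig(s) absent from ", path, ": ",
           paste(missing, collapse = ", "))
    off <- hdr[names(clens)] != as.numeric(clens)
    if (any(off))
      stop("contig length mismatch in ", path, ": ",
           paste(names(clens)[off], collapse = ", "))

    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq_min,
                                     what = c("rname", "pos"))
    sb <- Rsamtools::scanBam(path, param = param)[[1L]]
    keep <- as.character(sb$rname) %in% names(clens)
    if (any(keep)) {
      cidx <- match(as.character(sb$rname)[keep], names(clens))
      loc <- (sb$pos[keep] - 1L) %/% L           # 0-based local segment
      gseg <- as.integer(first_idx[cidx] + loc)
      counts[j, ] <- counts[j, ] + tabulate(gseg, nbins = ncol(counts))
    }

    ga <- GenomicAlignments::readGAlignmentPairs(
      path, param = Rsamtools::ScanBamParam(flag = flag,
                                            mapqFilter = mapq_min))
    fst <- GenomicAlignments::first(ga)
    snd <- GenomicAlignments::second(ga)
    same <- as.character(GenomicAlignments::seqnames(fst)) ==
      as.character(GenomicAlignments::seqnames(snd))
    ga_contig <- as.character(GenomicAlignments::seqnames(fst))
    usable <- same & ga_contig %in% names(clens)
    if (any(usable)) {
      fs <- GenomicAlignments::start(fst)[usable]
      fe <- GenomicAlignments::end(fst)[usable]
      ss <- GenomicAlignments::start(snd)[usable]
      se <- GenomicAlignments::end(snd)[usable]
      fstr <- as.character(GenomicAlignments::strand(fst))[usable]
      sstr <- as.character(GenomicAlignments::strand(snd))[usable]
      ctg <- ga_contig[usable]
      first_is_left <- fs <= ss
      lstart <- ifelse(first_is_left, fs, ss)
      lend   <- ifelse(first_is_left, fe, se)
      rstart <- ifelse(first_is_left, ss, fs)
      rend   <- ifelse(first_is_left, se, fe)
      lstr <- ifelse(first_is_left, fstr, sstr)
      rstr <- ifelse(first_is_left, sstr, fstr)
      fr <- lstr == "+" & rstr == "-"            # properly oriented pairs
      outer <- rend - lstart + 1
      lib <- abs(outer[fr])
      if (length(lib) > max_library_inserts)
        lib <- lib[seq_len(max_library_inserts)]
      lib_list[[j]] <- lib

      # spanning condition per segment: start >= left end, end <= right start
      cidx <- match(ctg, names(clens))[fr]
      le0 <- lend[fr]                            # left end, 0-based exclusive
      rs0 <- rstart[fr] - 1                      # right start, 0-based
      sz <- outer[fr]
      clen <- as.numeric(clens)[cidx]
      s_lo <- ceiling(le0 / L)                   # 0-based local index
      s_hi <- ifelse(rs0 >= clen, nseg_per[cidx] - 1, floor(rs0 / L) - 1)
      s_hi <- pmin(s_hi, nseg_per[cidx] - 1)
      ok <- which(s_lo <= s_hi)
      if (length(ok) > 0) {
        nrep <- s_hi[ok] - s_lo[ok] + 1
        segs <- rep(as.integer(first_idx[cidx[ok]]) + s_lo[ok], nrep) +
          sequence(nrep) - 1
        ins_list[[j]] <- data.frame(sample = j, segment = as.integer(segs),
                                    size = rep(sz[ok], nrep))
      }
    }
  }

  inserts <- do.call(rbind, ins_list[!vapply(ins_list, is.null, logical(1))])
  if (is.null(inserts))
    inserts <- data.frame(sample = integer(), segment = integer(),
                          size = numeric())
  rownames(counts) <- samples
  cnv_obs(counts, segmentation, inserts = inserts, samples = samples,
          library_sample = unlist(lib_list))
}
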