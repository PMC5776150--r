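# Detection of a k-mer panel in raw sequencing reads, per-cutoff summaries
# and deterministic every-Nth-read FASTQ subsampling.

#' Count panel k-mers in raw sequencing reads
#'
#' Scans each read once, canonicalizes every clean k-length window on both
#' strands and tallies, for every panel k-mer, its total number of
#' occurrences over all read windows (a k-mer appearing twice in one read
#' counts twice).  Reads shorter than k contribute nothing; quality lines
#' are ignored — no trimming or filtering is applied.
#'
#' @param panel A non-empty [kmer_list()] (the taxon-specific panel).
#' @param reads Character vector of FASTQ (or FASTA) file paths, plain or
#'   gzipped.
#' @return An object of class `detection_report` with fields `k`,
#'   `panel_size`, `n_reads`, `kmers` and `counts` (occurrence count per
#'   panel k-mer, in panel order).
#' @export
count_in_reads <- function(panel, reads) {
  stopifnot(inherits(panel, "kmer_list"))
  if (length(panel) == 0L) stop("panel is empty", call. = FALSE)
  if (length(reads) < 1L) stop("no read files given", call. = FALSE)
  k <- panel$k
  counts <- integer(length(panel))
  n_reads <- 0L
  for (f in reads) {
    seqs <- read_seqs(f)
    n_reads <- n_reads + length(seqs)
    if (length(seqs) == 0L) next
    joined <- paste(seqs, collapse = "N")
    canon <- canonical_fast(kmer_windows(joined, k)$window)
    idx <- match(canon, panel$kmers)
    idx <- idx[!is.na(idx)]
    if (length(idx))
      counts <- counts + tabulate(idx, nbins = length(panel))
  }
  structure(list(k = k, panel_size = length(panel), n_reads = n_reads,
                 kmers = panel$kmers, counts = counts),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: panel of %d %d-mers scanned against %d read(s)\n",
              x$panel_size, x$k, x$n_reads))
  d <- detected_at_cutoffs(x)
  for (i in seq_len(nrow(d)))
    cat(sprintf("  detected at frequency >= %-3d : %d\n",
                d$cutoff[i], d$n_detected[i]))
  invisible(x)
}

#' Number of panel k-mers detected at each frequency cutoff
#'
#' For each cutoff f, reports how many panel k-mers were seen at least f
#' times in the reads.  Raising f trades sensitivity for specificity:
#' spurious detections caused by sequencing errors in reads from close
#' non-target taxa sit at low frequency, genuine target signal at high.
#'
#' @param report A `detection_report` from [count_in_reads()].
#' @param cutoffs Strictly ascending positive integers; default
#'   `c(1, 2, 5, 10)`.
#' @return A data frame with columns `cutoff` and `n_detected`
#'   (non-increasing in `cutoff`).
#' @export
detected_at_cutoffs <- function(report, cutoffs = c(1L, 2L, 5L, 10L)) {
  stopifnot(inherits(report, "detection_report"))
  cutoffs <- as.integer(cutoffs)
  if (length(cutoffs) < 1L || any(is.na(cutoffs)) || any(cutoffs < 1L) ||
      is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly ascending positive integers",
         call. = FALSE)
  data.frame(cutoff = cutoffs,
             n_detected = vapply(cutoffs,
                                 function(f) sum(report$counts >= f),
                                 integer(1)))
}

# Read a FASTQ file as raw lines, validating the 4-line record structure.
read_fastq_lines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ file ", path, " has ", length(lines),
         " lines, not a multiple of 4", call. = FALSE)
  lines
}

#' Deterministically subsample a FASTQ file
#'
#' Emulates even selection of reads from a large run: with
#' `mode = "every_nth"` the output keeps reads at indices
#' `0, s, 2s, ...` with stride `s = floor(n_total / n_out)`, truncated to
#' exactly `n_out` records (so subsampling 10^8 reads down to 10^5 keeps
#' every 1000th read).  Note that every-Nth subsamples at different
#' `n_out` are not nested; `mode = "prefix"` (first `n_out` reads) is
#' offered where nesting matters.  All four lines of each kept record are
#' copied verbatim, so the operation is byte-deterministic.
#'
#' @param path Input FASTQ path, plain or gzipped.
#' @param n_out Number of reads to keep, `1 <= n_out <= n_total`.
#' @param out Output path; written gzipped if it ends in `.gz`.
#' @param mode `"every_nth"` (default) or `"prefix"`.
#' @return `out`, invisibly; attribute `indices` carries the 0-based read
#'   indices kept.
#' @export
subsample_every_nth <- function(path, n_out, out,
                                mode = c("every_nth", "prefix")) {
  mode <- match.arg(mode)
  n_out <- as.integer(n_out)
  lines <- read_fastq_lines(path)
  n_total <- length(lines) %/% 4L
  if (is.na(n_out) || n_out < 1L || n_out > n_total)
    stop("n_out (", n_out, ") must be between 1 and the number of reads (",
         n_total, ")", call. = FALSE)
  idx <- if (mode == "every_nth") {
    stride <- n_total %/% n_out
    seq.int(0L, by = stride, length.out = n_out)
  } else {
    seq.int(0L, length.out = n_out)
  }
  keep_lines <- as.vector(t(outer(idx * 4L, 1:4, `+`)))
  con <- if (grepl("\\.gz$", out)) gzfile(out, "wb") else file(out, "wb")
  writeLines(lines[keep_lines], con, sep = "\n")
  close(con)
  attr(out, "indices") <- idx
  invisible(out)
}
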