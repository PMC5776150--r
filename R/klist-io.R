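# KLIST v1: a bit-exact text serialization of a kmer_list.
#
#   line 1:  #KLIST<TAB>1<TAB>k=<int><TAB>n=<int><TAB>source=<text>
#   lines 2..n+1:  <canonical k-mer, uppercase ACGT><TAB><count>
#
# Body sorted ascending lexicographically (equivalently by 2-bit code),
# LF line endings, optional trailing newline.

#' Write a k-mer list to a KLIST v1 file
#'
#' @param x A [kmer_list()].
#' @param path Output file path (written with LF line endings).
#' @return `path`, invisibly.
#' @export
write_klist <- function(x, path) {
  stopifnot(inherits(x, "kmer_list"))
  header <- sprintf("#KLIST\t1\tk=%d\tn=%d\tsource=%s",
                    x$k, length(x$kmers), x$source_label)
  con <- file(path, open = "wb")
  on.exit(close(con))
  body <- if (length(x$kmers)) paste0(x$kmers, "\t", x$counts) else character(0)
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a KLIST v1 file
#'
#' Parses and validates a KLIST v1 file: header fields, body line count
#' against the header's `n`, k-mer alphabet and length, strictly ascending
#' sort order and positive counts.  Any violation is reported with the
#' offending line number.
#'
#' @param path Path to a KLIST v1 file.
#' @return A [kmer_list()] (with `n_sources = 1`; the file format carries
#'   only the free-text source label).
#' @export
read_klist <- function(path) {
  if (!file.exists(path)) stop("no such KLIST file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stop("KLIST parse error at line 1: empty file", call. = FALSE)
  m <- regmatches(lines[1L],
                  regexec("^#KLIST\t1\tk=([0-9]+)\tn=([0-9]+)\tsource=(.*)$",
                          lines[1L]))[[1L]]
  if (length(m) != 4L)
    stop("KLIST parse error at line 1: malformed header", call. = FALSE)
  k <- as.integer(m[2L])
  n <- as.integer(m[3L])
  src <- m[4L]
  body <- lines[-1L]
  # tolerate (only) trailing blank lines from a final newline
  while (length(body) > 0L && !nzchar(body[length(body)]))
    body <- body[-length(body)]
  if (length(body) != n)
    stop(sprintf("KLIST parse error: header declares n=%d but body has %d lines",
                 n, length(body)), call. = FALSE)
  kmers <- character(n)
  counts <- integer(n)
  if (n > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    len <- lengths(parts)
    if (any(len != 2L))
      stop("KLIST parse error at line ",
           which(len != 2L)[1L] + 1L, ": expected <kmer>\t<count>",
           call. = FALSE)
    kmers <- vapply(parts, `[[`, "", 1L)
    counts <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    bad <- which(is.na(counts) | counts < 1L)
    if (length(bad))
      stop("KLIST parse error at line ", bad[1L] + 1L,
           ": count must be an integer >= 1", call. = FALSE)
    bad <- which(nchar(kmers) != k | grepl("[^ACGT]", kmers))
    if (length(bad))
      stop("KLIST parse error at line ", bad[1L] + 1L,
           ": not an uppercase ACGT ", k, "-mer", call. = FALSE)
    if (n > 1L) {
      asc <- kmers[-1L] > kmers[-n]
      if (!all(asc))
        stop("KLIST parse error at line ", which(!asc)[1L] + 2L,
             ": k-mers out of order or duplicated", call. = FALSE)
    }
  }
  kmer_list(kmers, counts, k, n_sources = 1L, source_label = src)
}
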