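# Canonical k-mer primitives and k-mer list construction.
#
# The working representation of a canonical k-mer is its uppercase ACGT
# string.  For the ACGT alphabet, lexicographic (byte) order on strings of
# equal length is identical to the order of the 2-bit packed integer code
# (A=0, C=1, G=2, T=3, 5'-most base most significant), so sorted string
# vectors behave exactly like sorted code vectors while supporting k up to
# 32 without 64-bit integers.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings (ACGT and IUPAC codes).
#' @return Character vector of reverse complements, same length as `x`.
#' @export
#' @examples
#' dna_revcomp(c("ACGT", "AAAC"))
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Stops with the 1-based position of the first offending character.
check_acgt <- function(kmers, what = "k-mer") {
  bad <- regexpr("[^ACGT]", kmers)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    stop(sprintf("%s %d contains a non-ACGT character at position %d",
                 what, i, bad[i]), call. = FALSE)
  }
  invisible(TRUE)
}

check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1L || k > 32L)
    stop("k must be a single integer in 1..32", call. = FALSE)
  as.integer(k)
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement, so that one stored k-mer represents
#' both strands.  Reverse-complement palindromes map to themselves.
#'
#' @param kmers Character vector of same-length ACGT strings (upper case
#'   enforced; lower case input is upper-cased first).
#' @return Character vector of canonical k-mers.
#' @export
#' @examples
#' kmer_canonical("TTTT")  # "AAAA"
#' kmer_canonical("ACGT")  # palindrome, unchanged
kmer_canonical <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  kmers <- toupper(kmers)
  k <- unique(nchar(kmers))
  if (length(k) != 1L)
    stop("all k-mers must share the same length", call. = FALSE)
  check_k(k)
  check_acgt(kmers)
  canonical_fast(kmers)
}

# Canonicalization without validation, for internal hot paths where the
# windows are already known to be clean uppercase ACGT.
canonical_fast <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- dna_revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Encode and decode 2-bit packed k-mer codes
#'
#' Packs a k-mer into an integer code with 2 bits per base (A=0, C=1, G=2,
#' T=3; the 5'-most base occupies the most significant bit pair), returned
#' as a double.  Doubles represent integers exactly up to 2^53, so encoding
#' is supported for k <= 26; for longer k-mers the canonical string itself
#' is the identifier throughout the package (its sort order equals code
#' order).
#'
#' @param kmers Character vector of ACGT strings, all of one length k <= 26.
#' @param codes Numeric vector of codes in `[0, 4^k)`.
#' @param k k-mer length used when decoding.
#' @return `kmer_encode`: numeric codes; `kmer_decode`: character k-mers.
#' @export
#' @examples
#' kmer_encode("ACGT")            # 0*64 + 1*16 + 2*4 + 3 = 27
#' kmer_decode(27, 4)             # "ACGT"
kmer_encode <- function(kmers) {
  if (length(kmers) == 0L) return(numeric(0))
  kmers <- toupper(kmers)
  k <- unique(nchar(kmers))
  if (length(k) != 1L)
    stop("all k-mers must share the same length", call. = FALSE)
  k <- check_k(k)
  if (k > 26L)
    stop("numeric k-mer codes are exact only for k <= 26; ",
         "use the canonical string for longer k-mers", call. = FALSE)
  check_acgt(kmers)
  code <- numeric(length(kmers))
  for (i in seq_len(k)) {
    v <- match(substring(kmers, i, i), DNA_BASES) - 1L
    code <- code * 4 + v
  }
  code
}

#' @rdname kmer_encode
#' @export
kmer_decode <- function(codes, k) {
  k <- check_k(k)
  if (k > 26L)
    stop("numeric k-mer codes are exact only for k <= 26", call. = FALSE)
  if (any(codes < 0 | codes >= 4^k | codes != floor(codes)))
    stop("codes must be integers in [0, 4^k)", call. = FALSE)
  out <- matrix("", nrow = length(codes), ncol = k)
  rest <- codes
  for (i in rev(seq_len(k))) {
    out[, i] <- DNA_BASES[rest %% 4 + 1]
    rest <- rest %/% 4
  }
  apply(out, 1L, paste0, collapse = "")
}

# All length-k windows of a sequence together with 0-based start positions.
# Windows containing any non-ACGT symbol are dropped; lower case is
# upper-cased on ingest.
kmer_windows <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) return(list(start = integer(0), window = character(0)))
  ok_base <- strsplit(seq, "", fixed = TRUE)[[1]] %in% DNA_BASES
  starts <- seq_len(L - k + 1L)
  bad_cum <- cumsum(!ok_base)
  clean <- (bad_cum[starts + k - 1L] - c(0L, bad_cum)[starts]) == 0L
  starts <- starts[clean]
  if (length(starts) == 0L)
    return(list(start = integer(0), window = character(0)))
  list(start = starts - 1L, window = substring(seq, starts, starts + k - 1L))
}

#' Extract canonical k-mers from a sequence
#'
#' Slides a k-length window over the sequence and yields the canonical code
#' (string) of every window consisting solely of A/C/G/T; windows touching
#' any other symbol (N, IUPAC ambiguity codes, gaps) are skipped.  For an
#' N-free sequence of length L >= k exactly `L - k + 1` k-mers are
#' returned, in window order.
#'
#' @param seq A single DNA sequence string.
#' @param k k-mer length, 1..32.
#' @param canonical If `FALSE`, return the forward-strand windows instead
#'   of canonical forms.
#' @return Character vector of k-mers (possibly empty).
#' @export
#' @examples
#' extract_kmers("ACGTACGT", 4)
#' extract_kmers("ACGNACG", 4)  # every window touches N: empty
extract_kmers <- function(seq, k, canonical = TRUE) {
  stopifnot(length(seq) == 1L)
  k <- check_k(k)
  w <- kmer_windows(seq, k)$window
  if (canonical) canonical_fast(w) else w
}

# ---- sequence file ingest ---------------------------------------------------

#' Sniff whether a sequence file is FASTA or FASTQ
#'
#' Looks at the first non-blank character after (transparent) gzip
#' decompression: `>` means FASTA, `@` means FASTQ.
#'
#' @param path File path (plain or gzip-compressed).
#' @return `"fasta"`, `"fastq"`, or `"empty"` for a file with no
#'   non-blank content.
#' @export
sniff_seq_format <- function(path) {
  if (!file.exists(path))
    stop("cannot read sequence file: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                     error = function(e)
                       stop("cannot decode sequence file ", path, ": ",
                            conditionMessage(e), call. = FALSE))
    if (length(line) == 0L) return("empty")
    line <- trimws(line)
    if (nzchar(line)) break
  }
  ch <- substr(line, 1L, 1L)
  if (ch == ">") "fasta"
  else if (ch == "@") "fastq"
  else stop("cannot autodetect FASTA/FASTQ format of ", path,
            " (first non-blank character is '", ch, "')", call. = FALSE)
}

# Read all records of a FASTA or FASTQ file (plain or gzipped) as a named
# character vector of upper-cased sequences.
read_seqs <- function(path) {
  fmt <- sniff_seq_format(path)
  if (fmt == "empty") return(structure(character(0), names = character(0)))
  s <- tryCatch(Biostrings::readDNAStringSet(path, format = fmt),
                error = function(e)
                  stop("failed to parse ", fmt, " file ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  out <- toupper(as.character(s))
  names(out) <- names(s)
  out
}

# ---- KmerList ---------------------------------------------------------------

#' Construct a k-mer list
#'
#' A `kmer_list` is the universal currency of the pipeline: a table of
#' canonical k-mers with occurrence counts, sorted strictly ascending (byte
#' order, equivalently 2-bit code order), plus light provenance.
#'
#' @param kmers Character vector of distinct canonical k-mers, sorted
#'   ascending.
#' @param counts Integer vector of positive occurrence counts.
#' @param k k-mer length shared by all entries.
#' @param n_sources Number of source files/sequence sets aggregated.
#' @param source_label Free-text provenance label.
#' @return An object of class `kmer_list` with fields `k`, `kmers`,
#'   `counts`, `n_sources`, `source_label`.
#' @export
kmer_list <- function(kmers, counts, k, n_sources = 1L, source_label = "") {
  k <- check_k(k)
  kmers <- as.character(kmers)
  counts <- as.integer(counts)
  if (length(kmers) != length(counts))
    stop("kmers and counts differ in length", call. = FALSE)
  if (length(kmers) > 0L) {
    if (any(nchar(kmers) != k))
      stop("all k-mers must have length k = ", k, call. = FALSE)
    check_acgt(kmers)
    if (is.unsorted(kmers, strictly = TRUE))
      stop("k-mers must be strictly ascending (no duplicates)", call. = FALSE)
    if (any(is.na(counts)) || any(counts < 1L))
      stop("all counts must be integers >= 1", call. = FALSE)
  }
  structure(
    list(k = k, kmers = kmers, counts = counts,
         n_sources = as.integer(n_sources),
         source_label = as.character(source_label)[1L]),
    class = "kmer_list")
}

#' @export
print.kmer_list <- function(x, ...) {
  cat(sprintf("kmer_list: %d canonical %d-mers (total count %.0f) from %d source(s)\n",
              length(x$kmers), x$k, sum(as.numeric(x$counts)), x$n_sources))
  if (nzchar(x$source_label)) cat("  source:", x$source_label, "\n")
  n <- length(x$kmers)
  show <- seq_len(min(n, 6L))
  for (i in show) cat(sprintf("  %s  %d\n", x$kmers[i], x$counts[i]))
  if (n > length(show)) cat("  ...", n - length(show), "more\n")
  invisible(x)
}

#' @export
length.kmer_list <- function(x) length(x$kmers)

# Content identity: k, entries and label (n_sources is provenance metadata
# that the KLIST file format does not carry).
klist_identical <- function(a, b) {
  isTRUE(a$k == b$k) && identical(a$kmers, b$kmers) &&
    identical(a$counts, b$counts) &&
    identical(a$source_label, b$source_label)
}

# Aggregate a character vector of canonical k-mers into sorted unique
# (kmer, count) pairs.
tally_kmers <- function(canon) {
  if (length(canon) == 0L)
    return(list(kmers = character(0), counts = integer(0)))
  canon <- sort(canon, method = "radix")
  r <- rle(canon)
  list(kmers = r$values, counts = r$lengths)
}

#' Build a k-mer list from sequence files
#'
#' Reads one or more FASTA/FASTQ files (plain or gzipped, autodetected),
#' extracts canonical k-mers from every record of every file and aggregates
#' them into a single sorted [kmer_list()].  Counts are total canonical
#' occurrences over both strands; windows containing non-ACGT symbols are
#' skipped.
#'
#' @param paths Character vector of sequence file paths.
#' @param k k-mer length, 1..32.
#' @param source_label Provenance label; defaults to the base names of the
#'   input files.
#' @return A [kmer_list()] with `n_sources = length(paths)`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s", "ACGTACGT"), fa)
#' build_kmer_list(fa, k = 4)
build_kmer_list <- function(paths, k, source_label = NULL) {
  k <- check_k(k)
  if (length(paths) < 1L) stop("at least one input file required", call. = FALSE)
  if (is.null(source_label))
    source_label <- paste(basename(paths), collapse = ",")
  canon <- character(0)
  for (p in paths) {
    seqs <- read_seqs(p)
    if (length(seqs) == 0L) next
    # Joining records with "N" lets one windowing pass serve the whole
    # file: windows spanning a junction contain N and are dropped anyway.
    joined <- paste(seqs, collapse = "N")
    canon <- c(canon, canonical_fast(kmer_windows(joined, k)$window))
  }
  t <- tally_kmers(canon)
  kmer_list(t$kmers, t$counts, k, n_sources = length(paths),
            source_label = source_label)
}
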