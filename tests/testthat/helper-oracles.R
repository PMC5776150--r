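# Naive reference implementations used as independent oracles.  These are
# deliberately written with per-string loops and named-vector arithmetic,
# sharing no machinery with the package's Biostrings/radix-sort paths.

oracle_revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "",
                       fixed = TRUE)[[1L]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Named integer vector of canonical k-mer counts, names sorted in C order.
oracle_counts <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  acc <- new.env(parent = emptyenv())
  if (L >= k) {
    for (i in seq_len(L - k + 1L)) {
      w <- substr(seq, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      cw <- oracle_canonical(w)
      acc[[cw]] <- (if (is.null(acc[[cw]])) 0L else acc[[cw]]) + 1L
    }
  }
  nms <- sort(ls(acc), method = "radix")
  setNames(vapply(nms, function(n) acc[[n]], integer(1), USE.NAMES = FALSE),
           nms)
}

oracle_counts_multi <- function(seqs, k) {
  tabs <- lapply(seqs, oracle_counts, k = k)
  all_n <- sort(unique(unlist(lapply(tabs, names))), method = "radix")
  out <- setNames(integer(length(all_n)), all_n)
  for (tb in tabs) out[names(tb)] <- out[names(tb)] + tb
  out
}

# Naive mapping-based set operations on named count vectors.
oracle_union_min_presence <- function(tabs, m) {
  all_n <- sort(unique(unlist(lapply(tabs, names))), method = "radix")
  pres <- vapply(all_n, function(n)
    sum(vapply(tabs, function(tb) n %in% names(tb), logical(1))),
    integer(1))
  tot <- vapply(all_n, function(n)
    sum(vapply(tabs, function(tb)
      if (n %in% names(tb)) tb[[n]] else 0L, integer(1))),
    integer(1))
  setNames(tot, all_n)[pres >= m]
}

oracle_subtract <- function(a, b) a[!(names(a) %in% names(b))]

oracle_intersect <- function(a, b) {
  common <- intersect(names(a), names(b))
  setNames(pmin(a[common], b[common]),
           common)[sort(common, method = "radix")]
}

# ---- random fixture builders ------------------------------------------------

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_klist <- function(k, n_max = 30L, label = "rand") {
  pool <- unique(oracle_canonical(vapply(seq_len(n_max),
                                         function(i) random_dna(k), "")))
  kmer_list(sort(pool, method = "radix"),
            sample(1:20, length(pool), replace = TRUE), k,
            source_label = label)
}

write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "wb")
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0(">seq", i), seqs[i]))), con, sep = "\n")
  close(con)
  path
}

write_tmp_fastq <- function(seqs, path = tempfile(fileext = ".fq")) {
  con <- file(path, "wb")
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0("@read", i), seqs[i], "+", strrep("I", nchar(seqs[i]))))),
    con, sep = "\n")
  close(con)
  path
}

# kmer_list from a named count vector (oracle output)
klist_from_counts <- function(tab, k, label = "oracle") {
  kmer_list(names(tab), as.integer(tab), k, source_label = label)
}
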