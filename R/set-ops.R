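# Set algebra over sorted k-mer lists: presence-thresholded union,
# difference, intersection and frequency filtering.

check_same_k <- function(...) {
  ks <- vapply(list(...), function(l) l$k, integer(1))
  if (length(unique(ks)) != 1L)
    stop("k-mer lists have mixed k: ", paste(ks, collapse = ", "),
         call. = FALSE)
  ks[1L]
}

#' Presence-annotated union of k-mer lists
#'
#' For every k-mer occurring in any input list, reports the summed count
#' over all lists and the number of lists it is present in (presence is
#' binary per list: count >= 1).
#'
#' @param lists A list of [kmer_list()] objects sharing one k.
#' @return A data frame with columns `kmer`, `total_count`,
#'   `n_lists_present`, sorted ascending by `kmer`.
#' @export
klist_presence <- function(lists) {
  stopifnot(length(lists) >= 1L)
  do.call(check_same_k, lists)
  all_k <- unlist(lapply(lists, `[[`, "kmers"), use.names = FALSE)
  all_c <- unlist(lapply(lists, `[[`, "counts"), use.names = FALSE)
  if (length(all_k) == 0L)
    return(data.frame(kmer = character(0), total_count = integer(0),
                      n_lists_present = integer(0)))
  o <- order(all_k, method = "radix")
  all_k <- all_k[o]; all_c <- all_c[o]
  r <- rle(all_k)
  grp <- rep.int(seq_along(r$values), r$lengths)
  tot <- as.integer(rowsum(all_c, grp, reorder = FALSE))
  data.frame(kmer = r$values, total_count = tot,
             n_lists_present = r$lengths)
}

#' Union of k-mer lists with a minimum-presence (universality) threshold
#'
#' Returns the k-mers present (count >= 1) in at least `m` of the input
#' lists.  The count carried on each returned k-mer is its summed count
#' over all input lists, so downstream steps retain total multiplicity.
#'
#' @param lists A list of [kmer_list()] objects sharing one k.
#' @param m Minimum number of lists a k-mer must be present in,
#'   `1 <= m <= length(lists)`.
#' @return A [kmer_list()].
#' @export
#' @examples
#' a <- kmer_list(c("AAAA", "AAAC"), c(2L, 1L), 4)
#' b <- kmer_list(c("AAAA", "AAAG"), c(1L, 3L), 4)
#' klist_union_min_presence(list(a, b), m = 2)  # only AAAA, count 3
klist_union_min_presence <- function(lists, m) {
  stopifnot(length(lists) >= 1L)
  k <- do.call(check_same_k, lists)
  if (length(m) != 1L || is.na(m) || m < 1L || m > length(lists))
    stop("m must satisfy 1 <= m <= number of lists (",
         length(lists), ")", call. = FALSE)
  p <- klist_presence(lists)
  keep <- p$n_lists_present >= m
  kmer_list(p$kmer[keep], p$total_count[keep], k,
            n_sources = length(lists),
            source_label = sprintf("union(min_presence=%d)", as.integer(m)))
}

#' Difference of two k-mer lists
#'
#' Entries of `a` whose k-mer does not occur in `b`, with `a`'s counts
#' preserved.  Removal is by k-mer identity only; `b`'s counts are ignored.
#'
#' @param a,b [kmer_list()] objects with equal k.
#' @return A [kmer_list()].
#' @export
klist_subtract <- function(a, b) {
  k <- check_same_k(a, b)
  keep <- !(a$kmers %in% b$kmers)
  kmer_list(a$kmers[keep], a$counts[keep], k,
            n_sources = a$n_sources, source_label = a$source_label)
}

#' Intersection of two k-mer lists
#'
#' K-mers present in both lists; the count kept is the minimum of the two
#' counts (the most conservative shared multiplicity).
#'
#' @param a,b [kmer_list()] objects with equal k.
#' @return A [kmer_list()].
#' @export
klist_intersect <- function(a, b) {
  k <- check_same_k(a, b)
  idx <- match(a$kmers, b$kmers)
  keep <- !is.na(idx)
  kmer_list(a$kmers[keep], pmin(a$counts[keep], b$counts[idx[keep]]), k,
            n_sources = a$n_sources, source_label = a$source_label)
}

#' Filter a k-mer list by minimum count
#'
#' Keeps entries whose count is at least `f`, counts preserved.  In the
#' selection pipeline this is applied to non-target read-set lists so that
#' only k-mers genuinely present in the non-target sample (rather than
#' sequencing noise) are subtracted.
#'
#' @param a A [kmer_list()].
#' @param f Minimum count, >= 1.
#' @return A [kmer_list()].
#' @export
klist_filter_min_count <- function(a, f) {
  stopifnot(inherits(a, "kmer_list"))
  if (length(f) != 1L || is.na(f) || f < 1L)
    stop("f must be a single integer >= 1", call. = FALSE)
  keep <- a$counts >= f
  kmer_list(a$kmers[keep], a$counts[keep], a$k,
            n_sources = a$n_sources, source_label = a$source_label)
}
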