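# Mapping a specific-k-mer panel back onto a reference genome and merging
# the occurrences into clustered taxon-specific regions.
#
# Coordinates are 0-based half-open (BED convention) in all outputs;
# human-readable printing shows 1-based inclusive positions.

#' Locate panel k-mers on a reference genome
#'
#' Scans every clean window of every reference record; a window whose
#' canonical form is in the panel yields one hit at the window's forward
#' coordinates, with strand `+` when the forward window itself is the
#' canonical form and `-` when only its reverse complement is
#' (reverse-complement palindromes report `+`).  A panel k-mer occurring
#' at several reference positions contributes one hit per position.
#'
#' @param panel A non-empty [kmer_list()].
#' @param reference Path to a reference FASTA (possibly multi-record).
#' @return A data frame of hits with columns `ref_id`, `start` (0-based),
#'   `strand`, `kmer` (canonical form), sorted by `(ref_id, start)`.
#' @export
locate_kmers <- function(panel, reference) {
  stopifnot(inherits(panel, "kmer_list"))
  if (length(panel) == 0L) stop("panel is empty", call. = FALSE)
  seqs <- read_seqs(reference)
  if (length(seqs) == 0L)
    stop("reference contains no sequences: ", reference, call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  ids <- sub("[ \t].*$", "", names(seqs))  # first word, BED-style
  k <- panel$k
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    w <- kmer_windows(seqs[[i]], k)
    canon <- canonical_fast(w$window)
    sel <- canon %in% panel$kmers
    if (!any(sel)) next
    out[[i]] <- data.frame(
      ref_id = ids[i],
      start = w$start[sel],
      strand = ifelse(w$window[sel] == canon[sel], "+", "-"),
      kmer = canon[sel])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(ref_id = character(0), start = integer(0),
                      strand = character(0), kmer = character(0)))
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$ref_id, hits$start, method = "radix"), ]
  rownames(hits) <- NULL
  hits
}

#' Merge k-mer hits into clustered taxon-specific regions
#'
#' Hits whose k-length intervals overlap or touch (next start within k of
#' the previous start) are merged into one maximal cluster region, so a
#' run of n hits at consecutive start positions spans `n + k - 1` bp.
#' Gaps are the distances between the end of one cluster and the start of
#' the next on the same reference.
#'
#' @param hits A sorted hit data frame from [locate_kmers()].
#' @param k The panel's k-mer length.
#' @return An object of class `cluster_report` with fields `clusters` (a
#'   data frame: `ref_id`, `start`, `end` 0-based half-open, `n_kmers`,
#'   `span`) and `gaps` (a data frame: `ref_id`, `gap` for each adjacent
#'   cluster pair).
#' @export
#' @examples
#' hits <- data.frame(ref_id = "chr", start = c(10L, 11L, 12L),
#'                    strand = "+", kmer = NA)
#' cluster_hits(hits, k = 32)  # one cluster [10, 44), span 34
cluster_hits <- function(hits, k) {
  k <- check_k(k)
  stopifnot(is.data.frame(hits), all(c("ref_id", "start") %in% names(hits)))
  clusters <- NULL
  gaps <- NULL
  for (id in unique(hits$ref_id)) {
    s <- hits$start[hits$ref_id == id]
    if (is.unsorted(s))
      stop("hits must be sorted by start within each reference",
           call. = FALSE)
    ir <- IRanges::IRanges(start = s + 1L, width = k)
    red <- IRanges::reduce(ir)   # merges overlapping and adjacent intervals
    n_in <- IRanges::countOverlaps(red, ir, type = "any")
    cl <- data.frame(ref_id = id,
                     start = IRanges::start(red) - 1L,
                     end = IRanges::end(red),
                     n_kmers = n_in,
                     span = IRanges::width(red))
    clusters <- rbind(clusters, cl)
    if (nrow(cl) > 1L)
      gaps <- rbind(gaps, data.frame(
        ref_id = id,
        gap = cl$start[-1L] - cl$end[-nrow(cl)]))
  }
  if (is.null(gaps))
    gaps <- data.frame(ref_id = character(0), gap = integer(0))
  structure(list(clusters = clusters, gaps = gaps, k = k),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cl <- x$clusters
  cat(sprintf("cluster_report: %d clustered region(s) of %d-mer hits\n",
              nrow(cl), x$k))
  if (nrow(cl)) {
    cat(sprintf("  spans %d-%d bp (mean %.1f, median %.1f); %d-%d k-mers per cluster\n",
                min(cl$span), max(cl$span), mean(cl$span),
                stats::median(cl$span), min(cl$n_kmers), max(cl$n_kmers)))
    if (nrow(x$gaps))
      cat(sprintf("  gaps between adjacent clusters: %d-%d bp\n",
                  min(x$gaps$gap), max(x$gaps$gap)))
    show <- utils::head(cl, 5L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %s:%d-%d (1-based %d..%d)  %d k-mers\n",
                  show$ref_id[i], show$start[i], show$end[i],
                  show$start[i] + 1L, show$end[i], show$n_kmers[i]))
    if (nrow(cl) > nrow(show)) cat("  ...", nrow(cl) - nrow(show), "more\n")
  }
  invisible(x)
}

#' Write clustered regions as BED6
#'
#' One line per cluster: `ref<TAB>start<TAB>end<TAB>cluster_id<TAB>n_kmers<TAB>.`.
#' Gaps are written alongside as `<out>.gaps.tsv` (`ref_id<TAB>gap`).
#'
#' @param report A `cluster_report` from [cluster_hits()].
#' @param out Output BED path.
#' @return `out`, invisibly.
#' @export
write_cluster_bed <- function(report, out) {
  stopifnot(inherits(report, "cluster_report"))
  cl <- report$clusters
  lines <- sprintf("%s\t%d\t%d\tcluster_%d\t%d\t.",
                   cl$ref_id, cl$start, cl$end, seq_len(nrow(cl)),
                   cl$n_kmers)
  con <- file(out, "wb"); writeLines(lines, con, sep = "\n"); close(con)
  gp <- report$gaps
  con <- file(paste0(out, ".gaps.tsv"), "wb")
  writeLines(c("ref_id\tgap",
               if (nrow(gp)) sprintf("%s\t%d", gp$ref_id, gp$gap)),
             con, sep = "\n")
  close(con)
  invisible(out)
}
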