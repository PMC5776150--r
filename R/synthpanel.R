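# Synthetic plastome-like genome panels with a brute-force ground-truth
# oracle, and simple error-bearing read simulation.  The generator mirrors
# the data regime the pipeline was designed for: several near-identical
# target genomes, phylogenetically close non-targets, and two identical
# inverted-repeat blocks that are conserved across all taxa (so no
# taxon-specific k-mer can ever fall inside them).

#' Parameters of a synthetic plastome panel
#'
#' The genome is assembled as LSC + IR_A + SSC + IR_B with IR_B the exact
#' reverse complement of IR_A; both IR copies are held identical across
#' all taxa (the inverted repeat is highly conserved in real plastomes),
#' so all divergence is placed in the single-copy regions.  Target genomes
#' share `n_private_variants` planted substitutions (the signal the
#' selector must recover) plus independent intra-taxon substitutions;
#' non-targets diverge independently from the same ancestor.  The mutation
#' model is substitution-only, which keeps the exhaustive window oracle
#' exact.
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param lsc_len,ssc_len,ir_len Region lengths in bp (total genome
#'   `lsc + 2*ir + ssc`); defaults give a 20 kb toy plastome.
#' @param n_targets,n_nontargets Number of target / non-target genomes.
#' @param target_intra_divergence Substitutions per single-copy bp among
#'   target individuals (plastomes are nearly invariant within species).
#' @param nontarget_divergence Substitutions per single-copy bp between
#'   the ancestor and each non-target (percent-level, as between close
#'   congeners).
#' @param n_private_variants Target-private substitutions shared by all
#'   targets, placed in single-copy regions.
#' @param read_length,error_rate,n_reads Read simulation parameters:
#'   read length in bp, per-base substitution error rate, number of reads.
#' @param k,min_targets Selection parameters the truth panel is computed
#'   for.
#' @return An object of class `panel_params`.
#' @export
panel_params <- function(seed = 1L, lsc_len = 11000L, ssc_len = 3000L,
                         ir_len = 3000L, n_targets = 5L, n_nontargets = 10L,
                         target_intra_divergence = 5e-4,
                         nontarget_divergence = 0.02,
                         n_private_variants = 12L,
                         read_length = 100L, error_rate = 2e-3,
                         n_reads = 5000L, k = 32L, min_targets = 2L) {
  p <- list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
            ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
            n_targets = as.integer(n_targets),
            n_nontargets = as.integer(n_nontargets),
            target_intra_divergence = target_intra_divergence,
            nontarget_divergence = nontarget_divergence,
            n_private_variants = as.integer(n_private_variants),
            read_length = as.integer(read_length),
            error_rate = error_rate, n_reads = as.integer(n_reads),
            k = check_k(k), min_targets = as.integer(min_targets))
  stopifnot(p$lsc_len > 0L, p$ssc_len > 0L, p$ir_len > 0L,
            p$n_targets >= 1L, p$n_nontargets >= 0L,
            p$target_intra_divergence >= 0, p$target_intra_divergence < 1,
            p$nontarget_divergence >= 0, p$nontarget_divergence < 1,
            p$error_rate >= 0, p$error_rate < 1,
            p$n_private_variants >= 0L, p$n_reads >= 0L,
            p$read_length > 0L, p$min_targets >= 1L,
            p$min_targets <= p$n_targets)
  structure(p, class = "panel_params")
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Substitute bases[pos] with alleles; alleles must differ from the
# reference base at each position.
apply_substitutions <- function(bases, pos, alleles) {
  bases[pos] <- alleles
  bases
}

# Draw a random non-reference base for each position.
draw_alt_alleles <- function(ref_bases) {
  vapply(ref_bases, function(b) sample(setdiff(DNA_BASES, b), 1L), "",
         USE.NAMES = FALSE)
}

write_fasta <- function(seq, id, path, width = 70L) {
  starts <- seq.int(1L, nchar(seq), by = width)
  con <- file(path, "wb")
  writeLines(c(paste0(">", id),
               substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))),
             con, sep = "\n")
  close(con)
  invisible(path)
}

#' Generate a synthetic plastome panel with ground truth
#'
#' Builds an ancestral genome, derives target and non-target genomes per
#' [panel_params()], writes one FASTA per genome into `out_dir`, and
#' computes the ground-truth taxon-specific panel by exhaustive window
#' comparison ([oracle_specific_panel()]).  Deterministic for a fixed
#' seed: repeated runs produce byte-identical FASTA files.
#'
#' @param params A [panel_params()].
#' @param out_dir Output directory (created if missing).
#' @return An object of class `panel_truth` with fields `params`,
#'   `target_files`, `nontarget_files`, `genomes` (named character),
#'   `regions` (data frame of LSC/IR_A/SSC/IR_B intervals, 0-based
#'   half-open), `variant_pos` (1-based planted positions),
#'   `truth_panel` (a [kmer_list()]).
#' @export
generate_panel <- function(params, out_dir = tempfile("panel")) {
  stopifnot(inherits(params, "panel_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- params
  total_sc <- p$lsc_len + p$ssc_len
  if (p$n_private_variants > total_sc)
    stop("n_private_variants (", p$n_private_variants,
         ") exceeds available single-copy positions (", total_sc, ")",
         call. = FALSE)
  with_seed(p$seed, {
    lsc <- sample(DNA_BASES, p$lsc_len, replace = TRUE)
    ira <- sample(DNA_BASES, p$ir_len, replace = TRUE)
    ssc <- sample(DNA_BASES, p$ssc_len, replace = TRUE)
    irb <- rev(chartr("ACGT", "TGCA", ira))  # reverse complement, base-wise
    anc <- c(lsc, ira, ssc, irb)
    L <- length(anc)
    # 0-based half-open region table
    b <- cumsum(c(0L, p$lsc_len, p$ir_len, p$ssc_len, p$ir_len))
    regions <- data.frame(region = c("LSC", "IR_A", "SSC", "IR_B"),
                          start = b[1:4], end = b[2:5])
    # single-copy positions, 1-based on the assembled genome
    sc_pos <- c(seq_len(p$lsc_len),
                seq.int(b[3] + 1L, b[4]))
    var_pos <- sort(sample(sc_pos, p$n_private_variants))
    var_alleles <- draw_alt_alleles(anc[var_pos])

    mutate_sc <- function(g, rate, exclude = integer(0)) {
      pool <- setdiff(sc_pos, exclude)
      n_mut <- stats::rbinom(1L, length(pool), rate)
      if (n_mut == 0L) return(g)
      pos <- sample(pool, n_mut)
      apply_substitutions(g, pos, draw_alt_alleles(g[pos]))
    }

    genomes <- character(0)
    for (i in seq_len(p$n_targets)) {
      g <- apply_substitutions(anc, var_pos, var_alleles)
      g <- mutate_sc(g, p$target_intra_divergence, exclude = var_pos)
      genomes[sprintf("target_%02d", i)] <- paste(g, collapse = "")
    }
    for (j in seq_len(p$n_nontargets)) {
      g <- mutate_sc(anc, p$nontarget_divergence)
      genomes[sprintf("nontarget_%02d", j)] <- paste(g, collapse = "")
    }

    target_files <- character(0)
    nontarget_files <- character(0)
    for (nm in names(genomes)) {
      path <- file.path(out_dir, paste0(nm, ".fa"))
      write_fasta(genomes[[nm]], paste(nm, "synthetic plastome"), path)
      if (startsWith(nm, "target_")) target_files <- c(target_files, path)
      else nontarget_files <- c(nontarget_files, path)
    }

    truth <- oracle_specific_panel(
      target_seqs = unname(genomes[startsWith(names(genomes), "target_")]),
      nontarget_seqs = unname(genomes[startsWith(names(genomes), "nontarget_")]),
      k = p$k, m = p$min_targets)

    structure(list(params = p, out_dir = out_dir,
                   target_files = target_files,
                   nontarget_files = nontarget_files,
                   genomes = genomes, regions = regions,
                   variant_pos = var_pos, variant_alleles = var_alleles,
                   truth_panel = truth),
              class = "panel_truth")
  })
}

#' @export
print.panel_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf("panel_truth: %d target + %d non-target synthetic plastomes (%d bp each)\n",
              p$n_targets, p$n_nontargets,
              p$lsc_len + 2L * p$ir_len + p$ssc_len))
  cat(sprintf("  %d planted target-private variant(s); truth panel: %d specific %d-mers (m=%d)\n",
              p$n_private_variants, length(x$truth_panel), p$k,
              p$min_targets))
  cat("  files in:", x$out_dir, "\n")
  invisible(x)
}

# ---- exhaustive oracle ------------------------------------------------------
#
# A deliberately naive second path used as ground truth: per-string
# reverse complement via chartr + column-wise reversal, aggregation via
# table(), set logic via %in%/setdiff on names.  Shares no code with the
# Biostrings/rle-based production path beyond substring windowing.

naive_revcomp <- function(x, k) {
  comp <- chartr("ACGT", "TGCA", x)
  do.call(paste0, lapply(k:1, function(i) substring(comp, i, i)))
}

naive_canonical <- function(x, k) {
  rc <- naive_revcomp(x, k)
  ifelse(x <= rc, x, rc)
}

naive_windows <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) return(character(0))
  w <- substring(seq, 1:(L - k + 1L), k:L)
  w[grepl("^[ACGT]+$", w)]
}

# table() of canonical k-mer occurrences of one sequence
naive_count_table <- function(seq, k) {
  w <- naive_windows(seq, k)
  if (length(w) == 0L) return(table(character(0)))
  table(naive_canonical(w, k))
}

#' Exhaustive ground-truth taxon-specific panel
#'
#' Brute-force reference implementation of the selection pipeline used as
#' ground truth for synthetic panels: compares all windows of all genomes
#' directly (per-genome occurrence tables, presence in >= m targets,
#' removal of every k-mer seen in any non-target genome, and optional
#' removal of k-mers reaching frequency `f` in non-target read sets).
#' Counts on the returned panel are summed occurrences over the target
#' genomes.
#'
#' @param target_seqs Character vector of target genome sequences.
#' @param nontarget_seqs Character vector of non-target genome sequences.
#' @param k k-mer length.
#' @param m Universality cutoff (presence in >= m targets).
#' @param nontarget_read_seqs Optional list of character vectors, one per
#'   read set (each vector the reads of one set).
#' @param f Read-set frequency cutoff (used only when read sets given).
#' @return A [kmer_list()].
#' @export
oracle_specific_panel <- function(target_seqs, nontarget_seqs, k, m,
                                  nontarget_read_seqs = list(), f = 10L) {
  k <- check_k(k)
  stopifnot(m >= 1L, m <= length(target_seqs))
  tabs <- lapply(target_seqs, naive_count_table, k = k)
  presence <- table(unlist(lapply(tabs, names)))
  keep <- names(presence)[presence >= m]
  for (s in nontarget_seqs)
    keep <- setdiff(keep, names(naive_count_table(s, k)))
  for (reads in nontarget_read_seqs) {
    joined_tab <- naive_count_table(paste(reads, collapse = "N"), k)
    keep <- setdiff(keep, names(joined_tab)[joined_tab >= f])
  }
  keep <- sort(keep, method = "radix")
  counts <- Reduce(`+`, lapply(tabs, function(tb) {
    v <- as.integer(tb[keep]); v[is.na(v)] <- 0L; v
  }), integer(length(keep)))
  kmer_list(keep, as.integer(counts), k,
            n_sources = length(target_seqs),
            source_label = sprintf("oracle(k=%d,m=%d)", k, as.integer(m)))
}

#' Simulate error-bearing reads from a genome
#'
#' Draws reads with uniform start positions from either strand, applies
#' independent per-base substitution errors, and writes a FASTQ file with
#' a constant quality string.  Deterministic for a fixed seed.  Not a
#' platform error-profile simulator: errors are uniform and quality
#' values carry no information.
#'
#' @param genome A genome sequence string, or a path to a FASTA file
#'   (first record used).
#' @param params A [panel_params()] supplying `read_length`, `error_rate`
#'   and `n_reads`.
#' @param out Output FASTQ path; gzipped if it ends in `.gz`.
#' @param seed Seed; defaults to `params$seed`.
#' @param n_reads Override for `params$n_reads`.
#' @return `out`, invisibly.
#' @export
simulate_reads <- function(genome, params, out, seed = params$seed,
                           n_reads = params$n_reads) {
  stopifnot(inherits(params, "panel_params"))
  if (file.exists(genome)) genome <- unname(read_seqs(genome)[1L])
  L <- nchar(genome)
  rl <- params$read_length
  if (rl > L)
    stop("read_length (", rl, ") exceeds genome length (", L, ")",
         call. = FALSE)
  n_reads <- as.integer(n_reads)
  con <- if (grepl("\\.gz$", out)) gzfile(out, "wb") else file(out, "wb")
  on.exit(close(con))
  if (n_reads == 0L) {
    writeLines(character(0), con, sep = "\n")
    return(invisible(out))
  }
  with_seed(seed, {
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    minus <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
    seqs <- substring(genome, starts, starts + rl - 1L)
    if (any(minus)) seqs[minus] <- dna_revcomp(seqs[minus])
    if (params$error_rate > 0) {
      flat <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
      err <- which(stats::runif(length(flat)) < params$error_rate)
      if (length(err))
        flat[err] <- draw_alt_alleles(flat[err])
      all <- paste(flat, collapse = "")
      offs <- (seq_len(n_reads) - 1L) * rl
      seqs <- substring(all, offs + 1L, offs + rl)
    }
    qual <- strrep("I", rl)
    recs <- as.vector(rbind(
      sprintf("@sim_%06d/%s/%d", seq_len(n_reads),
              ifelse(minus, "rev", "fwd"), starts),
      seqs, "+", qual))
    writeLines(recs, con, sep = "\n")
  })
  invisible(out)
}
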