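# End-to-end taxon-specific k-mer selection: universality filter over
# target genomes, then two-step removal of non-specific k-mers (non-target
# assemblies, then frequency-filtered non-target read sets).

#' Selection pipeline configuration
#'
#' Bundles the three tunables of the specific k-mer selection pipeline.
#' Defaults correspond to the headline chloroplast run: 32-mers, presence
#' in at least 2 target genomes, and a non-target read frequency cutoff of
#' 10 (high enough to keep k-mers that are genuinely present in a
#' non-target sample while ignoring ones that only arise from sequencing
#' errors).
#'
#' @param k k-mer length, 1..32.
#' @param min_targets Universality cutoff m: minimum number of target
#'   genome files a k-mer must be present in.
#' @param nontarget_read_min_freq Frequency cutoff applied to each
#'   non-target read-set k-mer list before subtraction.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(k = 32L, min_targets = 2L,
                             nontarget_read_min_freq = 10L) {
  k <- check_k(k)
  min_targets <- as.integer(min_targets)
  nontarget_read_min_freq <- as.integer(nontarget_read_min_freq)
  if (is.na(min_targets) || min_targets < 1L)
    stop("min_targets must be >= 1", call. = FALSE)
  if (is.na(nontarget_read_min_freq) || nontarget_read_min_freq < 1L)
    stop("nontarget_read_min_freq must be >= 1", call. = FALSE)
  structure(list(k = k, min_targets = min_targets,
                 nontarget_read_min_freq = nontarget_read_min_freq),
            class = "selection_config")
}

#' @export
print.selection_config <- function(x, ...) {
  cat(sprintf("selection_config: k=%d, min_targets=%d, nontarget_read_min_freq=%d\n",
              x$k, x$min_targets, x$nontarget_read_min_freq))
  invisible(x)
}

#' Select taxon-specific k-mers
#'
#' Runs the full selection pipeline.  One target genome = one file is the
#' unit of presence: a per-file k-mer list is built for every target, the
#' lists are combined keeping k-mers present in at least `min_targets` of
#' them, and non-specific k-mers are then removed in two steps — first
#' every k-mer occurring in any non-target assembly, then every k-mer
#' reaching count `nontarget_read_min_freq` in any non-target read set
#' (each read file filtered separately, so one deep sample cannot mask
#' another's noise).  The result is deterministic for fixed inputs.
#'
#' @param targets Character vector of target genome FASTA paths (>= 1; one
#'   genome per file).
#' @param nontarget_assemblies Character vector of non-target assembly
#'   FASTA paths (may be empty).
#' @param nontarget_readsets Character vector of non-target FASTQ paths
#'   (may be empty).
#' @param config A [selection_config()].
#' @return An object of class `specific_kmer_set` with fields `panel` (a
#'   [kmer_list()]; counts are summed occurrences over the target genomes,
#'   provenance only), `config`, `provenance`, and `steps` (per-step k-mer
#'   counts, ready for a pipeline funnel plot).
#' @export
select_specific <- function(targets, nontarget_assemblies = character(),
                            nontarget_readsets = character(),
                            config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  if (length(targets) < 1L)
    stop("at least one target genome file is required", call. = FALSE)
  if (config$min_targets > length(targets))
    stop("min_targets (", config$min_targets,
         ") exceeds the number of target files (", length(targets), ")",
         call. = FALSE)
  k <- config$k

  steps <- data.frame(step = character(0), n_kmers = integer(0))
  log_step <- function(name, n)
    steps <<- rbind(steps, data.frame(step = name, n_kmers = as.integer(n)))

  target_lists <- lapply(targets, build_kmer_list, k = k)
  for (i in seq_along(targets)) {
    if (length(target_lists[[i]]) == 0L)
      stop("target genome yields an empty k-mer list: ", targets[i],
           call. = FALSE)
    log_step(paste0("target:", basename(targets[i])),
             length(target_lists[[i]]))
  }

  panel <- klist_union_min_presence(target_lists, config$min_targets)
  log_step(sprintf("union(min_presence=%d)", config$min_targets),
           length(panel))

  for (f in nontarget_assemblies) {
    panel <- klist_subtract(panel, build_kmer_list(f, k = k))
    log_step(paste0("minus assembly:", basename(f)), length(panel))
  }
  for (f in nontarget_readsets) {
    reads_list <- klist_filter_min_count(build_kmer_list(f, k = k),
                                         config$nontarget_read_min_freq)
    panel <- klist_subtract(panel, reads_list)
    log_step(sprintf("minus reads(freq>=%d):%s",
                     config$nontarget_read_min_freq, basename(f)),
             length(panel))
  }

  panel$source_label <- sprintf("specific(k=%d,m=%d,f=%d)", k,
                                config$min_targets,
                                config$nontarget_read_min_freq)
  structure(
    list(panel = panel, config = config,
         provenance = list(targets = targets,
                           nontarget_assemblies = nontarget_assemblies,
                           nontarget_readsets = nontarget_readsets),
         steps = steps),
    class = "specific_kmer_set")
}

#' @export
print.specific_kmer_set <- function(x, ...) {
  cat(sprintf("specific_kmer_set: %d taxon-specific %d-mers\n",
              length(x$panel), x$panel$k))
  cat(sprintf("  config: m=%d, read freq cutoff=%d\n",
              x$config$min_targets, x$config$nontarget_read_min_freq))
  cat(sprintf("  inputs: %d target(s), %d non-target assembly(ies), %d non-target read set(s)\n",
              length(x$provenance$targets),
              length(x$provenance$nontarget_assemblies),
              length(x$provenance$nontarget_readsets)))
  cat("  steps:\n")
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("    %-45s %d\n", x$steps$step[i], x$steps$n_kmers[i]))
  invisible(x)
}

#' Sweep the k-mer length
#'
#' Runs [select_specific()] once per k and reports the panel size for
#' each, to pick the k that maximizes the number of taxon-specific
#' k-mers.  The default grid is `{8, 12, 16, 20, 24, 28, 32}`.
#'
#' @inheritParams select_specific
#' @param config_base A [selection_config()] whose `k` is overridden at
#'   each sweep point.
#' @param ks Integer vector of k values, each in 1..32.
#' @return A data frame with columns `k` and `n_specific`.
#' @export
k_sweep <- function(targets, nontarget_assemblies = character(),
                    nontarget_readsets = character(),
                    config_base = selection_config(),
                    ks = c(8L, 12L, 16L, 20L, 24L, 28L, 32L)) {
  ks <- vapply(ks, check_k, integer(1))
  n <- vapply(ks, function(k) {
    cfg <- config_base
    cfg$k <- k
    length(select_specific(targets, nontarget_assemblies,
                           nontarget_readsets, cfg)$panel)
  }, integer(1))
  data.frame(k = ks, n_specific = n)
}
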