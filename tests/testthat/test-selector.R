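test_that("selection pipeline validates its inputs", {
  fa <- write_tmp_fasta(random_dna(100))
  expect_error(select_specific(character(0)), "at least one")
  expect_error(select_specific(fa, config = selection_config(min_targets = 2)),
               "exceeds the number of target files")
  short <- write_tmp_fasta("ACGT")   # shorter than k: empty k-mer list
  expect_error(select_specific(short, config = selection_config(k = 32,
                                                                min_targets = 1)),
               "empty k-mer list")
  expect_error(selection_config(k = 0), "k must be")
  expect_error(selection_config(min_targets = 0), ">= 1")
  expect_error(selection_config(nontarget_read_min_freq = 0), ">= 1")
})

test_that("a target identical to a non-target yields an empty panel", {
  s <- random_dna(300)
  tg <- replicate(3, write_tmp_fasta(s))
  nt <- write_tmp_fasta(s)
  res <- select_specific(tg, nt, config = selection_config(k = 16,
                                                           min_targets = 2))
  expect_length(res$panel, 0L)
  # invariant holds trivially: nothing intersects the non-target list
  expect_length(klist_intersect(res$panel, build_kmer_list(nt, 16)), 0L)
})

test_that("a single target-private substitution is recovered as its covering windows", {
  set.seed(303)
  k <- 16L
  anc <- random_dna(4000)
  pos <- 2000L
  mutated <- anc
  substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                       substr(anc, pos, pos))[1]
  tg <- replicate(3, write_tmp_fasta(mutated))
  nt <- lapply(1:2, function(i) write_tmp_fasta(anc))
  res <- select_specific(tg, unlist(nt),
                         config = selection_config(k = k, min_targets = 2))
  expect_lte(length(res$panel), k)
  want <- oracle_specific_panel(rep(mutated, 3), rep(anc, 2), k = k, m = 2)
  expect_equal(res$panel$kmers, want$kmers)
  expect_equal(res$panel$counts, want$counts)
  # every panel k-mer is a window covering the variant
  hits <- locate_kmers(res$panel, tg[1])
  expect_true(all(hits$start < pos & hits$start + k >= pos))
})

test_that("non-target read sets remove k-mers only at or above the frequency cutoff", {
  set.seed(304)
  k <- 8L
  genome <- random_dna(200)
  tg <- replicate(2, write_tmp_fasta(genome))
  noisy <- substr(genome, 50, 57)     # one target window seen often in reads
  rare <- substr(genome, 120, 127)    # another seen below the cutoff
  reads <- c(rep(noisy, 12), rep(rare, 5))
  fq <- write_tmp_fastq(reads)
  cfg <- selection_config(k = k, min_targets = 2,
                          nontarget_read_min_freq = 10)
  res <- select_specific(tg, nontarget_readsets = fq, config = cfg)
  expect_false(oracle_canonical(noisy) %in% res$panel$kmers)
  expect_true(oracle_canonical(rare) %in% res$panel$kmers)
  # with the cutoff above every read count nothing is removed
  cfg99 <- selection_config(k = k, min_targets = 2,
                            nontarget_read_min_freq = 99)
  res99 <- select_specific(tg, nontarget_readsets = fq, config = cfg99)
  expect_true(all(c(oracle_canonical(noisy), oracle_canonical(rare))
                  %in% res99$panel$kmers))
})

test_that("panel size is non-increasing in m and in the non-target set", {
  pp <- panel_params(seed = 9, lsc_len = 2500, ssc_len = 800, ir_len = 600,
                     n_targets = 4, n_nontargets = 5,
                     n_private_variants = 5, k = 16, min_targets = 1)
  tr <- generate_panel(pp)
  sizes_m <- vapply(1:4, function(m)
    length(select_specific(tr$target_files, tr$nontarget_files,
                           config = selection_config(k = 16,
                                                     min_targets = m))$panel),
    integer(1))
  expect_true(all(diff(sizes_m) <= 0))
  sizes_nt <- vapply(c(1, 3, 5), function(n)
    length(select_specific(tr$target_files, tr$nontarget_files[seq_len(n)],
                           config = selection_config(k = 16,
                                                     min_targets = 2))$panel),
    integer(1))
  expect_true(all(diff(sizes_nt) <= 0))
  # per-step log shrinks monotonically after the union step
  res <- select_specific(tr$target_files, tr$nontarget_files,
                         config = selection_config(k = 16, min_targets = 2))
  after_union <- res$steps$n_kmers[-seq_along(tr$target_files)]
  expect_true(all(diff(after_union) <= 0))
})

test_that("the k sweep runs the pipeline per k and matches the exhaustive oracle", {
  pp <- panel_params(seed = 10, lsc_len = 1800, ssc_len = 600, ir_len = 400,
                     n_targets = 3, n_nontargets = 4,
                     n_private_variants = 4, min_targets = 2)
  tr <- generate_panel(pp)
  ks <- c(8L, 16L, 32L)
  sw <- k_sweep(tr$target_files, tr$nontarget_files,
                config_base = selection_config(min_targets = 2), ks = ks)
  expect_equal(sw$k, ks)
  tg <- unname(tr$genomes[startsWith(names(tr$genomes), "target_")])
  nt <- unname(tr$genomes[startsWith(names(tr$genomes), "nontarget_")])
  want <- vapply(ks, function(k)
    length(oracle_specific_panel(tg, nt, k = k, m = 2)), integer(1))
  expect_equal(sw$n_specific, want)
  # identical genomes give zero at every k
  same <- replicate(3, write_tmp_fasta(tr$genomes[[1]]))
  sw0 <- k_sweep(same[1:2], same[3],
                 config_base = selection_config(min_targets = 2), ks = ks)
  expect_equal(sw0$n_specific, c(0L, 0L, 0L))
})
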