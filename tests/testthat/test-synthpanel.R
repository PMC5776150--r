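test_that("generated panels are deterministic and structurally correct", {
  pp <- small_params(seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- generate_panel(pp, d1)
  t2 <- generate_panel(pp, d2)
  for (f in basename(t1$target_files))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  expect_identical(t1$truth_panel$kmers, t2$truth_panel$kmers)
  g <- t1$genomes[[1]]
  r <- t1$regions
  expect_equal(nchar(g), sum(r$end - r$start))
  # IR_B is the reverse complement of IR_A, in every genome
  for (gm in t1$genomes) {
    ira <- substr(gm, r$start[r$region == "IR_A"] + 1, r$end[r$region == "IR_A"])
    irb <- substr(gm, r$start[r$region == "IR_B"] + 1, r$end[r$region == "IR_B"])
    expect_equal(irb, oracle_revcomp(ira))
  }
  # IR blocks are identical across all taxa
  irs <- vapply(t1$genomes, function(gm)
    substr(gm, r$start[r$region == "IR_A"] + 1, r$end[r$region == "IR_A"]), "")
  expect_length(unique(irs), 1L)
  # planted variants sit in single-copy regions and are shared by targets
  in_sc <- (t1$variant_pos <= r$end[r$region == "LSC"]) |
    (t1$variant_pos > r$start[r$region == "SSC"] &
       t1$variant_pos <= r$end[r$region == "SSC"])
  expect_true(all(in_sc))
  tg <- t1$genomes[startsWith(names(t1$genomes), "target_")]
  for (i in seq_along(t1$variant_pos)) {
    p <- t1$variant_pos[i]
    expect_true(all(vapply(tg, function(gm) substr(gm, p, p), "")
                    == t1$variant_alleles[i]))
  }
})

test_that("identical genomes give an empty truth panel; a single variant gives its windows", {
  t0 <- generate_panel(small_params(seed = 5, target_intra_divergence = 0,
                                    nontarget_divergence = 0,
                                    n_private_variants = 0L))
  expect_length(t0$truth_panel, 0L)
  # pipeline agrees on the degenerate case
  res0 <- select_specific(t0$target_files, t0$nontarget_files,
                          config = selection_config(k = 32, min_targets = 2))
  expect_length(res0$panel, 0L)
  t1 <- generate_panel(small_params(seed = 6, target_intra_divergence = 0,
                                    nontarget_divergence = 0,
                                    n_private_variants = 1L))
  expect_lte(length(t1$truth_panel), 32L)
  expect_gt(length(t1$truth_panel), 0L)
  res1 <- select_specific(t1$target_files, t1$nontarget_files,
                          config = selection_config(k = 32, min_targets = 2))
  expect_equal(res1$panel$kmers, t1$truth_panel$kmers)
  expect_equal(res1$panel$counts, t1$truth_panel$counts)
})

test_that("no truth-panel k-mer ever lies inside an identical IR block", {
  for (seed in c(31, 32)) {
    tr <- generate_panel(small_params(seed = seed, n_private_variants = 6L))
    if (length(tr$truth_panel) == 0L) next
    hits <- locate_kmers(tr$truth_panel, tr$target_files[1])
    r <- tr$regions
    for (ir in c("IR_A", "IR_B")) {
      s <- r$start[r$region == ir]; e <- r$end[r$region == ir]
      inside <- hits$start >= s & (hits$start + tr$params$k) <= e
      expect_false(any(inside))
    }
  }
})

test_that("the generator refuses more private variants than single-copy positions", {
  expect_error(generate_panel(small_params(n_private_variants = 10000L)),
               "exceeds available single-copy positions")
})

test_that("simulated reads are deterministic and cover the genome when error-free", {
  pp <- small_params(seed = 41, n_reads = 2000L, error_rate = 0)
  tr <- generate_panel(pp)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  simulate_reads(tr$genomes[[1]], pp, f1)
  simulate_reads(tr$genomes[[1]], pp, f2)
  expect_identical(readLines(f1), readLines(f2))
  # deep error-free coverage: every interior genome k-mer appears among the
  # read k-mers (the few windows at the genome ends can only be covered by
  # reads starting at the first/last positions, so they are excluded), and
  # conversely every read k-mer occurs in the genome
  g <- tr$genomes[[1]]
  core <- substr(g, pp$read_length, nchar(g) - pp$read_length)
  core_list <- build_kmer_list(write_tmp_fasta(core), 32)
  genome_list <- build_kmer_list(tr$target_files[1], 32)
  read_list <- build_kmer_list(f1, 32)
  expect_length(klist_subtract(core_list, read_list), 0L)
  expect_length(klist_subtract(read_list, genome_list), 0L)
  # empty and invalid requests
  e <- tempfile(fileext = ".fq")
  simulate_reads(tr$genomes[[1]], pp, e, n_reads = 0)
  expect_length(readLines(e), 0L)
  expect_error(simulate_reads(random_dna(50), pp, tempfile()),
               "exceeds genome length")
})

test_that("sequencing errors create spurious non-target detections that grow with read number", {
  pp <- small_params(seed = 55, lsc_len = 4000L, ssc_len = 1200L,
                     ir_len = 800L, n_private_variants = 8L,
                     error_rate = 6e-3, read_length = 100L)
  tr <- generate_panel(pp)
  expect_gt(length(tr$truth_panel), 0L)
  nt_genome <- tr$genomes[["nontarget_01"]]
  shallow <- tempfile(fileext = ".fq"); deep <- tempfile(fileext = ".fq")
  simulate_reads(nt_genome, pp, shallow, seed = 56, n_reads = 500L)
  simulate_reads(nt_genome, pp, deep, seed = 56, n_reads = 15000L)
  d_shallow <- detected_at_cutoffs(count_in_reads(tr$truth_panel, shallow))
  d_deep <- detected_at_cutoffs(count_in_reads(tr$truth_panel, deep))
  expect_gte(d_deep$n_detected[1], d_shallow$n_detected[1])
  expect_gt(d_deep$n_detected[1], 0L)   # errors do produce panel k-mers
})
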