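# Shared small synthetic-panel configuration: a 4 kb toy plastome that
# keeps the exhaustive oracle fast while retaining the LSC/IR/SSC/IR
# structure and both divergence regimes.
small_params <- function(...) {
  defaults <- list(seed = 1L, lsc_len = 2000L, ssc_len = 700L, ir_len = 500L,
                   n_targets = 3L, n_nontargets = 4L,
                   target_intra_divergence = 5e-4,
                   nontarget_divergence = 0.02, n_private_variants = 4L,
                   read_length = 80L, error_rate = 0, n_reads = 500L,
                   k = 32L, min_targets = 2L)
  do.call(panel_params, utils::modifyList(defaults, list(...)))
}
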