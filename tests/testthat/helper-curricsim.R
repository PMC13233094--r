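# small configurations used across test files
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_networks = 30L, d = 30L, n_eval = 200L, n_test = 500L,
                   master_seed = 7L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# binomial standard error helper
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
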