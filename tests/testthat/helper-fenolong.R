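# Shared helpers for the test suite.

# Reference session parameters used in many oracle checks.
ref_params <- function() no_params(1.5, 3.5, 2.5)

# A small noise-free session: exact two-compartment FeNO on the standard
# flow schedule.
noise_free_session <- function(params = ref_params(),
                               flows = flow_schedule("standard")) {
  list(flow = flows, feno = feno_2cm(params, flows))
}

# Quick MCMC configuration for unit tests (not for inference quality).
test_mcmc <- function(seed = 1, n_chains = 1, n_warmup = 400, n_iter = 600) {
  mcmc_config(n_chains = n_chains, n_warmup = n_warmup, n_iter = n_iter,
              seed = seed)
}
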