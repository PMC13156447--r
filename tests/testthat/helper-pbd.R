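# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

std_seq_low <- function(L = 8) {
  sequence_params(TR = 10.9, alpha = 20, theta = 2, moment_pi = 2, L = L)
}

std_seq_high <- function(L = 8) {
  sequence_params(TR = 10.9, alpha = 20, theta = 2, moment_pi = 14, L = L)
}

# converged-model lookup over the default fit box (expensive; build once)
std_lookup <- function() {
  if (is.null(.fixture_env$lookup))
    .fixture_env$lookup <- build_phase_lookup(std_seq_low(), std_seq_high())
  .fixture_env$lookup
}

std_tissue <- function() tissue_params(T1 = 1000, T2 = 120, D = 1300)

# model phases for a tissue vector at the standard protocol (converged L)
std_phases <- function(T2, D, T1 = 1000) {
  ts <- tissue_params(T1 = T1, T2 = T2, D = D, allow_t2_gt_t1 = TRUE)
  list(phi_L = Arg(steady_state_signal(ts, std_seq_low(L = 32))),
       phi_H = Arg(steady_state_signal(ts, std_seq_high(L = 32))))
}
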