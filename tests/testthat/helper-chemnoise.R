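# shared objects for the test suite: the wild-type parameter set and its
# adapted state are computed once
wt <- pathway_params()
wt_ss <- solve_steady_state(wt, 0)

# log-bin a spectrum for noise-tolerant comparisons
log_bin <- function(omega, S, n_bins = 20) {
  br <- exp(seq(log(min(omega)), log(max(omega) * 1.0001),
                length.out = n_bins + 1))
  g <- cut(omega, br)
  list(omega = as.vector(tapply(omega, g, mean)),
       S = as.vector(tapply(S, g, mean)))
}
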