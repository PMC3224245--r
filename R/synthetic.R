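# Synthetic tethered-cell-like motor traces and parameter-recovery
# fixtures. Every generated object carries its generating parameters and
# seed.

#' Generate a tethered-cell-like binary motor trace
#'
#' Simulates the noisy pathway (CheY-P Langevin fluctuations driving
#' time-varying motor switching rates) with the motor as a discrete
#' two-state telegraph process, sampled at video-like rate.
#'
#' @param params a [pathway_params()] object.
#' @param T_total trace length, s.
#' @param seed RNG seed.
#' @param dt_sample sampling interval of the output, s.
#' @param dt integration step, s.
#' @param c0 background concentration, mM.
#' @param sources noise sources driving the pathway upstream of the
#'   motor (the motor itself switches stochastically regardless);
#'   set `character(0)` for a constant-rate control trace.
#' @return a binary `chemnoise_timeseries` with provenance attributes
#'   `params` and `seed`.
#' @export
generate_motor_trace <- function(params, T_total = 1e3, seed = 1,
                                 dt_sample = 1 / 60, dt = 1e-4, c0 = 0,
                                 sources = setdiff(.all_sources,
                                                   "motor_switching")) {
  ss <- solve_steady_state(params, c0, "full")
  sample_every <- max(1L, round(dt_sample / dt))
  ts <- simulate_langevin(params, make_constant(c0), seed = seed, dt = dt,
                          T_total = T_total, sample_every = sample_every,
                          sources = union(sources, "motor_switching"),
                          discrete_motor = TRUE, ss = ss)
  attr(ts, "params") <- params
  attr(ts, "ss") <- ss
  ts
}

#' Recover the motor switching frequency from a binary trace
#'
#' Estimates the PSD of the CW/CCW trace and fits a Lorentzian; its
#' corner is `omega_X = k+ + k-`.
#'
#' @param trace a binary motor `chemnoise_timeseries`.
#' @param n_segments periodogram segments.
#' @param omega_range fit range, rad/s.
#' @return list with `omega_X` and the Lorentzian fit.
#' @export
recover_omega_x <- function(trace, n_segments = 16,
                            omega_range = c(0.05, 30)) {
  spec <- estimate_psd(trace, n_segments, observables = "X")
  keep <- spec$omega >= omega_range[1] & spec$omega <= omega_range[2]
  om <- spec$omega[keep]
  S <- spec$total[keep, "X"]
  # log-bin so the fit weights decades evenly and averages noise
  br <- exp(seq(log(min(om)), log(max(om) * 1.0001), length.out = 31))
  g <- cut(om, br)
  omb <- as.vector(tapply(om, g, mean))
  Sb <- as.vector(tapply(S, g, mean))
  ok <- !is.na(omb) & !is.na(Sb)
  fit <- fit_lorentzian(omb[ok], Sb[ok])
  list(omega_X = fit$omega_c, fit = fit, spectrum = spec)
}

#' Recover the adaptation frequency from an impulse response
#'
#' An attractant impulse produces a fast negative activity spike followed
#' by a slow opposite-sign lobe: the methylation accumulated during the
#' spike relaxes back at the adaptation frequency. `omega_M` is recovered
#' from a log-linear fit of that slow lobe's exponential decay.
#'
#' @param ts deterministic impulse-response `chemnoise_timeseries`.
#' @param observable column to fit.
#' @param settle time after the fast-spike extremum at which the slow
#'   lobe is considered settled, s.
#' @param frac_window fit window as fractions of the slow-lobe peak.
#' @return list with `omega_M` and the fitted time range.
#' @export
recover_omega_m <- function(ts, observable = "A_c", settle = 2,
                            frac_window = c(0.05, 0.9)) {
  x <- ts[[observable]]
  dev <- x - x[1]
  t_fast <- ts$t[which.max(abs(dev))]
  slow <- which(ts$t > t_fast + settle)
  ipk <- slow[which.max(abs(dev[slow]))]
  sgn <- sign(dev[ipk])
  amp <- abs(dev[ipk])
  tail_idx <- which(seq_along(dev) >= ipk & sign(dev) == sgn &
                    abs(dev) >= frac_window[1] * amp &
                    abs(dev) <= frac_window[2] * amp)
  if (length(tail_idx) < 10) stop("recovery tail too short to fit")
  fit <- lm(log(abs(dev[tail_idx])) ~ ts$t[tail_idx])
  list(omega_M = -unname(coef(fit)[2]),
       t_range = range(ts$t[tail_idx]))
}

#' Parameter-recovery fixture
#'
#' Bundles a deterministic impulse response and a long binary motor trace
#' generated from known parameters, together with the true
#' characteristic frequencies, as an end-to-end surface for the analysis
#' pipeline: fitting the bundle must recover `omega_M` (from the impulse
#' response) and `omega_X` (from the motor-trace PSD).
#'
#' @param params a [pathway_params()] object.
#' @param seed RNG seed.
#' @param T_trace motor-trace length, s.
#' @param impulse impulse stimulus for the response part.
#' @return list of class `recovery_fixture` with elements
#'   `impulse_response`, `motor_trace`, `truth` (list with `omega_M`,
#'   `omega_X`, `Yp_star_uM`), `params` and `seed`.
#' @export
parameter_recovery_fixture <- function(params = pathway_params(),
                                       seed = 1, T_trace = 1e4,
                                       impulse = make_impulse()) {
  ss <- solve_steady_state(params, impulse$c0, "full")
  imp <- integrate_deterministic(params, impulse, dt = 1e-3,
                                 T_total = 100, ss = ss)
  trace <- generate_motor_trace(params, T_total = T_trace, seed = seed)
  # the generator's true adaptation frequency is the slow relaxation
  # eigenvalue of the full linearized pathway (the CheB-P feedback makes
  # it somewhat faster than the bare methylation estimate omega_M)
  ev <- linearize_full(params, ss)$eigenvalues
  omega_M_true <- -max(Re(ev))
  out <- list(impulse_response = imp, motor_trace = trace,
              truth = list(omega_M = omega_M_true,
                           omega_M_methylation = ss$omega_M,
                           omega_X = ss$omega_X,
                           Yp_star_uM = ss$Yp_uM),
              params = params, seed = seed)
  class(out) <- "recovery_fixture"
  out
}

#' Write a recovery fixture to a directory of CSVs with a JSON manifest
#'
#' @param fixture a [parameter_recovery_fixture()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chemnoise_csv(fixture$impulse_response,
                      file.path(dir, "impulse_response.csv"))
  write_chemnoise_csv(fixture$motor_trace,
                      file.path(dir, "motor_trace.csv"))
  manifest <- list(seed = fixture$seed, truth = fixture$truth,
                   params = params_table(fixture$params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
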