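# Integrated signal response, band-limited variance, SNR, parameter
# sweeps and fluctuation-response analysis.

#' Integrated squared response to a stimulus
#'
#' `Delta_R^2 = (1/2pi) Int |chi(omega) dc_hat(omega)|^2 domega` over the
#' real line, evaluated by trapezoidal quadrature on the response curve's
#' (log-spaced) frequency grid using the stimulus' squared-modulus
#' transform (`ft_sq_smooth` -- the oscillation-averaged density -- when
#' available).
#'
#' @param chi a `response_curve` on a dense positive frequency grid.
#' @param stimulus a stimulus object with an analytic transform.
#' @param observable which observable of `chi` to integrate (default the
#'   last, i.e. the motor for full-pathway curves).
#' @return the integrated squared response (observable units squared).
#' @export
integrated_response <- function(chi, stimulus,
                                observable = utils::tail(chi$labels, 1)) {
  ftsq <- if (!is.null(stimulus$ft_sq_smooth)) stimulus$ft_sq_smooth
          else stimulus$ft_sq
  if (is.null(ftsq)) stop("stimulus has no square-integrable transform")
  y <- chi$magnitude[, observable]^2 * ftsq(chi$omega)
  if (any(!is.finite(y))) stop("non-integrable response-stimulus product")
  # even integrand: twice the positive-half integral
  2 * .trapz(chi$omega, y) / (2 * pi)
}

#' Band-limited variance from a spectrum
#'
#' `(1/2pi) Int_{-1/tau}^{1/tau} S(omega) domega` per observable and, when
#' the spectrum carries them, per source component. Spectra are flat at
#' zero frequency, so the interval below the grid minimum contributes its
#' rectangle.
#'
#' @param spectrum a `chemnoise_spectrum` whose grid covers the band.
#' @param tau_band observation time tau, s; the band edge is `1/tau_band`
#'   rad/s (`tau_band = 0` integrates the whole grid).
#' @param observable observable name; default the last (motor).
#' @return list with `total` and (if available) named `components`.
#' @export
variance_in_band <- function(spectrum, tau_band = 1,
                             observable = utils::tail(spectrum$labels, 1)) {
  wb <- if (tau_band <= 0) Inf else 1 / tau_band
  omega <- spectrum$omega
  if (is.finite(wb) && wb > max(omega) * (1 + 1e-12))
    stop("band edge exceeds the spectrum grid")
  estimated <- identical(spectrum$meta$kind, "estimated")
  half_int <- function(S) {
    if (estimated) {
      # periodogram bins: the discrete Parseval sum over the (uniform)
      # frequency grid; the DC bin was removed by demeaning and the
      # Nyquist bin is counted once
      keep <- omega <= wb
      dom <- omega[2] - omega[1]
      s <- 2 * sum(S[keep])
      if (max(omega) <= wb) s <- s - S[length(S)]
      return(s * dom / (2 * pi))
    }
    if (is.infinite(wb)) { w <- omega; y <- S }
    else {
      keep <- omega <= wb
      w <- omega[keep]; y <- S[keep]
      if (max(w) < wb) {  # interpolate the band edge
        S_edge <- stats::approx(omega, S, xout = wb)$y
        w <- c(w, wb); y <- c(y, S_edge)
      }
    }
    S0 <- y[1]  # flat continuation below the grid minimum
    (S0 * w[1] + .trapz(w, y)) / pi
  }
  out <- list(total = half_int(spectrum$total[, observable]))
  if (!is.null(spectrum$components))
    out$components <- vapply(spectrum$components,
                             function(cm) half_int(cm[, observable]), 0)
  out
}

# frequency grid adapted to a steady state's characteristic frequencies
.adapted_grid <- function(ss, omega_max = NULL, n = 1200) {
  lo <- min(1e-4, ss$omega_M / 300)
  hi <- max(1e3, 300 * ss$omega_X)
  if (!is.null(omega_max)) hi <- max(hi, omega_max)
  make_omega_grid(lo, hi, n)
}

#' Signal-to-noise ratio at the motor
#'
#' `SNR = Delta_X^2 / <delta X^2>`: the integrated squared motor response
#' to the stimulus divided by the band-limited variance of the noise
#' transmitted to the motor. Following the convention of the sweep
#' figures, the transmitted variance includes receptor switching, ligand
#' diffusion, methylation and phosphorylation, but not the motor's own
#' switching noise unless `include_motor_noise = TRUE`.
#'
#' @param params a [pathway_params()] object.
#' @param stimulus a stimulus object; its background sets the adapted
#'   state.
#' @param tau_band observation time for the variance band, s.
#' @param include_motor_noise include the motor-switching component in
#'   the denominator.
#' @param ss,linsys optional precomputed steady state / linear system.
#' @return list of class `snr_result` with `snr`, `delta_X2`,
#'   `variance` (total used) and per-source `components`.
#' @export
snr_at_motor <- function(params, stimulus, tau_band = 1,
                         include_motor_noise = FALSE, ss = NULL,
                         linsys = NULL) {
  if (is.null(ss)) ss <- solve_steady_state(params, stimulus$c0, "full")
  if (is.null(linsys)) linsys <- linearize_full(params, ss)
  grid <- .adapted_grid(ss)
  chi <- response_full(linsys, grid)
  dX2 <- integrated_response(chi, stimulus, "X")
  band_grid <- make_omega_grid(min(1e-4, ss$omega_M / 300),
                               1 / tau_band, 700)
  spec <- spectrum_full(linsys, band_grid)
  v <- variance_in_band(spec, tau_band, "X")
  comps <- v$components
  used <- comps[setdiff(names(comps),
                        if (include_motor_noise) character(0)
                        else "motor_switching")]
  var_used <- sum(used)
  if (var_used <= 0) stop("zero transmitted variance")
  out <- list(snr = dX2 / var_used, delta_X2 = dX2, variance = var_used,
              components = comps, tau_band = tau_band,
              include_motor_noise = include_motor_noise)
  class(out) <- "snr_result"
  out
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR at the motor: %.4g\n", x$snr))
  cat(sprintf("  Delta_X^2 = %.4g, variance (band 1/tau = %g rad/s) = %.4g\n",
              x$delta_X2, 1 / x$tau_band, x$variance))
  invisible(x)
}

#' Sweep receptor complex size and background concentration
#'
#' For each `(c0, N)`: rebuild the complex (fixed total receptor number,
#' `N_C = N_tot/N`, complex diameter `sqrt(N) s_R`), adapt to `c0`, apply
#' a step stimulus of `fraction * c0`, and record the integrated motor
#' response, the per-source transmitted variances and the SNR.
#'
#' @param params base [pathway_params()].
#' @param c0_grid background concentrations, mM.
#' @param N_grid complex sizes (integers >= 1).
#' @param fraction step size as a fraction of `c0`.
#' @param tau_band variance band observation time, s.
#' @return long-format data.frame of class `sweep_result`.
#' @export
sweep_complex_size <- function(params,
                               c0_grid = c(0.02, 0.03, 0.05),
                               N_grid = c(2, 3, 4, 6, 9, 12, 18, 27, 36,
                                          54, 80),
                               fraction = 0.1, tau_band = 1) {
  rows <- list()
  for (N in N_grid) {
    p <- params
    p$mwc$N <- N
    p$gamma_B_simpl <- 18 * p$gamma_R / N^2
    for (c0 in c0_grid) {
      r <- snr_at_motor(p, make_step(c0, fraction), tau_band)
      rows[[length(rows) + 1]] <- data.frame(
        c0 = c0, N = N, delta_X2 = r$delta_X2,
        var_receptor_switching = r$components[["receptor_switching"]],
        var_ligand = r$components[["ligand"]],
        var_methylation = r$components[["methylation"]],
        var_phosphorylation = r$components[["phosphorylation_A"]] +
          r$components[["phosphorylation_Y"]] +
          r$components[["phosphorylation_B"]],
        var_total = r$variance, snr = r$snr)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fraction") <- fraction
  attr(out, "tau_band") <- tau_band
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Sweep the adaptation rate constants
#'
#' Varies the methylation (`gamma_R`) and demethylation (`gamma_B`) rate
#' constants -- emulating cell-to-cell variation in CheR and CheB levels
#' -- and records integrated motor response, transmitted variance and SNR
#' for a step stimulus.
#'
#' @inheritParams sweep_complex_size
#' @param gammaR_grid,gammaB_grid rate-constant grids (1/s and 1/uM^2/s).
#' @param c0 background concentration, mM.
#' @return long-format data.frame of class `sweep_result`.
#' @export
sweep_adaptation <- function(params,
                             gammaR_grid = params$gamma_R *
                               10^seq(-2, 2, length.out = 9),
                             gammaB_grid = params$gamma_B *
                               10^seq(-2, 2, length.out = 9),
                             c0 = 0.1, fraction = 0.1, tau_band = 1) {
  stim <- make_step(c0, fraction)
  rows <- list()
  for (gR in gammaR_grid) {
    for (gB in gammaB_grid) {
      p <- params
      p$gamma_R <- gR
      p$gamma_B <- gB
      p$gamma_B_simpl <- 18 * gR / p$mwc$N^2
      r <- snr_at_motor(p, stim, tau_band)
      rows[[length(rows) + 1]] <- data.frame(
        gamma_R = gR, gamma_B = gB, delta_X2 = r$delta_X2,
        var_receptor_switching = r$components[["receptor_switching"]],
        var_ligand = r$components[["ligand"]],
        var_methylation = r$components[["methylation"]],
        var_phosphorylation = r$components[["phosphorylation_A"]] +
          r$components[["phosphorylation_Y"]] +
          r$components[["phosphorylation_B"]],
        var_total = r$variance, snr = r$snr)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "c0") <- c0
  attr(out, "tau_band") <- tau_band
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Fluctuation-response relationship
#'
#' Varies one pathway parameter, and for each value records the adapted
#' CheY-P concentration, the variance of CheY-P fluctuations (the full
#' integral of the analytic spectrum), the normalised variance, and the
#' adaptation time `1/omega_M`.
#'
#' @param params base [pathway_params()].
#' @param vary `"gamma_R"`, `"gamma_B"` or `"Y_tot"`.
#' @param grid values for the varied parameter.
#' @param c0 background concentration, mM.
#' @return data.frame of class `fluct_response` with columns `value`,
#'   `Yp_star_uM`, `var_Yp_uM2`, `var_norm`, `adaptation_time_s`.
#' @export
fluctuation_response <- function(params,
                                 vary = c("gamma_R", "gamma_B", "Y_tot"),
                                 grid = NULL, c0 = 0) {
  vary <- match.arg(vary)
  if (is.null(grid))
    grid <- params[[vary]] * 10^seq(-1, 1, length.out = 25)
  rows <- lapply(grid, function(v) {
    p <- params
    p[[vary]] <- v
    if (vary == "gamma_R") p$gamma_B_simpl <- 18 * v / p$mwc$N^2
    ss <- solve_steady_state(p, c0, "full")
    sys <- linearize_full(p, ss)
    grid_w <- make_omega_grid(min(1e-6, ss$omega_M / 100), 2e4, 1600)
    spec <- spectrum_full(sys, grid_w)
    var_n <- variance_in_band(spec, tau_band = 0, "N_Yp")$total
    var_uM2 <- var_n * ss$conv^2
    data.frame(value = v, Yp_star_uM = ss$Yp_uM, var_Yp_uM2 = var_uM2,
               var_norm = var_uM2 / ss$Yp_uM^2,
               adaptation_time_s = 1 / ss$omega_M)
  })
  out <- do.call(rbind, rows)
  attr(out, "vary") <- vary
  class(out) <- c("fluct_response", "data.frame")
  out
}

#' Fit a power law by least squares in log-log space
#'
#' @param x,y positive numeric vectors (>= 4 points).
#' @return list with `exponent`, `se` and `prefactor`.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) < 4) stop("need at least 4 points")
  if (any(x <= 0) || any(y <= 0)) stop("x and y must be positive")
  fit <- lm(log(y) ~ log(x))
  s <- suppressWarnings(summary(fit))$coefficients
  list(exponent = unname(s[2, 1]), se = unname(s[2, 2]),
       prefactor = exp(unname(s[1, 1])))
}

#' Receptor-level signal and noise of the simplified model
#'
#' Closed-form building block for the scaling laws: integrated squared
#' activity response to a 10 percent step and the per-source band-limited
#' variance of the total activity, from the simplified-model response and
#' spectrum.
#'
#' @param params a [pathway_params()] object.
#' @param c0 background concentration, mM.
#' @param fraction step fraction.
#' @param tau_band variance band observation time, s.
#' @return list with `delta_A2`, `var` (named per-source vector) and the
#'   steady state used.
#' @export
receptor_signal_noise <- function(params, c0 = 0.02, fraction = 0.1,
                                  tau_band = 1) {
  ss <- solve_steady_state(params, c0, "simplified")
  grid <- make_omega_grid(min(1e-7, ss$omega_M / 1e3),
                          max(1e3, 1e3 * ss$omega_M), 1500)
  chi <- response_simplified(grid, params, ss)
  # observation window long compared to the adaptation time, so the
  # integrated response reaches its pure-step value
  win <- max(1e3, 100 / ss$omega_M)
  dA2 <- integrated_response(chi, make_step(c0, fraction, window = win),
                             "A_c")
  spec <- spectrum_simplified(grid, params, ss)
  v <- variance_in_band(spec, tau_band, "A_c")
  list(delta_A2 = dA2, var = v$components, ss = ss)
}
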