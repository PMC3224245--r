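# Concentration stimuli: impulse, step and sinusoid, with analytic
# Fourier transforms and small-signal validity checks.
#
# Fourier convention: f_hat(omega) = integral f(t) exp(+i omega t) dt,
# matching d/dt -> -i omega in the dynamical equations.

new_stimulus <- function(type, c0, f, ft, ft_sq, pars) {
  s <- list(type = type, c0 = c0, f = f, ft = ft, ft_sq = ft_sq,
            pars = pars)
  class(s) <- "chemnoise_stimulus"
  s
}

#' @export
print.chemnoise_stimulus <- function(x, ...) {
  cat(sprintf("stimulus '%s', background c0 = %g mM\n", x$type, x$c0))
  cat("  ", paste(names(x$pars), signif(unlist(x$pars), 4), sep = " = ",
                  collapse = ", "), "\n")
  invisible(x)
}

#' Triangular concentration impulse
#'
#' Symmetric triangle of the given peak and duration starting at
#' `t_on`; area `peak * duration / 2`. The analytic transform is the
#' squared-sinc form of a triangle, tending to the area as omega -> 0.
#'
#' @param peak peak concentration above background, mM.
#' @param duration impulse duration, s.
#' @param c0 background concentration, mM.
#' @param t_on onset time, s.
#' @return a stimulus object with waveform `f(t)`, transform `ft(omega)`
#'   (complex) and squared modulus `ft_sq(omega)`.
#' @export
make_impulse <- function(peak = 1e-3, duration = 0.02, c0 = 0, t_on = 1) {
  if (peak <= 0 || duration <= 0) stop("peak and duration must be > 0")
  area <- peak * duration / 2
  f <- function(t) {
    u <- t - t_on
    ifelse(u > 0 & u < duration, peak * (1 - abs(2 * u / duration - 1)), 0)
  }
  sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
  ft <- function(omega)
    area * sinc(omega * duration / 4)^2 *
      exp(1i * omega * (t_on + duration / 2))
  ft_sq <- function(omega) (area * sinc(omega * duration / 4)^2)^2
  new_stimulus("impulse", c0, f, ft, ft_sq,
               list(peak = peak, duration = duration, t_on = t_on))
}

#' Step stimulus as a fixed fraction of the background
#'
#' Height `fraction * c0` switched on at `t_on`. A pure step is not
#' square-integrable; the squared-modulus spectral density used in
#' response integrals is the pure-step density `h^2/omega^2`
#' regularised below `1/window` by a finite observation window
#' (`h^2 (1 - cos(omega window))/omega^2`), whose oscillation average
#' equals the pure-step density. `ft_sq_smooth` carries that average for
#' quadrature on coarse grids.
#'
#' @param c0 background concentration, mM; must be > 0.
#' @param fraction step height as a fraction of `c0`.
#' @param t_on onset time, s.
#' @param window observation window, s.
#' @return a stimulus object.
#' @export
make_step <- function(c0, fraction = 0.1, t_on = 0, window = 1e3) {
  if (c0 <= 0) stop("step stimulus needs background c0 > 0")
  h <- fraction * c0
  f <- function(t) ifelse(t >= t_on, h, 0)
  ft <- function(omega) h * (exp(1i * omega * window) - 1) / (1i * omega)
  ft_sq <- function(omega)
    ifelse(omega == 0, (h * window)^2 / 2,
           h^2 * (1 - cos(omega * window)) / omega^2)
  s <- new_stimulus("step", c0, f, ft, ft_sq,
                    list(height = h, fraction = fraction, t_on = t_on,
                         window = window))
  s$ft_sq_smooth <- function(omega)
    ifelse(abs(omega) < pi / window, s$ft_sq(omega), h^2 / omega^2)
  s
}

#' Sinusoidal stimulus
#'
#' @param c0 background concentration, mM.
#' @param amplitude oscillation amplitude, mM; must be < `c0`.
#' @param omega angular frequency, rad/s.
#' @param t_on onset time, s.
#' @return a stimulus object (no square-integrable transform; `ft` is
#'   `NULL`).
#' @export
make_sine <- function(c0, amplitude, omega, t_on = 0) {
  if (amplitude >= c0) stop("amplitude must be smaller than c0")
  f <- function(t) ifelse(t >= t_on, amplitude * sin(omega * (t - t_on)), 0)
  new_stimulus("sine", c0, f, NULL, NULL,
               list(amplitude = amplitude, omega = omega, t_on = t_on))
}

#' Zero stimulus (constant background)
#'
#' @param c0 background concentration, mM.
#' @return a stimulus object with `f(t) = 0`.
#' @export
make_constant <- function(c0 = 0) {
  new_stimulus("none", c0, function(t) rep(0, length(t)),
               function(omega) rep(0 + 0i, length(omega)),
               function(omega) rep(0, length(omega)), list())
}

#' Small-signal validity check of a stimulus
#'
#' Linear-response analysis requires the concentration change to be small
#' compared with the apparent dissociation constants, i.e. compared with
#' `c0 + K_a_off` and `c0 + K_a_on`. A warning is emitted when the peak
#' deviation exceeds `threshold` times the smaller of the two.
#'
#' @param stimulus a stimulus object.
#' @param mwc an [mwc_params()] object.
#' @param threshold warning threshold on the ratio.
#' @param t_range time range over which to take the peak deviation, s.
#' @return (invisibly) a list with the peak deviation, the reference scale
#'   and the ratio; warns when the ratio exceeds `threshold`.
#' @export
small_signal_check <- function(stimulus, mwc = mwc_params(),
                               threshold = 0.1, t_range = c(0, 100)) {
  tt <- seq(t_range[1], t_range[2], length.out = 20001)
  peak <- max(abs(stimulus$f(tt)))
  ref <- min(stimulus$c0 + mwc$K_a_off, stimulus$c0 + mwc$K_a_on)
  ratio <- peak / ref
  if (ratio > threshold)
    warning(sprintf(paste0("stimulus is not small-signal: peak deviation ",
                           "%.3g mM is %.2f x the apparent dissociation ",
                           "scale %.3g mM"), peak, ratio, ref))
  invisible(list(peak = peak, reference = ref, ratio = ratio,
                 ok = ratio <= threshold))
}
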