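# MWC motor switching-rate model, calibration, linearization, and an
# exact two-state telegraph simulator.

#' Motor switching rates as a function of CheY-P
#'
#' In `mwc` mode the cooperative ring of `m_coop` subunits gives
#' occupancy-averaged switching rates
#' \deqn{k_+(Y_p) = k_+(0) [\frac{1 + \mu Y_p/K_{CCW}}{1 + Y_p/K_{CCW}}]^{m}}
#' \deqn{k_-(Y_p) = k_-(0) [\frac{1 + \mu Y_p/K_{CCW}}{1 + Y_p/K_{CW}}]^{m}}
#' so that with `mu > 1` and `K_CW < K_CCW` the CCW->CW rate rises and the
#' CW->CCW rate falls as CheY-P increases. In `linearized` mode the rates
#' are `k* + dk/dYp * (Yp - Yp_anchor)`, floored at zero.
#'
#' @param Yp CheY-P concentration, uM (vectorised).
#' @param motor a [motor_params()] object.
#' @param Yp_anchor anchor concentration for linearized mode; default is
#'   the value stored in `motor` (3.2 uM if never anchored).
#' @return list with `k_plus` and `k_minus` (1/s) and the CW `bias`
#'   `k_plus / (k_plus + k_minus)`.
#' @export
switching_rates <- function(Yp, motor = motor_params(),
                            Yp_anchor = NULL) {
  if (any(Yp < 0)) stop("Yp must be >= 0")
  if (motor$mode == "mwc") {
    num <- 1 + motor$mu * Yp / motor$K_CCW
    kp <- motor$k_plus_0 * (num / (1 + Yp / motor$K_CCW))^motor$m_coop
    km <- motor$k_minus_0 * (num / (1 + Yp / motor$K_CW))^motor$m_coop
  } else {
    a <- if (!is.null(Yp_anchor)) Yp_anchor else motor$Yp_anchor
    if (is.na(a)) a <- 3.2
    kp <- pmax(0, motor$k_plus_star + motor$dkplus_dYp * (Yp - a))
    km <- pmax(0, motor$k_minus_star + motor$dkminus_dYp * (Yp - a))
  }
  list(k_plus = kp, k_minus = km, bias = kp / (kp + km))
}

# analytic d k+-/dYp of the mwc rate model
mwc_motor_derivatives <- function(motor, Yp) {
  mu <- motor$mu; Kccw <- motor$K_CCW; Kcw <- motor$K_CW
  m <- motor$m_coop
  num <- 1 + mu * Yp / Kccw
  kp <- motor$k_plus_0 * (num / (1 + Yp / Kccw))^m
  km <- motor$k_minus_0 * (num / (1 + Yp / Kcw))^m
  dlog_num <- (mu / Kccw) / num
  c(dkplus_dYp = kp * m * (dlog_num - (1 / Kccw) / (1 + Yp / Kccw)),
    dkminus_dYp = km * m * (dlog_num - (1 / Kcw) / (1 + Yp / Kcw)))
}

#' Calibrate the motor to the CheY-P concentration scale
#'
#' Rescales both dissociation constants by a common factor so that the two
#' switching rates are equal -- CW bias 1/2 -- at the reference CheY-P
#' concentration (3.2 uM for wild type). Idempotent.
#'
#' @param motor a [motor_params()] object in `mwc` mode.
#' @param Yp_eq CheY-P concentration (uM) at which the rates must cross.
#' @return the calibrated [motor_params()] object.
#' @export
calibrate_motor <- function(motor, Yp_eq = 3.2) {
  if (motor$mode != "mwc")
    stop("calibrate_motor() needs an mwc-mode motor")
  # log k+ - log k- = log(k+0/k-0) + m [log(1 + y/(l K_CW)) -
  #                                     log(1 + y/(l K_CCW))]; root in l
  g <- function(loglam) {
    lam <- exp(loglam)
    log(motor$k_plus_0 / motor$k_minus_0) + motor$m_coop *
      (log1p(Yp_eq / (lam * motor$K_CW)) -
       log1p(Yp_eq / (lam * motor$K_CCW)))
  }
  lo <- -30; hi <- 30
  if (g(lo) * g(hi) > 0)
    stop("no positive scale factor equalises the switching rates")
  lam <- exp(uniroot(g, c(lo, hi), tol = 1e-14)$root)
  motor$K_CCW <- motor$K_CCW * lam
  motor$K_CW <- motor$K_CW * lam
  motor
}

#' Linearize the motor around an operating point
#'
#' @param motor a [motor_params()] object.
#' @param Yp_star operating CheY-P concentration, uM.
#' @return list with `omega_X = k+ + k-` (1/s), the CW bias `X_star`, the
#'   sensitivity `omega_2_Y = (1 - X*) dk+/dYp - X* dk-/dYp` (1/s/uM), and
#'   the rates and slopes at the operating point.
#' @export
linearize_motor <- function(motor, Yp_star) {
  if (Yp_star < 0) stop("Yp_star must be >= 0")
  r <- switching_rates(Yp_star, motor)
  if (motor$mode == "mwc") {
    d <- mwc_motor_derivatives(motor, Yp_star)
  } else {
    d <- c(dkplus_dYp = motor$dkplus_dYp, dkminus_dYp = motor$dkminus_dYp)
  }
  X_star <- r$bias
  list(omega_X = r$k_plus + r$k_minus,
       X_star = X_star,
       omega_2_Y = (1 - X_star) * d[["dkplus_dYp"]] -
                   X_star * d[["dkminus_dYp"]],
       k_plus = r$k_plus, k_minus = r$k_minus,
       dkplus_dYp = d[["dkplus_dYp"]], dkminus_dYp = d[["dkminus_dYp"]])
}

#' Exact two-state telegraph simulation of the motor
#'
#' Event-driven continuous-time simulation of CW/CCW switching. Constant
#' rates use exact exponential dwell times; time-varying rates use Ogata
#' thinning with a rate bound refreshed on a regular grid.
#'
#' @param rate_fn either `c(k_plus, k_minus)` (constant rates, 1/s) or a
#'   function `t -> c(k_plus, k_minus)`.
#' @param T_total trace length, s.
#' @param seed RNG seed.
#' @param dt_sample sampling interval of the returned series, s.
#' @param x0 initial state (0 = CCW, 1 = CW); default random from the
#'   stationary bias at t = 0.
#' @param bound_dt refresh interval for the thinning rate bound, s.
#' @return a `chemnoise_timeseries` data.frame with columns `t` and `X`
#'   (0/1); the event times are attached as attribute `events`.
#' @export
simulate_telegraph <- function(rate_fn, T_total, seed = 1,
                               dt_sample = 0.01, x0 = NULL,
                               bound_dt = 0.01) {
  set.seed(seed)
  constant <- is.numeric(rate_fn)
  rates_at <- if (constant) function(t) rate_fn else rate_fn
  r0 <- rates_at(0)
  if (is.null(x0)) x0 <- as.integer(runif(1) < r0[1] / sum(r0))
  state <- as.integer(x0)
  t_now <- 0
  events <- numeric(0)

  if (constant) {
    kp <- rate_fn[1]; km <- rate_fn[2]
    # draw dwell times in blocks until T_total is covered
    while (t_now < T_total) {
      n_blk <- max(64L, ceiling((T_total - t_now) * (kp + km) * 1.2))
      # alternating dwells starting from current state
      rates_seq <- if (state == 0L) rep(c(kp, km), length.out = n_blk)
                   else rep(c(km, kp), length.out = n_blk)
      dw <- rexp(n_blk, rate = rates_seq)
      tt <- t_now + cumsum(dw)
      keep <- tt <= T_total
      events <- c(events, tt[keep])
      if (!all(keep)) { t_now <- T_total; break }
      t_now <- tt[n_blk]
      state <- (state + n_blk) %% 2L
    }
  } else {
    while (t_now < T_total) {
      t_end <- min(t_now + bound_dt, T_total)
      r_a <- rates_at(t_now); r_b <- rates_at(t_end)
      bound <- 1.5 * max(r_a, r_b)  # local bound with safety margin
      tc <- t_now
      repeat {
        tc <- tc + rexp(1, bound)
        if (tc >= t_end) break
        r <- rates_at(tc)
        k <- if (state == 0L) r[1] else r[2]
        if (runif(1) < k / bound) {
          events <- c(events, tc)
          state <- 1L - state
        }
      }
      t_now <- t_end
    }
  }

  tgrid <- seq(0, T_total, by = dt_sample)
  x <- as.integer(x0) + findInterval(tgrid, events)
  ts <- data.frame(t = tgrid, X = x %% 2L)
  attr(ts, "events") <- events
  attr(ts, "dt") <- dt_sample
  attr(ts, "seed") <- seed
  class(ts) <- c("chemnoise_timeseries", "data.frame")
  ts
}

#' Analytic telegraph (motor-switching) power spectrum
#'
#' Two-sided Lorentzian `Q_X / (omega^2 + omega_X^2)` with
#' `Q_X = 2 k+ k- / (k+ + k-)` and `omega_X = k+ + k-`; integrates to the
#' exact stationary variance `X*(1 - X*)`.
#'
#' @param omega angular frequency grid, rad/s.
#' @param k_plus,k_minus switching rates, 1/s.
#' @return PSD values, 1/(rad/s).
#' @export
telegraph_psd <- function(omega, k_plus, k_minus) {
  Q <- 2 * k_plus * k_minus / (k_plus + k_minus)
  Q / (omega^2 + (k_plus + k_minus)^2)
}
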