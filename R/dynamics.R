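# Pathway dynamics: right-hand sides, steady states, deterministic Euler
# integration and Euler-Maruyama Langevin simulation.

#' Right-hand side of the full pathway model
#'
#' Time derivatives of the representative complex methylation level, the
#' phosphorylated CheA/CheY/CheB copy numbers and the motor CW bias, at
#' ligand concentration `c`. The receptor activity is computed from
#' `(c, M)` through the MWC model; demethylation is proportional to the
#' squared CheB-P concentration; phosphotransfer uses the cell volume to
#' convert copy numbers to concentrations.
#'
#' @param state named numeric vector with `M`, `N_Ap`, `N_Yp`, `N_Bp`, `X`.
#' @param c ligand concentration, mM.
#' @param params a [pathway_params()] object. In linearized motor mode the
#'   anchor CheY-P concentration must be set (it is after
#'   [solve_steady_state()]); an unanchored motor uses 3.2 uM.
#' @return list of derivatives `dM`, `dN_Ap`, `dN_Yp`, `dN_Bp`, `dX` plus
#'   the total receptor activity `A_c`.
#' @export
full_rhs <- function(state, c, params) {
  d <- derived_counts(params)
  conv <- d$conv
  N <- params$mwc$N
  N_tot_eff <- d$N_C * N
  if (any(state[c("N_Ap", "N_Yp", "N_Bp")] < 0))
    stop("negative copy numbers in state")
  A <- receptor_activity(c, state[["M"]], params$mwc)
  A_c <- d$N_C * A
  Bp_uM <- conv * state[["N_Bp"]]
  Yp_uM <- conv * state[["N_Yp"]]
  kyv <- params$k_y * conv
  kbv <- params$k_b * conv
  nAp <- state[["N_Ap"]]; nYp <- state[["N_Yp"]]; nBp <- state[["N_Bp"]]
  dM <- params$gamma_R * (N - A) - params$gamma_B * Bp_uM^2 * A
  dAp <- params$k_A * (A_c / N_tot_eff) * (d$N_A_tot - nAp) -
         kyv * (d$N_Y_tot - nYp) * nAp - kbv * (d$N_B_tot - nBp) * nAp
  dYp <- kyv * (d$N_Y_tot - nYp) * nAp - params$k_minus_y * nYp
  dBp <- kbv * (d$N_B_tot - nBp) * nAp - params$k_minus_b * nBp
  r <- switching_rates(Yp_uM, params$motor)
  dX <- r$k_plus * (1 - state[["X"]]) - r$k_minus * state[["X"]]
  list(dM = dM, dN_Ap = dAp, dN_Yp = dYp, dN_Bp = dBp, dX = dX, A_c = A_c)
}

# quasi-steady phosphorylation chain at fixed per-receptor activity:
# returns concentrations (uM). Totals are taken from the integer copy
# numbers so that the balance matches full_rhs() exactly.
phospho_chain <- function(A_r, params) {
  d <- derived_counts(params)
  conv <- d$conv
  ky <- params$k_y; kb <- params$k_b
  kmy <- params$k_minus_y; kmb <- params$k_minus_b
  Yt <- d$N_Y_tot * conv; Bt <- d$N_B_tot * conv; At <- d$N_A_tot * conv
  balance <- function(Ap) {
    Yp <- Yt * ky * Ap / (ky * Ap + kmy)
    Bp <- Bt * kb * Ap / (kb * Ap + kmb)
    params$k_A * A_r * (At - Ap) -
      (ky * (Yt - Yp) + kb * (Bt - Bp)) * Ap
  }
  Ap <- uniroot(balance, c(1e-15, At * (1 - 1e-12)), tol = 1e-15)$root
  list(Ap = Ap,
       Yp = Yt * ky * Ap / (ky * Ap + kmy),
       Bp = Bt * kb * Ap / (kb * Ap + kmb))
}

#' Solve the adapted steady state of the pathway
#'
#' Simultaneously satisfies the methylation balance (methylation of
#' inactive receptors against CheB-P-dependent demethylation), the three
#' phosphorylation balances, and the motor balance, for a cell adapted to
#' background concentration `c0`. Also reports the derived characteristic
#' frequencies: `omega_1` and the adaptation frequency
#' `omega_M = omega_1 * dA/dM`, the motor frequency
#' `omega_X = k+* + k-*`, and the motor sensitivities `omega_2_Y` (per uM
#' CheY-P) and `omega_2_act` (per unit total receptor activity, through
#' the quasi-static gain of the phosphorylation chain).
#'
#' In linearized motor mode with an unset anchor, the starred rates are
#' anchored at the adapted CheY-P concentration, i.e. they *are* the
#' steady-state switching rates.
#'
#' @param params a [pathway_params()] object.
#' @param c0 background ligand concentration, mM.
#' @param model `"full"` (phosphorylation cascade, CheB-P-dependent
#'   demethylation) or `"simplified"` (activity-cubed demethylation; the
#'   phosphorylation chain is still evaluated at the operating point to
#'   derive the motor coupling).
#' @return an object of class `steady_state`.
#' @export
solve_steady_state <- function(params, c0 = 0,
                               model = c("full", "simplified")) {
  model <- match.arg(model)
  d <- derived_counts(params)
  conv <- d$conv
  N <- params$mwc$N
  N_tot_eff <- d$N_C * N

  if (model == "full") {
    g <- function(A_r) {
      ch <- phospho_chain(A_r, params)
      params$gamma_R * (1 - A_r) - params$gamma_B * ch$Bp^2 * A_r
    }
    A_r <- uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-14)$root
  } else {
    beta <- params$gamma_R / (params$gamma_B_simpl * N^2)
    A_r <- adapted_activity_simplified(beta)
  }
  ch <- phospho_chain(A_r, params)
  h <- 1e-6
  ch_hi <- phospho_chain(A_r * (1 + h), params)
  ch_lo <- phospho_chain(A_r * (1 - h), params)
  dYp_dAr <- (ch_hi$Yp - ch_lo$Yp) / (2 * A_r * h)
  dYp_daC <- dYp_dAr / N_tot_eff  # uM per unit total activity

  M_star <- adapted_methylation(c0, A_r, params$mwc)
  sens <- receptor_sensitivities(c0, M_star, params$mwc)

  motor <- params$motor
  if (motor$mode == "linearized" && is.na(motor$Yp_anchor))
    motor$Yp_anchor <- ch$Yp
  lin <- linearize_motor(motor, ch$Yp)
  omega_2_act <- (1 - lin$X_star) * lin$dkplus_dYp * dYp_daC -
                 lin$X_star * lin$dkminus_dYp * dYp_daC

  omega_1 <- params$gamma_R * (3 - 2 * A_r) / A_r
  omega_M <- omega_1 * sens$dA_dM
  k12 <- params$k_2 / (1 - A_r)  # k1 + k2 with k1 = k2 Ar/(1 - Ar)

  params$motor <- motor
  ss <- list(
    model = model, c0 = c0, params = params,
    A_r_star = A_r, A_star = N * A_r, A_c_star = N_tot_eff * A_r,
    M_star = M_star,
    Ap_uM = ch$Ap, Yp_uM = ch$Yp, Bp_uM = ch$Bp,
    N_Ap_star = ch$Ap / conv, N_Yp_star = ch$Yp / conv,
    N_Bp_star = ch$Bp / conv,
    X_star = lin$X_star,
    k_plus_star = lin$k_plus, k_minus_star = lin$k_minus,
    omega_X = lin$omega_X, omega_2_Y = lin$omega_2_Y,
    omega_2_act = omega_2_act, dYp_daC = dYp_daC,
    omega_1 = omega_1, omega_M = omega_M,
    k1 = params$k_2 * A_r / (1 - A_r), k12 = k12,
    dA_dc = sens$dA_dc, dA_dM = sens$dA_dM,
    N_C = d$N_C, N_tot_eff = N_tot_eff, conv = conv, s_um = d$s_um
  )
  class(ss) <- "steady_state"

  if (model == "full") {
    st <- c(M = M_star, N_Ap = ss$N_Ap_star, N_Yp = ss$N_Yp_star,
            N_Bp = ss$N_Bp_star, X = ss$X_star)
    rhs <- full_rhs(st, c0, params)
    scale <- c(1, ss$N_Ap_star, ss$N_Yp_star, ss$N_Bp_star, 1)
    res <- max(abs(unlist(rhs[1:5])) / pmax(scale, 1))
    if (res > 1e-9)
      stop(sprintf("steady-state residual %.3g exceeds 1e-9", res))
    ss$residual <- res
  } else {
    ss$residual <- abs(params$gamma_R * (N - ss$A_star) -
                       params$gamma_B_simpl * ss$A_star^3)
  }
  ss
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Adapted steady state (%s model) at c0 = %g mM\n",
              x$model, x$c0))
  cat(sprintf("  A_r* = %.4f, M* = %.3f, CheY-P* = %.3f uM, X* = %.4f\n",
              x$A_r_star, x$M_star, x$Yp_uM, x$X_star))
  cat(sprintf("  omega_M = %.4g 1/s, omega_X = %.4g 1/s\n",
              x$omega_M, x$omega_X))
  invisible(x)
}

# -- shared engine plumbing ---------------------------------------------

.all_sources <- c("receptor_switching", "ligand", "methylation",
                  "phosphorylation_A", "phosphorylation_Y",
                  "phosphorylation_B", "motor_switching")

stimulus_to_core <- function(stimulus) {
  switch(stimulus$type,
    none = list(type = 0L, p1 = 0, p2 = 0, p3 = 0),
    impulse = list(type = 1L, p1 = stimulus$pars$peak,
                   p2 = stimulus$pars$duration, p3 = stimulus$pars$t_on),
    step = list(type = 2L, p1 = stimulus$pars$height,
                p2 = stimulus$pars$t_on, p3 = 0),
    sine = list(type = 3L, p1 = stimulus$pars$amplitude,
                p2 = stimulus$pars$omega, p3 = stimulus$pars$t_on),
    stop("unsupported stimulus type: ", stimulus$type))
}

core_pars <- function(params, ss, dt, sources = .all_sources) {
  Q <- noise_intensities(ss, params)
  on <- function(s) as.numeric(s %in% sources)
  m <- params$motor
  mwc <- params$mwc
  # white-noise-equivalent per-step ligand concentration sd (mM); the
  # ligand exchange rate k_D far exceeds any simulated band, so the
  # OU-filtered concentration noise is sampled from its flat low-frequency
  # density S_c(0), divided by N_C for the incoherent aggregate.
  sigma_c <- if (ss$c0 > 0 && on("ligand") > 0) {
    sqrt(Q$S_c0 / (ss$N_C * dt))
  } else 0
  lin_simpl <- list(
    dkplus_dAc = m$dkplus_dYp * ss$dYp_daC,
    dkminus_dAc = m$dkminus_dYp * ss$dYp_daC)
  list(
    N = mwc$N, N_C = as.double(ss$N_C), N_tot = as.double(ss$N_tot_eff),
    conv = ss$conv,
    gamma_R = params$gamma_R, gamma_B = params$gamma_B,
    gamma_B_simpl = params$gamma_B_simpl,
    k_A = params$k_A, kyv = params$k_y * ss$conv,
    kbv = params$k_b * ss$conv,
    k_minus_y = params$k_minus_y, k_minus_b = params$k_minus_b,
    NA_tot = concentration_to_copy_number(params$A_tot, params$V_cell),
    NY_tot = concentration_to_copy_number(params$Y_tot, params$V_cell),
    NB_tot = concentration_to_copy_number(params$B_tot, params$V_cell),
    k12 = ss$k12, c0 = ss$c0, sigma_c = sigma_c,
    motor_mode = if (m$mode == "mwc") 1L else 0L,
    k_plus_star = ss$k_plus_star, k_minus_star = ss$k_minus_star,
    dkplus_dYp = m$dkplus_dYp, dkminus_dYp = m$dkminus_dYp,
    Yp_anchor = if (is.na(m$Yp_anchor)) ss$Yp_uM else m$Yp_anchor,
    mu = m$mu, K_CCW = m$K_CCW, K_CW = m$K_CW,
    k_plus_0 = m$k_plus_0, k_minus_0 = m$k_minus_0, m_coop = m$m_coop,
    dkplus_dAc = lin_simpl$dkplus_dAc, dkminus_dAc = lin_simpl$dkminus_dAc,
    aC_star = ss$A_c_star,
    eps0 = mwc$eps0, nu_a = mwc$nu_a, Ka_off = mwc$K_a_off,
    Ka_on = mwc$K_a_on, nu_s = mwc$nu_s, Ks_off = mwc$K_s_off,
    Ks_on = mwc$K_s_on,
    Qa_tot = on("receptor_switching") * 2 * params$k_2 * ss$A_c_star,
    QM_eff = on("methylation") * Q$Q_M / ss$N_C,
    QAp = on("phosphorylation_A") * Q$Q_Ap,
    QAYp = on("phosphorylation_Y") * Q$Q_AYp,
    QmYp = on("phosphorylation_Y") * Q$Q_mYp,
    QABp = on("phosphorylation_B") * Q$Q_ABp,
    QmBp = on("phosphorylation_B") * Q$Q_mBp,
    QX = on("motor_switching") * Q$Q_X
  )
}

core_init <- function(ss) {
  c(ss$A_c_star, ss$M_star, ss$N_Ap_star, ss$N_Yp_star, ss$N_Bp_star,
    ss$X_star)
}

as_chemnoise_ts <- function(mat, dt_sample, seed = NA) {
  ts <- as.data.frame(mat)
  attr(ts, "dt") <- dt_sample
  attr(ts, "seed") <- seed
  class(ts) <- c("chemnoise_timeseries", "data.frame")
  ts
}

#' Deterministic Euler integration of the pathway
#'
#' Forward-Euler integration of the noise-free pathway equations; the
#' receptor activity is recomputed each step from the current ligand
#' concentration and methylation level, then all other variables are
#' updated as `x <- x + dt * rate`. Starts from the steady state adapted
#' to the stimulus background, so a zero stimulus stays flat to machine
#' precision.
#'
#' @param params a [pathway_params()] object.
#' @param stimulus a stimulus object ([make_impulse()] etc.).
#' @param dt integration time step, s.
#' @param T_total integration time, s.
#' @param sample_every record every n-th step.
#' @param model `"full"` or `"simplified"`.
#' @param ss optional precomputed [solve_steady_state()] result.
#' @return a `chemnoise_timeseries` data.frame with columns
#'   `t, c, A_c, N_Ap, N_Yp, N_Bp, X`.
#' @export
integrate_deterministic <- function(params, stimulus = make_constant(),
                                    dt = 1e-3, T_total = 100,
                                    sample_every = 1L,
                                    model = c("full", "simplified"),
                                    ss = NULL) {
  model <- match.arg(model)
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(ss)) ss <- solve_steady_state(params, stimulus$c0, model)
  pars <- core_pars(ss$params, ss, dt, sources = character(0))
  mat <- pathway_euler_core(core_init(ss), pars, stimulus_to_core(stimulus),
                            dt, round(T_total / dt), as.integer(sample_every),
                            FALSE, 0, 0L, FALSE,
                            if (model == "simplified") 1L else 0L, 0L)
  as_chemnoise_ts(mat, dt * sample_every)
}

#' Euler-Maruyama Langevin simulation of the pathway
#'
#' Stochastic integration with independent Gaussian increments of variance
#' `Q_i * dt` per elementary noise source, evaluated at the adapted state
#' (additive noise). The shared phosphotransfer noises are injected with
#' opposite signs into the donor (CheA-P) and acceptor (CheY-P / CheB-P)
#' equations. With every source disabled the trajectory is bit-for-bit
#' the deterministic Euler solution.
#'
#' @inheritParams integrate_deterministic
#' @param seed integer seed; replicate `i` derives an independent
#'   sub-stream deterministically from `(seed, i)`.
#' @param n_replicates number of independent replicates.
#' @param sources character vector of enabled noise sources, a subset of
#'   `c("receptor_switching", "ligand", "methylation",
#'   "phosphorylation_A", "phosphorylation_Y", "phosphorylation_B",
#'   "motor_switching")`.
#' @param discrete_motor simulate the motor as a two-state telegraph
#'   process driven by the instantaneous switching rates instead of the
#'   continuous Langevin bias.
#' @return a single `chemnoise_timeseries` when `n_replicates = 1`, else a
#'   list of them (class `chemnoise_ensemble`).
#' @export
simulate_langevin <- function(params, stimulus = make_constant(),
                              seed = 1, dt = 1e-4, T_total = 100,
                              n_replicates = 1, sample_every = 10L,
                              sources = .all_sources,
                              discrete_motor = FALSE,
                              model = c("full", "simplified"),
                              ss = NULL) {
  model <- match.arg(model)
  if (dt <= 0) stop("dt must be > 0")
  bad <- setdiff(sources, .all_sources)
  if (length(bad)) stop("unknown noise sources: ", paste(bad, collapse = ", "))
  if (is.null(ss)) ss <- solve_steady_state(params, stimulus$c0, model)
  noise <- length(sources) > 0
  pars <- core_pars(ss$params, ss, dt, sources)
  stim <- stimulus_to_core(stimulus)
  nsteps <- round(T_total / dt)
  run1 <- function(i) {
    mat <- pathway_euler_core(core_init(ss), pars, stim, dt, nsteps,
                              as.integer(sample_every), noise,
                              as.double(seed), as.integer(i),
                              discrete_motor,
                              if (model == "simplified") 1L else 0L, 0L)
    as_chemnoise_ts(mat, dt * sample_every, seed)
  }
  if (n_replicates == 1) return(run1(0L))
  out <- lapply(seq_len(n_replicates) - 1L, run1)
  class(out) <- "chemnoise_ensemble"
  out
}

#' Ensemble-averaged PSD of stationary Langevin fluctuations
#'
#' Simulates `n_replicates` independent stationary trajectories one at a
#' time (constant memory) and averages their segment periodograms; the
#' Monte-Carlo counterpart of the analytic spectra.
#'
#' @inheritParams simulate_langevin
#' @param observables columns whose PSD to estimate.
#' @param n_segments periodogram segments per replicate.
#' @param c0 background concentration, mM.
#' @return a `chemnoise_spectrum` (positive frequencies, two-sided
#'   values) averaged over all replicates and segments.
#' @export
ensemble_psd <- function(params, c0 = 0, seed = 1, dt = 1e-4,
                         T_total = 1e3, n_replicates = 200,
                         sample_every = 10L,
                         observables = c("A_c", "N_Yp", "X"),
                         n_segments = 4, sources = .all_sources,
                         discrete_motor = FALSE,
                         model = c("full", "simplified"), ss = NULL) {
  model <- match.arg(model)
  if (is.null(ss)) ss <- solve_steady_state(params, c0, model)
  pars <- core_pars(ss$params, ss, dt, sources)
  stim <- stimulus_to_core(make_constant(c0))
  nsteps <- round(T_total / dt)
  acc <- NULL
  omega <- NULL
  for (i in seq_len(n_replicates)) {
    mat <- pathway_euler_core(core_init(ss), pars, stim, dt, nsteps,
                              as.integer(sample_every), TRUE,
                              as.double(seed), as.integer(i - 1L),
                              discrete_motor,
                              if (model == "simplified") 1L else 0L,
                              if (discrete_motor) 0L else 1L)
    ts <- as_chemnoise_ts(mat, dt * sample_every, seed)
    spec <- estimate_psd(ts, n_segments, observables)
    if (is.null(acc)) { acc <- spec$total; omega <- spec$omega }
    else acc <- acc + spec$total
  }
  new_spectrum(omega, acc / n_replicates,
               meta = list(kind = "estimated", n_replicates = n_replicates,
                           T_total = T_total, dt = dt, seed = seed))
}
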