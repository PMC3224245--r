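# Frequency-domain analysis: noise intensities, analytic response
# functions and noise power spectra (closed-form simplified model and
# linear-noise matrix engine for the full model), plus PSD estimation
# from simulated time series.
#
# Conventions: angular frequency omega in rad/s; d/dt -> -i omega; PSDs
# are two-sided, normalised so that (1/2pi) * integral over the real line
# equals the variance.

#' Logarithmic angular-frequency grid
#'
#' @param omega_min,omega_max grid limits, rad/s.
#' @param n number of points.
#' @return numeric vector (log-spaced).
#' @export
make_omega_grid <- function(omega_min = 1e-4, omega_max = 1e3, n = 800) {
  exp(seq(log(omega_min), log(omega_max), length.out = n))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Noise intensities of the elementary sources
#'
#' Each intensity is twice the one-way steady-state flux of the associated
#' process (for two-way processes) or the one-way flux of a single
#' reaction channel (each phosphorylation / dephosphorylation channel
#' carries its own noise term; paired channels balance at steady state).
#'
#' @param ss a [solve_steady_state()] result.
#' @param params the [pathway_params()] used for `ss`.
#' @return list of class `noise_intensities` with
#' \describe{
#' \item{Q_a}{receptor-complex switching, per complex (activity^2/s).}
#' \item{Q_L}{ligand diffusion, molecules^2/s in the complex-sized
#'   sensing volume; proportional to the diffusion constant `D` used.}
#' \item{Q_M}{receptor de/methylation, per complex (methyl^2/s).}
#' \item{Q_Ap, Q_AYp, Q_ABp, Q_mYp, Q_mBp}{phosphorylation channels,
#'   molecules^2/s.}
#' \item{Q_X}{motor switching, 1/s.}
#' \item{S_c0, k_D}{derived ligand-noise quantities: the zero-frequency
#'   concentration PSD per complex (mM^2 s) and the diffusive exchange
#'   rate `D/(2 s^2)` (1/s).}
#' }
#' @export
noise_intensities <- function(ss, params = ss$params) {
  conv <- ss$conv
  d <- derived_counts(params)
  kyv <- params$k_y * conv
  kbv <- params$k_b * conv
  s_um <- ss$s_um
  n0 <- ss$c0 * .MOLEC_PER_mM_um3          # molecules / um^3
  Q_L <- params$ql_factor * params$D * s_um * n0
  k_D <- params$D / (2 * s_um^2)
  # concentration PSD at omega = 0 for one complex, mM^2 s
  S_c0 <- Q_L / k_D^2 / (s_um^3 * .MOLEC_PER_mM_um3)^2
  out <- list(
    Q_a = 2 * params$k_2 * ss$A_star,
    Q_L = Q_L,
    Q_M = 2 * params$gamma_R * (params$mwc$N - ss$A_star),
    Q_Ap = params$k_A * ss$A_r_star * (d$N_A_tot - ss$N_Ap_star),
    Q_AYp = kyv * (d$N_Y_tot - ss$N_Yp_star) * ss$N_Ap_star,
    Q_ABp = kbv * (d$N_B_tot - ss$N_Bp_star) * ss$N_Ap_star,
    Q_mYp = params$k_minus_y * ss$N_Yp_star,
    Q_mBp = params$k_minus_b * ss$N_Bp_star,
    Q_X = 2 * ss$k_plus_star * ss$k_minus_star /
          (ss$k_plus_star + ss$k_minus_star),
    S_c0 = S_c0, k_D = k_D, D = params$D
  )
  class(out) <- "noise_intensities"
  out
}

# -- linear-noise system -------------------------------------------------

.source_names <- c("a", "L", "M", "Ap", "AYp", "ABp", "mYp", "mBp", "X")
.component_of <- c(a = "receptor_switching", L = "ligand",
                   M = "methylation", Ap = "phosphorylation_A",
                   AYp = "phosphorylation_Y", mYp = "phosphorylation_Y",
                   ABp = "phosphorylation_B", mBp = "phosphorylation_B",
                   X = "motor_switching")
.component_names <- c("receptor_switching", "ligand", "methylation",
                      "phosphorylation_A", "phosphorylation_Y",
                      "phosphorylation_B", "motor_switching")

#' Linearize the full pathway around its steady state
#'
#' Assembles the linear-noise system: the Jacobian `J` of the deterministic
#' dynamics, the stimulus-coupling vectors (`b1` multiplying the
#' concentration deviation, `b2` multiplying its time derivative), the
#' noise-routing matrix `G` (one column per elementary white source;
#' shared phosphotransfer sources appear in exactly two rows with opposite
#' signs) and the intensity vector `Q`.
#'
#' State variables: total receptor activity `A_c` (relaxing at the fast
#' switching rate `k1 + k2` towards the MWC activity), the ligand molecule
#' number `L` in a complex-sized volume (exchange rate `k_D`), the mean
#' complex methylation `M`, the phosphorylated copy numbers, and the motor
#' bias `X`. Fluctuations at different complexes are independent, so
#' per-complex sources enter with incoherent (`sqrt(N_C)`) scaling while
#' the stimulus drives all complexes coherently.
#'
#' @param params a [pathway_params()] object.
#' @param ss a [solve_steady_state()] result (computed if `NULL`).
#' @param reduce return the two-variable reduced system (instantaneous
#'   receptor switching and phosphorylation): states `A_c`, `X` with
#'   adaptation frequency `omega_M` and motor filter `omega_X`, which
#'   reproduces the closed-form simplified response functions exactly.
#' @param ligand_correlated treat ligand fluctuations as perfectly
#'   correlated across complexes (coherent amplitude summation) instead of
#'   independent.
#' @return an object of class `linear_system`.
#' @export
linearize_full <- function(params, ss = NULL, reduce = FALSE,
                           ligand_correlated = FALSE) {
  if (is.null(ss)) ss <- solve_steady_state(params, 0, "full")
  Q <- noise_intensities(ss, params)
  N_C <- ss$N_C

  if (reduce) {
    labels <- c("A_c", "X")
    J <- matrix(c(-ss$omega_M, 0,
                  ss$omega_2_act, -ss$omega_X), 2, 2, byrow = TRUE,
                dimnames = list(labels, labels))
    G <- matrix(0, 2, 2, dimnames = list(labels, c("M", "X")))
    G["A_c", "M"] <- ss$dA_dM
    G["X", "X"] <- 1
    Qv <- c(M = N_C * Q$Q_M, X = Q$Q_X)
    sys <- list(labels = labels, J = J,
                b1 = c(0, 0), b2 = c(N_C * ss$dA_dc, 0),
                G = G, Q = Qv, ss = ss, reduced = TRUE,
                D = params$D)
  } else {
    labels <- c("A_c", "L", "M", "N_Ap", "N_Yp", "N_Bp", "X")
    n <- length(labels)
    J <- matrix(0, n, n, dimnames = list(labels, labels))
    conv <- ss$conv
    d <- derived_counts(params)
    kyv <- params$k_y * conv
    kbv <- params$k_b * conv
    vol_fac <- ss$s_um^3 * .MOLEC_PER_mM_um3  # molecules per mM
    lig_scale <- if (ligand_correlated) N_C else sqrt(N_C)

    J["A_c", "A_c"] <- -ss$k12
    J["A_c", "M"] <- ss$k12 * N_C * ss$dA_dM
    J["A_c", "L"] <- ss$k12 * lig_scale * ss$dA_dc / vol_fac
    J["L", "L"] <- -Q$k_D
    J["M", "A_c"] <- -(params$gamma_R + params$gamma_B * ss$Bp_uM^2) / N_C
    J["M", "N_Bp"] <- -2 * params$gamma_B * ss$Bp_uM * ss$A_star * conv
    J["N_Ap", "A_c"] <- params$k_A / ss$N_tot_eff *
      (d$N_A_tot - ss$N_Ap_star)
    J["N_Ap", "N_Ap"] <- -params$k_A * ss$A_r_star -
      kyv * (d$N_Y_tot - ss$N_Yp_star) - kbv * (d$N_B_tot - ss$N_Bp_star)
    J["N_Ap", "N_Yp"] <- kyv * ss$N_Ap_star
    J["N_Ap", "N_Bp"] <- kbv * ss$N_Ap_star
    J["N_Yp", "N_Ap"] <- kyv * (d$N_Y_tot - ss$N_Yp_star)
    J["N_Yp", "N_Yp"] <- -kyv * ss$N_Ap_star - params$k_minus_y
    J["N_Bp", "N_Ap"] <- kbv * (d$N_B_tot - ss$N_Bp_star)
    J["N_Bp", "N_Bp"] <- -kbv * ss$N_Ap_star - params$k_minus_b
    J["X", "N_Yp"] <- ss$omega_2_Y * conv
    J["X", "X"] <- -ss$omega_X

    G <- matrix(0, n, length(.source_names),
                dimnames = list(labels, .source_names))
    G["A_c", "a"] <- 1
    G["L", "L"] <- 1
    G["M", "M"] <- 1
    G["N_Ap", c("Ap", "AYp", "ABp")] <- 1    # signs as assigned to the
    G["N_Yp", "AYp"] <- -1                   # donor equation; shared
    G["N_Yp", "mYp"] <- 1                    # sources flip sign in the
    G["N_Bp", "ABp"] <- -1                   # acceptor equation
    G["N_Bp", "mBp"] <- 1
    G["X", "X"] <- 1

    Qv <- c(a = N_C * Q$Q_a, L = Q$Q_L, M = Q$Q_M / N_C,
            Ap = Q$Q_Ap, AYp = Q$Q_AYp, ABp = Q$Q_ABp,
            mYp = Q$Q_mYp, mBp = Q$Q_mBp, X = Q$Q_X)

    b1 <- setNames(numeric(n), labels)
    b1["A_c"] <- ss$k12 * N_C * ss$dA_dc
    sys <- list(labels = labels, J = J, b1 = b1,
                b2 = setNames(numeric(n), labels), G = G, Q = Qv,
                ss = ss, reduced = FALSE, D = params$D)
  }
  ev <- eigen(sys$J, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("linearized system is unstable (eigenvalue with Re >= 0)")
  sys$eigenvalues <- ev
  class(sys) <- "linear_system"
  sys
}

#' Frequency response of the linearized pathway
#'
#' Solves `(-i omega I - J) chi = b1 - i omega b2` per frequency: the
#' complex gain of every state variable with respect to a small
#' concentration input.
#'
#' @param linsys a [linearize_full()] system.
#' @param omega angular frequency grid, rad/s.
#' @return object of class `response_curve`: complex matrix `chi`
#'   (frequencies by observables), `magnitude`, and unwrapped `phase`.
#' @export
response_full <- function(linsys, omega = make_omega_grid()) {
  n <- length(linsys$labels)
  chi <- matrix(0i, length(omega), n,
                dimnames = list(NULL, linsys$labels))
  for (k in seq_along(omega)) {
    A <- -1i * omega[k] * diag(n) - linsys$J
    chi[k, ] <- solve(A, linsys$b1 - 1i * omega[k] * linsys$b2)
  }
  new_response(omega, chi)
}

new_response <- function(omega, chi) {
  phase <- vapply(seq_len(ncol(chi)),
                  function(j) unwrap_phase(Arg(chi[, j])),
                  numeric(nrow(chi)))
  dim(phase) <- dim(chi)
  dimnames(phase) <- dimnames(chi)
  r <- list(omega = omega, chi = chi, magnitude = Mod(chi),
            phase = phase, labels = colnames(chi))
  class(r) <- "response_curve"
  r
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  corr <- cumsum(ifelse(dp > pi, -2 * pi, ifelse(dp < -pi, 2 * pi, 0)))
  p + c(0, corr)
}

#' Closed-form response of the simplified pathway
#'
#' Receptor activity: a high-pass filter
#' `chi_Ac = -i omega N_C (dA/dc) / (omega_M - i omega)`; adaptation
#' cancels the response below `omega_M` while above it the gain saturates
#' at `N_C |dA/dc|`. Motor: an additional low-pass filter
#' `chi_X = omega_2 / (omega_X - i omega) * chi_Ac`.
#'
#' @param omega angular frequency grid, rad/s.
#' @param params a [pathway_params()] object.
#' @param ss steady state (simplified model used if `NULL`).
#' @return a `response_curve` with observables `A_c` and `X`.
#' @export
response_simplified <- function(omega, params, ss = NULL) {
  if (is.null(ss)) ss <- solve_steady_state(params, 0, "simplified")
  chi_A <- -1i * omega * ss$N_C * ss$dA_dc / (ss$omega_M - 1i * omega)
  chi_X <- ss$omega_2_act / (ss$omega_X - 1i * omega) * chi_A
  new_response(omega, cbind(A_c = chi_A, X = chi_X))
}

new_spectrum <- function(omega, total, components = NULL, meta = list()) {
  s <- list(omega = omega, total = total, components = components,
            labels = colnames(total), meta = meta)
  class(s) <- "chemnoise_spectrum"
  s
}

#' Source-decomposed noise spectra of the linearized full pathway
#'
#' `S_x(omega) = sum_s |[(-i omega I - J)^{-1} G]_{x,s}|^2 Q_s`; the
#' per-source terms are aggregated into the named components
#' (`receptor_switching`, `ligand`, `methylation`, `phosphorylation_A`,
#' `phosphorylation_Y`, `phosphorylation_B`, `motor_switching`) which sum
#' exactly to the total.
#'
#' @inheritParams response_full
#' @return object of class `chemnoise_spectrum` with matrix `total`
#'   (frequencies by observables) and a list `components`.
#' @export
spectrum_full <- function(linsys, omega = make_omega_grid()) {
  n <- length(linsys$labels)
  srcs <- colnames(linsys$G)
  tot <- matrix(0, length(omega), n,
                dimnames = list(NULL, linsys$labels))
  comp_keys <- unique(unname(.component_of[srcs]))
  comps <- lapply(comp_keys, function(k) tot)
  names(comps) <- comp_keys
  for (k in seq_along(omega)) {
    A <- -1i * omega[k] * diag(n) - linsys$J
    H <- solve(A, linsys$G)                       # n x nsrc, complex
    P <- Mod(H)^2 * rep(linsys$Q, each = n)       # per-source power
    for (s in seq_along(srcs)) {
      key <- .component_of[[srcs[s]]]
      comps[[key]][k, ] <- comps[[key]][k, ] + P[, s]
    }
  }
  for (key in comp_keys) tot <- tot + comps[[key]]
  new_spectrum(omega, tot, comps,
               meta = list(D = linsys$D, kind = "analytic"))
}

#' Closed-form noise spectra of the simplified pathway
#'
#' Activity: `S_Ac = N_C [omega^2 S_a + (dA/dc)^2 omega^2 S_c +
#' (dA/dM)^2 Q_M] / (omega_M^2 + omega^2)` with `S_a` the Lorentzian of
#' receptor switching (corner `k1 + k2`) and `S_c` the diffusive ligand
#' Lorentzian (corner `k_D`). Motor:
#' `S_X = [omega_2^2 S_Ac + Q_X] / (omega^2 + omega_X^2)`.
#'
#' @inheritParams response_simplified
#' @return a `chemnoise_spectrum` with observables `A_c` and `X` and
#'   per-source components.
#' @export
spectrum_simplified <- function(omega, params, ss = NULL) {
  if (is.null(ss)) ss <- solve_steady_state(params, 0, "simplified")
  Q <- noise_intensities(ss, params)
  N_C <- ss$N_C
  S_a <- Q$Q_a / (omega^2 + ss$k12^2)
  S_c <- (Q$S_c0 * Q$k_D^2) / (omega^2 + Q$k_D^2)
  den_A <- ss$omega_M^2 + omega^2
  comp_A <- list(
    receptor_switching = N_C * omega^2 * S_a / den_A,
    ligand = N_C * ss$dA_dc^2 * omega^2 * S_c / den_A,
    methylation = N_C * ss$dA_dM^2 * Q$Q_M / den_A)
  den_X <- omega^2 + ss$omega_X^2
  w2 <- ss$omega_2_act^2
  comps <- lapply(names(comp_A), function(k)
    cbind(A_c = comp_A[[k]], X = w2 * comp_A[[k]] / den_X))
  names(comps) <- names(comp_A)
  comps$motor_switching <- cbind(A_c = 0 * omega, X = Q$Q_X / den_X)
  tot <- Reduce(`+`, comps)
  new_spectrum(omega, tot, comps,
               meta = list(D = params$D, kind = "analytic"))
}

# -- PSD estimation ------------------------------------------------------

#' Estimate power spectral density from a time series
#'
#' Segment-averaged (Bartlett) periodogram, two-sided, normalised so that
#' `(1/2pi)` times the integral over the real line (twice the positive
#' half) recovers the sample variance exactly (discrete Parseval; each
#' segment is demeaned).
#'
#' @param ts a `chemnoise_timeseries` (or data.frame with column `t` and
#'   uniform spacing).
#' @param n_segments number of non-overlapping segments to average.
#' @param observables columns to use; default all but `t`.
#' @return a `chemnoise_spectrum` with `omega` (positive frequencies) and
#'   the estimated two-sided PSD per observable.
#' @export
estimate_psd <- function(ts, n_segments = 1, observables = NULL) {
  dt <- attr(ts, "dt")
  if (is.null(dt)) dt <- diff(ts$t[1:2])
  if (is.null(observables))
    observables <- setdiff(colnames(ts), c("t", "c"))
  n_total <- nrow(ts)
  seg_len <- floor(n_total / n_segments)
  if (seg_len < 8) stop("series shorter than requested segments")
  nf <- floor(seg_len / 2)
  omega <- 2 * pi * seq_len(nf) / (seg_len * dt)
  tot <- matrix(0, nf, length(observables),
                dimnames = list(NULL, observables))
  for (s in seq_len(n_segments)) {
    idx <- ((s - 1) * seg_len + 1):(s * seg_len)
    for (j in seq_along(observables)) {
      x <- ts[[observables[j]]][idx]
      x <- x - mean(x)
      P <- dt * Mod(fft(x))^2 / seg_len
      tot[, j] <- tot[, j] + P[2:(nf + 1)]
    }
  }
  tot <- tot / n_segments
  new_spectrum(omega, tot,
               meta = list(kind = "estimated", dt = dt,
                           seg_len = seg_len, n_segments = n_segments))
}

#' Fit a Lorentzian to an estimated spectrum
#'
#' Least squares on log S against `log(Q / (omega^2 + omega_c^2))`.
#'
#' @param omega angular frequency grid, rad/s.
#' @param S PSD values.
#' @return list with `omega_c` (corner, rad/s) and `Q` (intensity).
#' @export
fit_lorentzian <- function(omega, S) {
  keep <- S > 0 & omega > 0
  omega <- omega[keep]; S <- S[keep]
  Q0 <- stats::median(S * (omega^2 + stats::median(omega)^2))
  w0 <- sqrt(stats::median(omega)^2)
  obj <- function(p) {
    Sfit <- exp(p[1]) / (omega^2 + exp(2 * p[2]))
    sum((log(S) - log(Sfit))^2)
  }
  fit <- optim(c(log(Q0), log(w0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(omega_c = exp(fit$par[2]), Q = exp(fit$par[1]),
       converged = fit$convergence == 0)
}

# -- CSV export ----------------------------------------------------------

#' Write a spectrum, response curve or time series to CSV
#'
#' @param x a `chemnoise_spectrum`, `response_curve` or
#'   `chemnoise_timeseries`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_chemnoise_csv <- function(x, path) {
  if (inherits(x, "chemnoise_spectrum")) {
    df <- data.frame(omega_rad_s = x$omega)
    for (lab in x$labels) df[[paste0("S_", lab)]] <- x$total[, lab]
    if (!is.null(x$components))
      for (key in names(x$components))
        for (lab in x$labels)
          df[[paste0("S_", lab, "_", key)]] <- x$components[[key]][, lab]
  } else if (inherits(x, "response_curve")) {
    df <- data.frame(omega_rad_s = x$omega)
    for (lab in x$labels) {
      df[[paste0("mag_", lab)]] <- x$magnitude[, lab]
      df[[paste0("phase_", lab)]] <- x$phase[, lab]
    }
  } else {
    df <- as.data.frame(x)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
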