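test_that("noise intensities follow the twice-the-flux rule", {
  Q <- noise_intensities(wt_ss)
  # motor switching from the wild-type rates
  expect_equal(Q$Q_X, 2 * 1.05 * 1.06 / 2.11, tolerance = 1e-9)
  # no background concentration, no ligand noise
  expect_equal(Q$Q_L, 0)
  # phosphorylation and dephosphorylation channels balance at steady state
  expect_equal(Q$Q_AYp, Q$Q_mYp, tolerance = 1e-6)
  expect_equal(Q$Q_ABp, Q$Q_mBp, tolerance = 1e-6)
  expect_equal(Q$Q_M, 2 * wt$gamma_R * (wt$mwc$N - wt_ss$A_star))
  # with a background, Q_L is proportional to the diffusion constant used
  ss2 <- solve_steady_state(wt, 0.02)
  Q2 <- noise_intensities(ss2)
  expect_gt(Q2$Q_L, 0)
  expect_equal(Q2$D, 1e3)
})

test_that("the analytic Jacobian matches finite differences of full_rhs", {
  sys <- linearize_full(wt, wt_ss)
  # full_rhs evaluates the activity instantaneously, i.e. the adiabatic
  # limit of the fast A_c state: its Jacobian is the slow block plus the
  # chain through A_c (which only methylation perturbs, dAc/dM = N_C dA/dM)
  vars <- c("M", "N_Ap", "N_Yp", "N_Bp", "X")
  rows <- c(dM = "M", dN_Ap = "N_Ap", dN_Yp = "N_Yp", dN_Bp = "N_Bp",
            dX = "X")
  st0 <- c(M = wt_ss$M_star, N_Ap = wt_ss$N_Ap_star,
           N_Yp = wt_ss$N_Yp_star, N_Bp = wt_ss$N_Bp_star, X = wt_ss$X_star)
  for (v in vars) {
    h <- max(1e-6, 1e-6 * abs(st0[[v]]))
    up <- st0; up[[v]] <- up[[v]] + h
    dn <- st0; dn[[v]] <- dn[[v]] - h
    fu <- full_rhs(up, 0, wt_ss$params)
    fd <- full_rhs(dn, 0, wt_ss$params)
    num <- (unlist(fu[1:5]) - unlist(fd[1:5])) / (2 * h)
    dAc_dv <- if (v == "M") wt_ss$N_C * wt_ss$dA_dM else 0
    for (r in names(rows)) {
      ana <- sys$J[rows[[r]], v] + sys$J[rows[[r]], "A_c"] * dAc_dv
      expect_equal(unname(num[[r]]), unname(ana), tolerance = 1e-5)
    }
  }
  # each shared phosphotransfer source appears in exactly two rows with
  # opposite signs
  for (src in c("AYp", "ABp")) {
    col <- sys$G[, src]
    expect_equal(sum(col != 0), 2)
    expect_equal(sum(col), 0)
  }
  # stability
  expect_true(all(Re(sys$eigenvalues) < 0))
})

test_that("reduced system reproduces the closed-form response exactly", {
  red <- linearize_full(wt, wt_ss, reduce = TRUE)
  grid <- make_omega_grid(1e-5, 1e3, 300)
  chiR <- response_full(red, grid)
  chiC <- response_simplified(grid, wt, ss = wt_ss)
  expect_lt(max(Mod(chiR$chi - chiC$chi) / pmax(Mod(chiC$chi), 1e-300)),
            1e-8)
})

test_that("response curves have the expected symmetries and limits", {
  sys <- linearize_full(wt, wt_ss)
  grid <- make_omega_grid(1e-6, 1e2, 400)
  chi <- response_full(sys, grid)
  # Hermitian symmetry: chi(-w) = conj(chi(w))
  chi_neg <- vapply(seq_along(grid), function(k) {
    A <- 1i * grid[k] * diag(length(sys$labels)) - sys$J
    solve(A, sys$b1 + 1i * grid[k] * sys$b2)[5]
  }, complex(1))
  expect_lt(max(Mod(chi_neg - Conj(chi$chi[, "N_Yp"]))), 1e-6)
  # adaptation kills the DC response; the plateau is N_C |dA/dc|
  expect_lt(chi$magnitude[1, "A_c"], 1e-3 * max(chi$magnitude[, "A_c"]))
  plateau <- unname(chi$magnitude[which.min(abs(grid - 10)), "A_c"])
  expect_equal(plateau, wt_ss$N_C * abs(wt_ss$dA_dc), tolerance = 0.05)
  # relative to the receptor response, CheY-P is filtered at high
  # frequency while CheA-P follows the receptors over the same decade
  i1 <- which.min(abs(grid - 3)); i2 <- which.min(abs(grid - 30))
  drop_rel <- function(obs)
    (chi$magnitude[i1, obs] / chi$magnitude[i2, obs]) /
    (chi$magnitude[i1, "A_c"] / chi$magnitude[i2, "A_c"])
  expect_gt(drop_rel("N_Yp"), 2)
  # CheA-P is filtered far less than CheY-P over the same decade
  expect_lt(drop_rel("N_Ap"), drop_rel("N_Yp") / 2)
  # phase of CheY-P and the motor exceeds pi at high frequency
  expect_gt(max(chi$phase[, "N_Yp"]), pi)
  expect_gt(max(chi$phase[, "X"]), pi)
})

test_that("receptor-activity phase tends to pi/2 at low and pi at high omega", {
  grid <- c(wt_ss$omega_M / 1e3, wt_ss$omega_M * 1e3)
  chi <- response_simplified(grid, wt, ss = wt_ss)
  expect_equal(unname(chi$phase[1, "A_c"]), pi / 2, tolerance = 0.01)
  expect_equal(unname(chi$phase[2, "A_c"]), pi, tolerance = 0.01)
})

test_that("spectra are non-negative, even in construction, and decompose", {
  sys <- linearize_full(wt, wt_ss)
  grid <- make_omega_grid(1e-4, 1e3, 300)
  spec <- spectrum_full(sys, grid)
  expect_true(all(spec$total >= 0))
  tot <- Reduce(`+`, spec$components)
  expect_lt(max(abs(tot - spec$total) / pmax(spec$total, 1e-300)), 1e-10)
  # motor-switching component of S_X is exactly the telegraph Lorentzian
  expect_equal(spec$components$motor_switching[, "X"],
               telegraph_psd(grid, wt_ss$k_plus_star, wt_ss$k_minus_star),
               tolerance = 1e-10)
  # with wild-type parameters the motor spectrum is dominated by its own
  # switching noise; methylation and phosphorylation form the
  # low-frequency shoulder of the transmitted noise
  iband <- grid < 10
  ms <- spec$components$motor_switching[iband, "X"]
  expect_true(all(ms > 0.5 * spec$total[iband, "X"]))
  trans <- spec$total[, "X"] - spec$components$motor_switching[, "X"]
  shoulder <- spec$components$methylation[, "X"] +
    spec$components$phosphorylation_A[, "X"] +
    spec$components$phosphorylation_Y[, "X"] +
    spec$components$phosphorylation_B[, "X"]
  ilow <- grid < 0.05
  expect_true(all(shoulder[ilow] > 0.9 * trans[ilow]))
})

test_that("simplified spectrum has the closed-form single-source limits", {
  ssS <- solve_steady_state(wt, 0.02, "simplified")
  grid <- make_omega_grid(1e-4, 1e2, 200)
  spec <- spectrum_simplified(grid, wt, ssS)
  expect_true(all(spec$total >= 0))
  # motor-only: S_X = Q_X / (omega^2 + omega_X^2)
  Q <- noise_intensities(ssS)
  expect_equal(spec$components$motor_switching[, "X"],
               Q$Q_X / (grid^2 + ssS$omega_X^2), tolerance = 1e-12)
  # zero-frequency ligand spectrum scales as c0/(D s): doubling D halves it
  p2 <- wt; p2$D <- 2 * wt$D
  ss2 <- solve_steady_state(p2, 0.02, "simplified")
  Q2 <- noise_intensities(ss2, p2)
  expect_equal(Q$S_c0 / Q2$S_c0, 2, tolerance = 1e-9)
})

test_that("estimate_psd is calibrated on white noise and closes Parseval", {
  set.seed(2)
  dt <- 0.01
  n <- 2^15
  x <- rnorm(n, sd = 3)
  ts <- data.frame(t = (0:(n - 1)) * dt, X = x)
  attr(ts, "dt") <- dt
  class(ts) <- c("chemnoise_timeseries", "data.frame")
  spec <- estimate_psd(ts, n_segments = 8, observables = "X")
  # flat two-sided level sigma^2 dt
  expect_equal(mean(spec$total[, "X"]), 9 * dt, tolerance = 0.05)
  # Parseval: band integral over the whole grid = sample variance
  v <- variance_in_band(spec, tau_band = 0, "X")$total
  expect_equal(v, var(x), tolerance = 0.02)
  expect_error(estimate_psd(ts[1:20, ], n_segments = 10), "shorter")
})

test_that("a Lorentzian fit recovers the telegraph corner frequency", {
  tg <- simulate_telegraph(c(1.05, 1.06), T_total = 1e4, seed = 21)
  spec <- estimate_psd(tg, n_segments = 16, observables = "X")
  keep <- spec$omega >= 0.05 & spec$omega <= 30
  b <- log_bin(spec$omega[keep], spec$total[keep, "X"], 25)
  fit <- fit_lorentzian(b$omega, b$S)
  expect_lt(abs(fit$omega_c / 2.11 - 1), 0.05)
})
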