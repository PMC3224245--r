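test_that("integrated response matches the closed-form step result", {
  # receptor level, simplified model: the quadrature must reproduce
  # (N_C dA/dc)^2 (alpha c)^2 / (2 omega_M) for a step within 1%
  ss <- solve_steady_state(wt, 0.02, "simplified")
  grid <- make_omega_grid(1e-7, 1e3, 2000)
  chi <- response_simplified(grid, wt, ss)
  st <- make_step(0.02, 0.1)
  got <- integrated_response(chi, st, "A_c")
  closed <- (ss$N_C * ss$dA_dc)^2 * (0.1 * 0.02)^2 / (2 * ss$omega_M)
  expect_equal(got, closed, tolerance = 0.01)
  # zero stimulus integrates to zero; linearity: doubling the amplitude
  # quadruples the integrated response
  expect_equal(integrated_response(chi, make_constant(0.02), "A_c"), 0)
  got2 <- integrated_response(chi, make_step(0.02, 0.2), "A_c")
  expect_equal(got2 / got, 4, tolerance = 1e-9)
})

test_that("band variance reproduces closed-form integrals", {
  grid <- make_omega_grid(1e-4, 10, 1200)
  # flat spectrum Q: variance over +-1/tau is Q/(pi tau)
  flat <- list(omega = grid, total = cbind(X = rep(2.5, length(grid))),
               components = NULL, labels = "X")
  class(flat) <- "chemnoise_spectrum"
  expect_equal(variance_in_band(flat, 1, "X")$total, 2.5 / pi,
               tolerance = 1e-3)
  # Lorentzian: (Q/(pi omega_c)) arctan(band/omega_c)
  lor <- list(omega = grid,
              total = cbind(X = telegraph_psd(grid, 1.05, 1.06)),
              components = NULL, labels = "X")
  class(lor) <- "chemnoise_spectrum"
  Q <- 2 * 1.05 * 1.06 / 2.11
  expect_equal(variance_in_band(lor, 1, "X")$total,
               Q / (pi * 2.11) * atan(1 / 2.11), tolerance = 1e-3)
  expect_error(variance_in_band(lor, 0.01, "X"), "band edge")
})

test_that("scaling laws of the simplified receptor module are recovered", {
  # signal response grows linearly with complex size at fixed N_tot
  Ns <- c(2, 3, 4, 6, 8, 12, 16)
  res <- lapply(Ns, function(N) {
    p <- pathway_params(mwc = mwc_params(N = N))
    receptor_signal_noise(p, c0 = 0.02)
  })
  dA2 <- vapply(res, function(r) r$delta_A2, 0)
  v_sw <- vapply(res, function(r) r$var[["receptor_switching"]], 0)
  v_lig <- vapply(res, function(r) r$var[["ligand"]], 0)
  v_m <- vapply(res, function(r) r$var[["methylation"]], 0)
  expect_equal(fit_power_law(Ns, dA2)$exponent, 1, tolerance = 0.1)
  # switching variance roughly constant (exponent about 0)
  expect_lt(abs(fit_power_law(Ns, v_sw)$exponent), 0.1)
  expect_lt(max(v_sw) / min(v_sw), 1.5)
  # ligand variance grows as N^(5/2), methylation about linearly
  expect_equal(fit_power_law(Ns, v_lig)$exponent, 2.5, tolerance = 0.1)
  expect_equal(fit_power_law(Ns, v_m)$exponent, 1, tolerance = 0.15)
})

test_that("small-gamma_R exponents: response -1/3, switching-limited SNR -2/3", {
  base_gBs <- 18 * 0.0061 / 18^2
  gR <- 0.0061 * 10^seq(-4, -3, length.out = 6)
  res <- lapply(gR, function(g) {
    p <- pathway_params(gamma_R = g, gamma_B_simpl = base_gBs)
    receptor_signal_noise(p, c0 = 0.02)
  })
  dA2 <- vapply(res, function(r) r$delta_A2, 0)
  v_sw <- vapply(res, function(r) r$var[["receptor_switching"]], 0)
  expect_equal(fit_power_law(gR, dA2)$exponent, -1 / 3, tolerance = 0.1)
  expect_equal(fit_power_law(gR, v_sw)$exponent, 1 / 3, tolerance = 0.1)
  expect_equal(fit_power_law(gR, dA2 / v_sw)$exponent, -2 / 3,
               tolerance = 0.05)
})

test_that("removing a noise source never decreases the SNR", {
  st <- make_step(0.02, 0.1)
  full <- snr_at_motor(wt, st, include_motor_noise = TRUE)
  partial <- snr_at_motor(wt, st, include_motor_noise = FALSE)
  expect_gte(partial$snr, full$snr)
  # and dropping ligand noise (c0 = 0 background has none) is consistent:
  # all components are non-negative
  expect_true(all(partial$components >= 0))
})

test_that("adaptation-rate sweep shows the published asymmetry", {
  # response increases as gamma_R -> 0 over +-2 decades
  gR <- wt$gamma_R * 10^seq(-2, 1, length.out = 7)
  stim <- make_step(0.1, 0.1)
  resR <- vapply(gR, function(g) {
    p <- wt; p$gamma_R <- g
    r <- snr_at_motor(p, stim)
    c(r$delta_X2, r$snr, r$variance)
  }, numeric(3))
  expect_true(all(diff(resR[1, ]) < 0))  # dX2 decreasing in gamma_R
  expect_true(all(diff(resR[2, ]) < 0))  # SNR decreasing in gamma_R
  # response and SNR decrease for vanishing gamma_B (saturated activity)
  gB <- wt$gamma_B * 10^c(-5, -4, -3, 0)
  resB <- vapply(gB, function(g) {
    p <- wt; p$gamma_B <- g
    r <- snr_at_motor(p, stim)
    c(r$delta_X2, r$snr, r$variance)
  }, numeric(3))
  expect_lt(resB[1, 1], resB[1, 4])  # dX2 smaller at vanishing gamma_B
  expect_lt(resB[2, 1], resB[2, 4])  # SNR smaller at vanishing gamma_B
  # transmitted variance vanishes in both saturation limits
  expect_lt(resB[3, 1], 0.2 * resB[3, 4])
  expect_lt(resR[3, 1], 0.2 * resR[3, 7])
})

test_that("complex-size sweep: response maximal in the Tar range, switching flat", {
  sw <- sweep_complex_size(wt, c0_grid = c(0.005, 0.02, 0.1, 0.8, 5),
                          N_grid = c(6, 18, 36))
  s18 <- sw[sw$N == 18, ]
  # integrated response peaks at a background between the Tar dissociation
  # constants (0.02 and 0.5 mM)
  best <- s18$c0[which.max(s18$delta_X2)]
  expect_gte(best, 0.02); expect_lte(best, 0.5)
  # receptor-switching variance varies by less than 1.5x over the N range
  s02 <- sw[sw$c0 == 0.02, ]
  expect_lt(max(s02$var_receptor_switching) /
            min(s02$var_receptor_switching), 1.5)
})

test_that("fluctuation-response: variance peaks near half-phosphorylation", {
  fr <- fluctuation_response(wt, "gamma_R",
                             grid = wt$gamma_R *
                               10^seq(-2, 2, length.out = 17))
  imax <- which.max(fr$var_Yp_uM2)
  expect_gt(imax, 1); expect_lt(imax, nrow(fr))   # interior maximum
  expect_lt(abs(fr$Yp_star_uM[imax] - wt$Y_tot / 2), 1.5)
  # normalised variance decreases as adapted CheY-P increases (except the
  # smallest values)
  ord <- order(fr$Yp_star_uM)
  nv <- fr$var_norm[ord]
  expect_true(all(diff(nv[fr$Yp_star_uM[ord] > 1.5]) < 0))
  # on the short-adaptation-time branch (times below the one at the
  # variance peak) adaptation time rises with variance
  short <- fr$adaptation_time_s < fr$adaptation_time_s[imax]
  expect_gt(stats::cor(fr$adaptation_time_s[short], fr$var_Yp_uM2[short],
                       method = "spearman"), 0.8)
})

test_that("fit_power_law is exact on power laws and robust to noise", {
  x <- 10^seq(0, 2, length.out = 12)
  expect_equal(fit_power_law(x, 3 * x^2)$exponent, 2, tolerance = 1e-10)
  set.seed(4)
  y <- x^(1 / 3) * exp(rnorm(12, sd = 0.01))
  f <- fit_power_law(x, y)
  expect_equal(f$exponent, 1 / 3, tolerance = 0.03)
  expect_error(fit_power_law(x[1:3], x[1:3]), "4 points")
  expect_error(fit_power_law(x, -x), "positive")
})
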