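test_that("steady state satisfies every balance and the printed rates", {
  expect_lt(wt_ss$residual, 1e-9)
  rhs <- full_rhs(c(M = wt_ss$M_star, N_Ap = wt_ss$N_Ap_star,
                    N_Yp = wt_ss$N_Yp_star, N_Bp = wt_ss$N_Bp_star,
                    X = wt_ss$X_star), 0, wt_ss$params)
  expect_lt(max(abs(unlist(rhs[1:5]))), 1e-6)
  # wild-type motor: X* = k+/(k+ + k-) and omega_X from the starred rates
  expect_equal(wt_ss$X_star, 1.05 / 2.11, tolerance = 1e-9)
  expect_equal(wt_ss$omega_X, 2.11, tolerance = 1e-9)
  # derived frequencies
  expect_equal(wt_ss$omega_1,
               wt$gamma_R * (3 - 2 * wt_ss$A_r_star) / wt_ss$A_r_star)
  expect_equal(wt_ss$omega_M, wt_ss$omega_1 * wt_ss$dA_dM)
})

test_that("full_rhs matches an independent hand-coded evaluation", {
  d <- derived_counts(wt)
  conv <- d$conv
  set.seed(7)
  for (i in 1:10) {
    st <- c(M = runif(1, 20, 50), N_Ap = runif(1, 0, 4215),
            N_Yp = runif(1, 0, 8178), N_Bp = runif(1, 0, 236),
            X = runif(1))
    c0 <- runif(1, 0, 0.5)
    A <- wt$mwc$N / (1 + exp(free_energy(c0, st[["M"]], wt$mwc)))
    Bp <- conv * st[["N_Bp"]]
    # duplicate implementation, written independently of full_rhs
    dup <- list(
      dM = 0.0061 * (18 - A) - 3.14 * Bp^2 * A,
      dAp = 10 * (A / 18) * (4215 - st[["N_Ap"]]) -
        100 * conv * (8178 - st[["N_Yp"]]) * st[["N_Ap"]] -
        15 * conv * (236 - st[["N_Bp"]]) * st[["N_Ap"]],
      dYp = 100 * conv * (8178 - st[["N_Yp"]]) * st[["N_Ap"]] -
        5 * st[["N_Yp"]],
      dBp = 15 * conv * (236 - st[["N_Bp"]]) * st[["N_Ap"]] -
        1.35 * st[["N_Bp"]])
    got <- full_rhs(st, c0, wt_ss$params)
    expect_equal(got$dM, dup$dM, tolerance = 1e-10)
    expect_equal(got$dN_Ap, dup$dAp, tolerance = 1e-10)
    expect_equal(got$dN_Yp, dup$dYp, tolerance = 1e-10)
    expect_equal(got$dN_Bp, dup$dBp, tolerance = 1e-10)
  }
  expect_error(full_rhs(c(M = 30, N_Ap = -5, N_Yp = 10, N_Bp = 10, X = 0.5),
                        0, wt), "negative")
})

test_that("phosphotransfer flux enters donor and acceptor with opposite sign", {
  st <- c(M = wt_ss$M_star, N_Ap = wt_ss$N_Ap_star,
          N_Yp = wt_ss$N_Yp_star, N_Bp = wt_ss$N_Bp_star, X = wt_ss$X_star)
  base <- full_rhs(st, 0, wt_ss$params)
  st2 <- st; st2[["N_Yp"]] <- st[["N_Yp"]] - 500  # more free CheY
  pert <- full_rhs(st2, 0, wt_ss$params)
  dtransfer_Yp <- (pert$dN_Yp + wt$k_minus_y * st2[["N_Yp"]]) -
                  (base$dN_Yp + wt$k_minus_y * st[["N_Yp"]])
  dtransfer_Ap <- pert$dN_Ap - base$dN_Ap
  expect_gt(dtransfer_Yp, 0)             # more transfer to CheY
  expect_equal(dtransfer_Ap, -dtransfer_Yp, tolerance = 1e-9)
})

test_that("deterministic integration is flat without stimulus and converges", {
  flat <- integrate_deterministic(wt, make_constant(), dt = 1e-3,
                                  T_total = 20, ss = wt_ss)
  expect_lt(max(abs(flat$A_c - flat$A_c[1])) / flat$A_c[1], 1e-8)
  expect_lt(max(abs(flat$X - flat$X[1])), 1e-8)
  # halving dt changes the impulse peak by < 0.5%
  t1 <- integrate_deterministic(wt, make_impulse(), dt = 1e-3,
                                T_total = 4, ss = wt_ss)
  t2 <- integrate_deterministic(wt, make_impulse(), dt = 5e-4,
                                T_total = 4, ss = wt_ss)
  pk1 <- min(t1$A_c) - t1$A_c[1]
  pk2 <- min(t2$A_c) - t2$A_c[1]
  expect_lt(abs(pk1 / pk2 - 1), 0.005)
})

test_that("attractant impulse: negative deflection then readaptation", {
  ts <- integrate_deterministic(wt, make_impulse(), T_total = 80,
                                ss = wt_ss)
  for (obs in c("A_c", "N_Ap", "N_Yp", "X")) {
    dev <- ts[[obs]] - ts[[obs]][1]
    expect_lt(min(dev), 0)                          # transient decrease
    expect_lt(abs(dev[which.min(abs(ts$t - 80))]),
              0.02 * abs(min(dev)))                 # readapted
  }
  # long integration from a perturbed start converges to the fixed point
  pert <- integrate_deterministic(wt, make_impulse(peak = 5e-4),
                                  T_total = 150, ss = wt_ss)
  expect_lt(abs(pert$N_Yp[nrow(pert)] - wt_ss$N_Yp_star), 0.05)
})

test_that("Langevin with all sources off equals the deterministic path", {
  d1 <- integrate_deterministic(wt, make_impulse(), dt = 1e-3,
                                T_total = 5, ss = wt_ss)
  d2 <- simulate_langevin(wt, make_impulse(), seed = 1, dt = 1e-3,
                          T_total = 5, sample_every = 1L,
                          sources = character(0), ss = wt_ss)
  expect_identical(as.matrix(as.data.frame(d1)),
                   as.matrix(as.data.frame(d2)))
})

test_that("Langevin trajectories respect totals and track the mean", {
  ts <- simulate_langevin(wt, seed = 5, dt = 1e-4, T_total = 50,
                          sample_every = 10L, ss = wt_ss)
  d <- derived_counts(wt)
  expect_true(all(ts$N_Yp <= d$N_Y_tot & ts$N_Yp >= 0))
  expect_true(all(ts$N_Bp <= d$N_B_tot & ts$N_Bp >= 0))
  # ensemble mean of the stochastic impulse response tracks the
  # deterministic solution within 3 standard errors
  nrep <- 60
  det <- integrate_deterministic(wt, make_impulse(t_on = 0.5), dt = 1e-4,
                                 T_total = 2, sample_every = 100L,
                                 ss = wt_ss)
  ens <- simulate_langevin(wt, make_impulse(t_on = 0.5), seed = 9,
                           dt = 1e-4, T_total = 2, n_replicates = nrep,
                           sample_every = 100L, ss = wt_ss)
  ymat <- sapply(ens, function(e) e$N_Yp)
  mu <- rowMeans(ymat)
  se <- apply(ymat, 1, sd) / sqrt(nrep)
  frac_inside <- mean(abs(mu - det$N_Yp) <= 3 * se + 1e-9)
  expect_gt(frac_inside, 0.95)
})

test_that("same seed reproduces the same stochastic trajectory", {
  a <- simulate_langevin(wt, seed = 123, dt = 1e-3, T_total = 2, ss = wt_ss)
  b <- simulate_langevin(wt, seed = 123, dt = 1e-3, T_total = 2, ss = wt_ss)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_langevin(wt, seed = 124, dt = 1e-3, T_total = 2, ss = wt_ss)
  expect_false(identical(a$X, c_$X))
})

test_that("simplified model steady state satisfies the cubic balance", {
  ssS <- solve_steady_state(wt, 0, "simplified")
  N <- wt$mwc$N
  lhs <- wt$gamma_R * (N - ssS$A_star)
  rhs <- wt$gamma_B_simpl * ssS$A_star^3
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_equal(ssS$A_r_star, 1 / 3, tolerance = 1e-9)
})
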