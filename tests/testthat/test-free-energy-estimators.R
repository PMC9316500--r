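test_that("population estimator: closed forms, n/a convention, oracle recovery", {
  RT <- R_GAS * 300
  even <- c(rep(0, 50), rep(pi, 50))
  expect_equal(delta_g_ez_from_populations(even)$value, 0)
  ratio_e <- c(rep(pi, 272), rep(0, 100))   # N_E/N_Z = e within 1%
  expect_equal(delta_g_ez_from_populations(ratio_e)$value, RT,
               tolerance = 0.01)
  stuck <- delta_g_ez_from_populations(rep(pi, 100))
  expect_true(is.na(stuck$value))
  expect_error(delta_g_ez_from_populations(numeric(0)), "empty")
  ## recovery on a low-barrier system against the quadrature oracle
  sys <- easy_sys(N_s = 0)
  r <- run_replica_exchange(sys, single_state_ladder(1, 1), 1e5,
                            swap_interval = 10, seed = 17, sample_interval = 10)
  d <- delta_g_ez_from_populations(r$samples)
  expect_lt(abs(d$value - exact_delta_g_ez(sys, 1, 1)), 3 * d$stderr + 1e-9)
})

test_that("MBAR: gauge, trivial cases, enumeration oracle on a discrete toy", {
  ## two identical states
  u <- matrix(rnorm(200), 2, 100, byrow = TRUE)
  u[2, ] <- u[1, ]
  f <- mbar_solve(u, N_k = c(50, 50))$f_k
  expect_equal(f, c(0, 0), tolerance = 1e-9)
  ## single state: gauge only
  expect_equal(mbar_solve(matrix(rnorm(30), 1), N_k = 30)$f_k, 0)
  ## 3-microstate toy, 2 Hamiltonians, iid draws from exact Boltzmann weights
  u1 <- c(0, 1.0, 2.5); u2 <- c(1.5, 0.2, 0)
  exact <- -log(sum(exp(-u2)) / sum(exp(-u1)))
  set.seed(21)
  n <- 4000
  micro <- c(sample(1:3, n, TRUE, prob = exp(-u1)),
             sample(1:3, n, TRUE, prob = exp(-u2)))
  um <- rbind(u1[micro], u2[micro])
  est <- mbar_solve(um, N_k = c(n, n))
  expect_true(est$converged)
  expect_lt(abs(est$f_k[2] - exact), 0.05)   # ~3 sigma: sd 0.016 across seeds
  ## gauge invariance: global and per-sample shifts
  est2 <- mbar_solve(um + 7.3, N_k = c(n, n))
  expect_equal(est2$f_k, est$f_k, tolerance = 1e-8)
  shift <- rnorm(ncol(um))
  est3 <- mbar_solve(sweep(um, 2, shift, "+"), N_k = c(n, n))
  expect_equal(est3$f_k, est$f_k, tolerance = 1e-8)
})

test_that("BAR: trivial zero, Gaussian-toy recovery, equals 2-state MBAR", {
  ## identical neighbour Hamiltonians: all work values are exactly zero
  expect_equal(bar_delta_f(rep(0, 300), rep(0, 200))$delta_f, 0,
               tolerance = 1e-10)
  set.seed(22)
  ## Crooks-consistent Gaussian work distributions with known answer
  df_true <- 1.7; s2 <- 4
  wf <- rnorm(2000, df_true + s2 / 2, sqrt(s2))
  wr <- rnorm(2000, -df_true + s2 / 2, sqrt(s2))
  expect_lt(abs(bar_delta_f(wf, wr)$delta_f - df_true), 0.11)  # ~3 x sd(0.034)
  ## exact agreement with the two-state MBAR restriction (unequal n)
  wf2 <- rnorm(500, 2, 1); wr2 <- rnorm(400, -1, 1.3)
  b <- bar_delta_f(wf2, wr2)$delta_f
  um <- cbind(rbind(rep(0, 500), wf2), rbind(wr2, rep(0, 400)))
  m <- unname(mbar_solve(um, N_k = c(500, 400))$f_k[2])
  expect_equal(b, m, tolerance = 1e-8)
  ## disjoint work distributions raise the overlap flag
  expect_true(bar_delta_f(rnorm(50, 40), rnorm(50, 40))$overlap_warning)
})

test_that("stratification telescopes exactly and converts sign correctly", {
  expect_equal(stratified_delta_f(rep(0, 5))$delta_f_total, 0)
  f <- c(0, cumsum(rnorm(7)))
  expect_identical(sum(diff(f)), stratified_delta_f(diff(f))$delta_f_total)
  expect_equal(stratified_delta_f(diff(f))$delta_f_total, f[8] - f[1])
  ## hydration scale: -RT * total
  s <- stratified_delta_f(c(1, 2), RT = 0.5)
  expect_equal(s$delta_g, -1.5)
})

test_that("stratified hydration matches the closed-form oracle (per isomer)", {
  sys <- surrogate_system(cal_sys()$K_b, cal_sys()$a, cal_sys()$d_eps, N_s = 8)
  ld <- lambda_hop_ladder(0.05, 6)
  for (init in c("E", "Z")) {
    r <- run_replica_exchange(sys, ld, 1e5, swap_interval = 10, init = init,
                              seed = if (init == "E") 23 else 24)
    hyd <- hydration_from_samples(r$samples, n_boot = 50, boot_seed = 9)
    oracle <- exact_hydration_delta_g(sys, 1, 0.05, init)
    expect_lt(abs(hyd$delta_g - oracle), 3 * hyd$delta_g_se + 0.02)
    ## BAR strata and MBAR strata agree on the same data
    expect_equal(sum(hyd$delta_f_k), sum(hyd$delta_f_k_mbar),
                 tolerance = 0.05)
  }
})

test_that("MBAR PMF: flat for uniform data, matches the quadrature profile", {
  ## uniform phi, all weights equal -> flat within noise
  set.seed(25)
  mat <- structure(list(u = matrix(0, 2, 4000), N_k = c(2000, 2000),
                        phi = runif(4000, -pi, pi),
                        origin = rep(1:2, each = 2000), RT = R_GAS * 300),
                   class = "reduced_energy_matrix")
  mb <- mbar_solve(mat)
  pmf <- mbar_pmf(mat, mb, 1, 12)
  expect_lt(max(pmf$free_energy, na.rm = TRUE), 0.15)
  ## gas HREM on the calibrated system recovers the exact profile
  sys <- cal_sys()
  r <- run_replica_exchange(sys, trem_ladder(0.05, 8), 2e5,
                            swap_interval = 10, seed = 26, sample_interval = 10)
  m2 <- reduced_energy_matrix(r$samples, subsample = 5)
  p2 <- mbar_pmf(m2, mbar_solve(m2), 1, 72)
  expect_lt(abs(profile_barrier(p2) - 40), 1.5)
  ## PMF-integrated well masses agree with the population estimator
  pe_pmf <- sum(p2$mass[abs(p2$phi) >= pi / 2])
  dg_pmf <- m2$RT * log(pe_pmf / (1 - pe_pmf))
  d <- delta_g_ez_from_populations(r$samples)
  expect_lt(abs(dg_pmf - d$value), 4 * d$stderr + 0.05)
})

test_that("mixture identity: algebraic limits and printed worked example", {
  expect_equal(mixture_delta_g(-5, -5, 0.3), -5)
  expect_equal(mixture_delta_g(-5, -5, 7), -5)
  expect_equal(mixture_delta_g(-18.57, -15.91, 1e-14), -18.57,
               tolerance = 1e-10)
  expect_error(mixture_delta_g(-5, -4, -1), "estimator error")
  rt <- R_GAS * 300
  expect_equal(mixture_delta_g(-18.57, -15.91, exp(-0.68 / rt)), -18.41,
               tolerance = 0.005)
  ## exactness with the decoupled-end ratio, against the quadrature oracle
  sys <- cal_sys()
  dgE <- exact_hydration_delta_g(sys, 1, 0.05, "E")
  dgZ <- exact_hydration_delta_g(sys, 1, 0.05, "Z")
  r_gas <- exp(-exact_delta_g_ez(sys, 1, 0.05) / rt)
  expect_equal(mixture_delta_g(dgE, dgZ, r_gas),
               exact_hydration_delta_g(sys, 1, 0.05, "all"),
               tolerance = 1e-9)
  ## and the cycle-transport reproduces that ratio from coupled-state data
  r_sol <- exp(-exact_delta_g_ez(sys, 1, 1) / rt)
  expect_equal(transport_ratio_to_decoupled(r_sol, dgE, dgZ), r_gas,
               tolerance = 1e-9)
})

test_that("ratio conversion follows the adopted sign convention", {
  expect_equal(ratio_from_delta_g_ez(0), 1)
  expect_equal(ratio_from_delta_g_ez(R_GAS * 300 * log(2)), 2)
  expect_equal(ratio_from_delta_g_ez(0.53), 2.433, tolerance = 0.001)
})

test_that("statistical inefficiency is 1 for white noise, > 1 for sticky series", {
  set.seed(27)
  expect_lt(statistical_inefficiency(rnorm(5000)), 1.3)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 5000))
  expect_gt(statistical_inefficiency(ar), 5)
})
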