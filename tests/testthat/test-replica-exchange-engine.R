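test_that("runs are bit-reproducible for identical seeds", {
  sys <- easy_sys()
  ld <- st_hrem_ladder(0.2, 3)
  a <- run_replica_exchange(sys, ld, 5e3, swap_interval = 5, seed = 42)
  b <- run_replica_exchange(sys, ld, 5e3, swap_interval = 5, seed = 42)
  expect_identical(a$samples$phi, b$samples$phi)
  expect_identical(a$samples$v_sS, b$samples$v_sS)
  expect_identical(a$trace$walker_slot, b$trace$walker_slot)
  c <- run_replica_exchange(sys, ld, 5e3, swap_interval = 5, seed = 43)
  expect_false(identical(a$samples$phi, c$samples$phi))
})

test_that("zero-width proposals leave the configuration unchanged", {
  sys <- easy_sys()
  r <- run_replica_exchange(sys, st_hrem_ladder(0.5, 2), 200,
                            swap_interval = 10, init = "E", seed = 1,
                            sample_interval = 10, burn_in = 0,
                            dphi = 0, sigma_y = 0, scale_dphi = FALSE)
  expect_true(all(r$samples$phi == pi))
  expect_true(all(r$samples$v_s == 0))
  cfg <- list(phi = 0.3, y = rep(0.1, sys$N_s))
  expect_identical(mc_sweep(sys, cfg, 1, 1, dphi = 0, sigma_y = 0), cfg)
})

test_that("a 300 K single-state run never crosses the 40 kcal/mol barrier", {
  sys <- cal_sys()
  r <- run_replica_exchange(sys, single_state_ladder(1, 1), 5e4,
                            swap_interval = 10, init = "Z", seed = 2)
  expect_true(all(abs(r$samples$phi) < pi / 2))
  expect_identical(length(r$trace$attempts), 0L)   # plain MC: no edges
})

test_that("hot-state sampling matches the quadrature density (chi-square)", {
  sys <- cal_sys()
  r <- run_replica_exchange(sys, single_state_ladder(0.05, 0), 2e5,
                            swap_interval = 10, init = "Z", seed = 5,
                            sample_interval = 50)
  br <- seq(-pi, pi, length.out = 25)
  cnt <- tabulate(findInterval(r$samples$phi[, 1], br, all.inside = TRUE), 24)
  pe <- exact_bin_masses(sys, 0.05, 0, br)
  pv <- suppressWarnings(stats::chisq.test(cnt, p = pe))$p.value
  expect_gt(pv, 0.01)
})

test_that("R reference sweep targets the same distribution as the kernel", {
  sys <- easy_sys(N_s = 0)
  set.seed(9)
  cfg <- list(phi = 0, y = numeric(0))
  ph <- replicate(4e4, {
    cfg <<- mc_sweep(sys, cfg, 0.3, 0.5, dphi = 1.0)
    cfg$phi
  })
  br <- seq(-pi, pi, length.out = 13)
  cnt <- tabulate(findInterval(ph[seq(1, 4e4, 20)], br, all.inside = TRUE), 12)
  pe <- exact_bin_masses(sys, 0.3, 0.5, br)
  pv <- suppressWarnings(stats::chisq.test(cnt, p = pe))$p.value
  expect_gt(pv, 0.01)
})

test_that("swap acceptance: closed forms and empirical frequency", {
  expect_equal(swap_acceptance(0), 1.0)
  expect_equal(swap_acceptance(log(2)), 0.5)
  expect_equal(swap_acceptance(-3), 1.0)
  set.seed(4)
  for (delta in c(0.2, 1.5)) {
    p <- swap_acceptance(delta)
    hits <- mean(runif(1e5) < p)
    expect_lt(abs(hits - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("walker ids stay a permutation through every swap round", {
  sys <- easy_sys()
  r <- run_replica_exchange(sys, st_hrem_ladder(0.1, 5), 2e4,
                            swap_interval = 5, seed = 7)
  H <- r$trace$walker_slot
  expect_true(all(apply(H, 1, function(x) identical(sort(x), 1:5))))
  expect_true(all(r$trace$accepts <= r$trace$attempts))
})

test_that("composite chain hits the product-Boltzmann distribution (2 replicas)", {
  sys <- surrogate_system(K_b = 2, a = 1, d_eps = 0, N_s = 0)
  ld <- st_hrem_ladder(0.5, 2)
  r <- run_replica_exchange(sys, ld, 4e5, swap_interval = 5, init = "Z",
                            seed = 3, sample_interval = 20, dphi = 0.8,
                            scale_dphi = FALSE)
  nb <- 8
  br <- seq(-pi, pi, length.out = nb + 1)
  b1 <- findInterval(r$samples$phi[, 1], br, all.inside = TRUE)
  b2 <- findInterval(r$samples$phi[, 2], br, all.inside = TRUE)
  emp <- table(factor(b1, 1:nb), factor(b2, 1:nb)) / length(b1)
  ex <- outer(exact_bin_masses(sys, 1, 0, br),
              exact_bin_masses(sys, 0.5, 0, br))
  tv <- sum(abs(emp - ex)) / 2
  expect_lt(tv, 0.08)   # ~0.02 typical at this run length
})

test_that("lambda-hopping walkers keep their initial isomer; ST-HREM does not", {
  sys <- cal_sys()
  lh <- run_replica_exchange(sys, lambda_hop_ladder(0.05, 8), 5e4,
                             swap_interval = 10, init = "E", seed = 11)
  expect_true(all(abs(lh$samples$phi) >= pi / 2))
  st <- run_replica_exchange(sys, st_hrem_ladder(0.05, 8), 2e5,
                             swap_interval = 10, init = "Z", seed = 12)
  expect_gt(sum(abs(st$samples$phi[, 1]) >= pi / 2), 0)
  expect_gt(sum(abs(st$samples$phi[, 1]) < pi / 2), 0)
})

test_that("lambda-ladder exchange ratios fall as the solvent grows", {
  ers <- vapply(c(8, 96), function(ns) {
    sys <- surrogate_system(N_s = ns)
    r <- run_replica_exchange(sys, lambda_hop_ladder(0.05, 8), 3e4,
                              swap_interval = 10, seed = 41)
    mean(exchange_ratios(r$trace)$ratios)
  }, numeric(1))
  expect_gt(ers[1], ers[2])
})

test_that("sample sets survive a round trip through gzipped TSV", {
  sys <- easy_sys()
  r <- run_replica_exchange(sys, st_hrem_ladder(0.2, 3), 3e3,
                            swap_interval = 5, seed = 13, sample_interval = 5)
  path <- tempfile(fileext = ".tsv.gz")
  write_sample_set(r$samples, path)
  back <- read_sample_set(path)
  expect_equal(back$phi, r$samples$phi, tolerance = 1e-15)
  expect_equal(back$v_sS, r$samples$v_sS, tolerance = 1e-15)
  expect_equal(back$ladder$s_intra, r$samples$ladder$s_intra,
               tolerance = 1e-15)
  expect_equal(back$system$K_b, sys$K_b)
})
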