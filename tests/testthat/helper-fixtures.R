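## calibrated system, built once per test session
cal_sys <- local({
  sys <- NULL
  function() {
    if (is.null(sys)) sys <<- calibrate_system()
    sys
  }
})

## low-barrier system: frequent isomer interconversion, cheap equilibration
easy_sys <- function(N_s = 4)
  surrogate_system(K_b = 4, a = 1.2, d_eps = 1.8, N_s = N_s)

run_pair <- function(system, ladder, n_sweeps, seed, ...) {
  E <- run_replica_exchange(system, ladder, n_sweeps = n_sweeps,
                            init = "E", seed = seed, ...)
  Z <- run_replica_exchange(system, ladder, n_sweeps = n_sweeps,
                            init = "Z", seed = seed + 1L, ...)
  list(E = E, Z = Z)
}

## quadrature bin masses of the phi marginal at (s, lambda)
exact_bin_masses <- function(system, s, lambda, breaks, n_grid = 4096) {
  h <- 2 * pi / n_grid
  phi <- seq(-pi + h / 2, pi - h / 2, by = h)
  u <- (s * (system$K_b / 2 * (1 - cos(2 * phi)) +
               system$a / 2 * (1 - cos(phi))) -
          lambda * system$d_eps / 2 * (1 - cos(phi))) / (R_GAS * system$T0)
  p <- exp(-u - max(-u)); p <- p / sum(p)
  bin <- findInterval(phi, breaks, all.inside = TRUE)
  vapply(seq_len(length(breaks) - 1), function(b) sum(p[bin == b]),
         numeric(1))
}
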