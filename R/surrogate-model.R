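#' @useDynLib lambdahop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot rnorm runif sd quantile
NULL

#' Gas constant in kcal/(mol K)
#'
#' Fixed at 1.9872e-3 so that RT at 300 K is 0.59616 kcal/mol; the mixture
#' free-energy arithmetic is sensitive to this constant at the 0.01 kcal/mol
#' level.
#' @export
R_GAS <- 1.9872e-3

#' Construct a surrogate solvated-solute system
#'
#' The surrogate replaces an all-atom solvated molecule with a single
#' torsional coordinate phi plus `N_s` harmonic solvent coordinates.  Its
#' potential energy decomposes exactly as
#' \deqn{U(s, \lambda) = V_s(y) + s\,V_S(\phi) + \lambda\,V_{sS}(\phi, y)}
#' with
#' \deqn{V_S = (K_b/2)(1 - \cos 2\phi) + (a/2)(1 - \cos\phi)}
#' \deqn{V_{sS} = -(\Delta\epsilon/2)(1 - \cos\phi) + (g/2)\sum_i y_i^2}
#' \deqn{V_s = (k_s/2)\sum_i y_i^2.}
#' The Z isomer lives in the well at phi = 0 (|phi| < pi/2), the E isomer in
#' the well at phi = pi.  The solvent-coupling amplitude `d_eps` screens the
#' E-destabilisation `a` so that full coupling (lambda = 1) inverts the E/Z
#' stability while leaving the torsional barrier nearly unchanged.  Because
#' the phi- and y-dependent parts separate, every equilibrium quantity has a
#' quadrature or closed-form oracle.
#'
#' @param K_b torsional barrier stiffness, kcal/mol (must be > 0)
#' @param a gas-phase E-destabilisation amplitude, kcal/mol
#' @param d_eps solvent-screening amplitude, kcal/mol
#' @param N_s number of auxiliary solvent coordinates (>= 0)
#' @param k_s solvent self-stiffness, kcal/mol per unit^2 (> 0)
#' @param g solvent-coupling stiffness, kcal/mol per unit^2
#' @param T0 target temperature, K
#' @return an object of class `surrogate_system`
#' @export
surrogate_system <- function(K_b = 38.5, a = 3.0, d_eps = 3.5, N_s = 32,
                             k_s = 1.0, g = 0.5, T0 = 300) {
  stopifnot(is.numeric(K_b), K_b > 0, N_s >= 0, k_s > 0, T0 > 0)
  if (k_s + min(0, g) <= 0 || k_s + g <= 0)
    stop("invalid system: k_s + lambda*g must stay positive on [0, 1]")
  sys <- list(K_b = K_b, a = a, d_eps = d_eps, N_s = as.integer(N_s),
              k_s = k_s, g = g, T0 = T0, R_gas = R_GAS)
  class(sys) <- "surrogate_system"
  sys
}

#' @export
print.surrogate_system <- function(x, ...) {
  cat("Surrogate torsional system\n")
  cat(sprintf("  K_b = %.6g  a = %.6g  d_eps = %.6g kcal/mol\n",
              x$K_b, x$a, x$d_eps))
  cat(sprintf("  N_s = %d  k_s = %.3g  g = %.3g  T0 = %g K (RT = %.5f)\n",
              x$N_s, x$k_s, x$g, x$T0, x$R_gas * x$T0))
  invisible(x)
}

beta_of <- function(system) 1 / (system$R_gas * system$T0)

#' Wrap a torsional angle into (-pi, pi]
#' @param phi angle(s) in radians
#' @export
wrap_phi <- function(phi) {
  w <- (phi + pi) %% (2 * pi)
  w[w <= 0] <- w[w <= 0] + 2 * pi
  w - pi
}

#' Potential-energy components of a configuration
#'
#' @param system a `surrogate_system`
#' @param phi torsional angle, radians
#' @param y numeric vector of length `N_s` (solvent coordinates)
#' @return list with components `v_s`, `v_S`, `v_sS` (kcal/mol)
#' @export
potential_components <- function(system, phi, y = numeric(system$N_s)) {
  if (!is.finite(phi) || !all(is.finite(y)))
    stop("invalid configuration: non-finite coordinates")
  if (length(y) != system$N_s)
    stop("invalid configuration: length(y) != N_s")
  sy <- sum(y^2)
  list(v_s  = 0.5 * system$k_s * sy,
       v_S  = 0.5 * system$K_b * (1 - cos(2 * phi)) +
              0.5 * system$a * (1 - cos(phi)),
       v_sS = -0.5 * system$d_eps * (1 - cos(phi)) + 0.5 * system$g * sy)
}

#' Reduced (dimensionless) energy at a ladder point
#'
#' Combines stored energy components linearly:
#' beta * (v_s + s_intra * v_S + lambda * v_sS).  Vectorised over components.
#'
#' @param system a `surrogate_system`
#' @param comps list with `v_s`, `v_S`, `v_sS` (scalars or vectors)
#' @param s_intra solute intramolecular scaling in (0, 1]
#' @param lambda solute-solvent scaling in [0, 1]
#' @export
reduced_energy <- function(system, comps, s_intra, lambda) {
  if (s_intra <= 0 || s_intra > 1 || lambda < 0 || lambda > 1)
    stop("protocol error: s_intra must be in (0,1] and lambda in [0,1]")
  beta_of(system) * (comps$v_s + s_intra * comps$v_S + lambda * comps$v_sS)
}

## phi-dependent part of the reduced potential at ladder point (s, lambda);
## the Gaussian y-part factorises and cancels from all phi marginals.
u_phi <- function(system, phi, s_intra, lambda) {
  beta_of(system) *
    (s_intra * (0.5 * system$K_b * (1 - cos(2 * phi)) +
                0.5 * system$a * (1 - cos(phi))) -
     lambda * 0.5 * system$d_eps * (1 - cos(phi)))
}

phi_grid <- function(n_grid) {
  ## midpoint grid on (-pi, pi]; trapezoid == midpoint for periodic funcs
  h <- 2 * pi / n_grid
  seq(-pi + h / 2, pi - h / 2, by = h)
}

#' Exact free-energy profile along the torsional angle
#'
#' Quadrature oracle: minus RT log of the Boltzmann density of phi at ladder
#' point (s, lambda), shifted so the global minimum is zero.  The solvent
#' coordinates integrate out exactly (the y-part of `v_sS` is phi-free), so
#' the profile is independent of `N_s`, `k_s` and `g`.
#'
#' @inheritParams reduced_energy
#' @param n_grid number of uniform phi grid points (>= 64)
#' @return data.frame with columns `phi` (bin centers) and `free_energy`
#'   (kcal/mol)
#' @export
exact_phi_profile <- function(system, s_intra = 1, lambda = 0,
                              n_grid = 2048) {
  stopifnot(n_grid >= 64)
  phi <- phi_grid(n_grid)
  u <- u_phi(system, phi, s_intra, lambda)
  lp <- -u - log_sum_exp(-u)          # log density up to bin width
  fe <- -(system$R_gas * system$T0) * lp
  data.frame(phi = phi, free_energy = fe - min(fe))
}

#' Torsional barrier from a free-energy profile
#'
#' Profile maximum minus the Z-well (|phi| < pi/2) minimum, in kcal/mol.
#' @param profile data.frame as returned by [exact_phi_profile()] or
#'   [mbar_pmf()]
#' @export
profile_barrier <- function(profile) {
  ok <- is.finite(profile$free_energy)
  zwell <- ok & abs(profile$phi) < pi / 2
  max(profile$free_energy[ok]) - min(profile$free_energy[zwell])
}

#' Exact E/Z free-energy gap by quadrature
#'
#' Returns RT log(P_E / P_Z) at ladder point (s, lambda), with
#' Z <=> |phi| < pi/2.  Positive values mean the E isomer is favoured.
#' (The published account defines this with the opposite sign, inconsistently
#' with its own tabulated values; this package uses the convention that
#' reproduces them.)
#'
#' @inheritParams exact_phi_profile
#' @export
exact_delta_g_ez <- function(system, s_intra = 1, lambda = 0,
                             n_grid = 2048) {
  phi <- phi_grid(n_grid)
  u <- u_phi(system, phi, s_intra, lambda)
  zmask <- abs(phi) < pi / 2
  lpz <- log_sum_exp(-u[zmask])
  lpe <- log_sum_exp(-u[!zmask])
  system$R_gas * system$T0 * (lpe - lpz)
}

## log partition function (up to the same additive constant for all lambda)
## at ladder point (s, lambda): closed-form Gaussian y-integral times phi
## quadrature, optionally restricted to one isomer's half-domain.
log_z <- function(system, s_intra, lambda, restrict = "all", n_grid = 2048) {
  keff <- system$k_s + lambda * system$g
  if (keff <= 0) stop("invalid system: k_s + lambda*g <= 0")
  RT <- system$R_gas * system$T0
  phi <- phi_grid(n_grid)
  u <- u_phi(system, phi, s_intra, lambda)
  mask <- switch(restrict,
                 all = rep(TRUE, length(phi)),
                 Z = abs(phi) < pi / 2,
                 E = abs(phi) >= pi / 2,
                 stop("restrict must be one of 'all', 'E', 'Z'"))
  h <- 2 * pi / n_grid
  0.5 * system$N_s * log(2 * pi * RT / keff) +
    log_sum_exp(-u[mask]) + log(h)
}

#' Exact (de)coupling free energy between two lambda values
#'
#' Closed-form Gaussian-integral-times-quadrature oracle for
#' \deqn{\Delta G = -RT \ln [Z(\lambda_{hi}) / Z(\lambda_{lo})]}
#' at fixed `s_intra` = 1, i.e. the free-energy change for turning the
#' solute-solvent coupling up from `lambda_lo` to `lambda_hi` (the surrogate
#' analogue of a hydration free energy when `lambda_lo` is the quasi-gaseous
#' end state).  `restrict` confines the phi integral to one isomer's
#' half-domain.
#'
#' @param system a `surrogate_system`
#' @param lambda_hi,lambda_lo coupling endpoints, `lambda_hi > lambda_lo`
#' @param restrict one of `"all"`, `"E"`, `"Z"`
#' @param n_grid phi quadrature size
#' @export
exact_hydration_delta_g <- function(system, lambda_hi = 1, lambda_lo = 0.05,
                                    restrict = "all", n_grid = 2048) {
  if (lambda_hi < lambda_lo) stop("lambda_hi must be >= lambda_lo")
  RT <- system$R_gas * system$T0
  -RT * (log_z(system, 1, lambda_hi, restrict, n_grid) -
         log_z(system, 1, lambda_lo, restrict, n_grid))
}

#' Calibrate the surrogate to printed free-energy targets
#'
#' One-dimensional root-finding sets `a` from the gas-phase E/Z gap,
#' `K_b` from the bare torsional barrier (iterated to self-consistency since
#' the barrier top depends weakly on `a`), and `d_eps` from the
#' solution-phase gap at full coupling.  The returned system reproduces all
#' three targets through the exact quadrature oracles to `tol`.
#'
#' @param gas_dgez target gas-phase (lambda = 0) E/Z gap, kcal/mol
#' @param sol_dgez target solution-phase (lambda = 1) E/Z gap, kcal/mol
#' @param barrier target bare torsional barrier at (s = 1, lambda = 0),
#'   kcal/mol
#' @param N_s,k_s,g,T0 passed to [surrogate_system()]
#' @param n_grid quadrature size used both here and by the oracles
#' @param tol calibration tolerance, kcal/mol
#' @return calibrated `surrogate_system`
#' @export
calibrate_system <- function(gas_dgez = -3.0, sol_dgez = 0.51, barrier = 40,
                             N_s = 32, k_s = 1.0, g = 0.5, T0 = 300,
                             n_grid = 2048, tol = 1e-9) {
  if (barrier < 4 * max(abs(gas_dgez), abs(sol_dgez)))
    stop("calibration error: barrier must dominate the E/Z gaps")
  K_b <- barrier
  a <- abs(gas_dgez)
  mk <- function(K_b, a, d_eps) surrogate_system(K_b, a, d_eps, N_s, k_s, g, T0)
  for (it in 1:8) {
    fa <- function(a.) exact_delta_g_ez(mk(K_b, a., 0), 1, 0, n_grid) - gas_dgez
    a_new <- tryCatch(
      uniroot(fa, lower = -abs(gas_dgez) - 2, upper = abs(gas_dgez) + 2,
              tol = tol / 10, extendInt = "downX")$root,
      error = function(e) stop(sprintf(
        "calibration error (a): %s; bracket f(%g)=%g f(%g)=%g",
        conditionMessage(e), -abs(gas_dgez) - 2, fa(-abs(gas_dgez) - 2),
        abs(gas_dgez) + 2, fa(abs(gas_dgez) + 2))))
    fb <- function(K.) profile_barrier(
      exact_phi_profile(mk(K., a_new, 0), 1, 0, n_grid)) - barrier
    K_new <- tryCatch(
      uniroot(fb, lower = barrier / 2, upper = barrier * 1.5,
              tol = tol / 10)$root,
      error = function(e) stop(sprintf(
        "calibration error (K_b): %s; bracket f(%g)=%g f(%g)=%g",
        conditionMessage(e), barrier / 2, fb(barrier / 2),
        barrier * 1.5, fb(barrier * 1.5))))
    done <- abs(K_new - K_b) < tol && abs(a_new - a) < tol
    K_b <- K_new; a <- a_new
    if (done) break
  }
  fd <- function(d.) exact_delta_g_ez(mk(K_b, a, d.), 1, 1, n_grid) - sol_dgez
  d_eps <- tryCatch(
    uniroot(fd, lower = -1, upper = abs(gas_dgez) + abs(sol_dgez) + 3,
            tol = tol / 10, extendInt = "upX")$root,
    error = function(e) stop(sprintf(
      "calibration error (d_eps): %s", conditionMessage(e))))
  sys <- mk(K_b, a, d_eps)
  sys$calibration <- list(gas_dgez = gas_dgez, sol_dgez = sol_dgez,
                          barrier = barrier, n_grid = n_grid)
  sys
}

#' Serialize a surrogate system to JSON
#' @param system a `surrogate_system`
#' @param path file path
#' @export
write_system <- function(system, path) {
  jsonlite::write_json(unclass(system)[c("K_b", "a", "d_eps", "N_s",
                                         "k_s", "g", "T0", "R_gas")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a surrogate system from JSON
#' @param path file path
#' @export
read_system <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  surrogate_system(as.numeric(x$K_b), as.numeric(x$a), as.numeric(x$d_eps),
                   as.integer(x$N_s), as.numeric(x$k_s), as.numeric(x$g),
                   as.numeric(x$T0))
}

## numerically safe log(sum(exp(x)))
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
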