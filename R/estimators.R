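#' E/Z free-energy gap from target-state populations
#'
#' Classifies each sampled torsional angle (Z <=> |phi| < pi/2) and returns
#' RT log(N_E / N_Z); positive values mean the E isomer is favoured.  The
#' error is block-averaged over `n_blocks` contiguous blocks; when fewer
#' than two blocks contain both isomers the error falls back to the delta
#' method inflated by the statistical inefficiency of the isomer indicator.
#' If an isomer is never visited the result is an "n/a" (`NA` value), the
#' convention used for pathological lambda-hopping runs, not an error.
#'
#' @param samples a `sample_set` (or a numeric vector of phi values)
#' @param slot ladder slot to analyse (1 = target state)
#' @param T temperature, K (defaults to the system's `T0`)
#' @param n_blocks number of blocks for the error estimate
#' @return list with `value`, `stderr`, `n_E`, `n_Z` (kcal/mol)
#' @export
delta_g_ez_from_populations <- function(samples, slot = 1, T = NULL,
                                        n_blocks = 10) {
  if (inherits(samples, "sample_set")) {
    phi <- samples$phi[, slot]
    if (is.null(T)) T <- samples$system$T0
  } else {
    phi <- as.numeric(samples)
    if (is.null(T)) T <- 300
  }
  if (length(phi) == 0) stop("estimator error: empty target-state series")
  RT <- R_GAS * T
  is_e <- abs(phi) >= pi / 2
  n_E <- sum(is_e); n_Z <- sum(!is_e)
  if (n_E == 0 || n_Z == 0)
    return(list(value = NA_real_, stderr = NA_real_, n_E = n_E, n_Z = n_Z))
  value <- RT * log(n_E / n_Z)
  blk <- split(is_e, ceiling(seq_along(is_e) / (length(is_e) / n_blocks)))
  bv <- vapply(blk, function(b) {
    e <- sum(b); z <- sum(!b)
    if (e == 0 || z == 0) NA_real_ else RT * log(e / z)
  }, numeric(1))
  bv <- bv[!is.na(bv)]
  ## delta-method error inflated by the indicator's statistical
  ## inefficiency; blocks that miss an isomer entirely bias the block
  ## estimate low, so report the more conservative of the two
  g <- statistical_inefficiency(as.numeric(is_e))
  se_delta <- RT * sqrt((1 / n_E + 1 / n_Z) * g)
  se_block <- if (length(bv) >= 2) sd(bv) / sqrt(length(bv)) else NA_real_
  list(value = value, stderr = max(se_block, se_delta, na.rm = TRUE),
       n_E = n_E, n_Z = n_Z)
}

#' Statistical inefficiency of a time series
#'
#' g = 1 + 2 sum_t (1 - t/N) rho_t, with the autocorrelation sum truncated
#' at the first negative value.  The decorrelated sample size is N / g.
#' @param x numeric series
#' @param lag_max maximum lag examined
#' @export
statistical_inefficiency <- function(x, lag_max = min(length(x) - 1, 2000)) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(1)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  t <- seq_along(rho)
  max(1, 1 + 2 * sum((1 - t / n) * rho))
}

#' Build a reduced-energy matrix from a replica-exchange sample set
#'
#' Pools all slots' samples and evaluates the dimensionless energy of every
#' pooled sample at every ladder state, reconstructed exactly from the
#' stored energy components (u is linear in (s, lambda); no re-simulation).
#'
#' @param samples a `sample_set`
#' @param subsample either `"auto"` (decorrelate using the integrated
#'   autocorrelation time of the solute-solvent energy at the target state),
#'   a positive integer stride, or 1 for no subsampling
#' @return object of class `reduced_energy_matrix`: list with `u`
#'   (K x N matrix), `N_k`, `phi` (pooled), `origin` (source slot per
#'   sample), `states` (s, lambda per row) and `RT`
#' @export
reduced_energy_matrix <- function(samples, subsample = 1) {
  ld <- samples$ladder
  K <- ld$N_rep
  if (identical(subsample, "auto")) {
    g <- statistical_inefficiency(samples$v_sS[, 1] + samples$v_S[, 1])
    subsample <- max(1L, ceiling(g))
  }
  idx <- seq(1, nrow(samples$phi), by = subsample)
  beta <- beta_of(samples$system)
  vs <- as.vector(samples$v_s[idx, , drop = FALSE])
  vS <- as.vector(samples$v_S[idx, , drop = FALSE])
  vsS <- as.vector(samples$v_sS[idx, , drop = FALSE])
  u <- matrix(0, nrow = K, ncol = length(vs))
  for (k in seq_len(K))
    u[k, ] <- beta * (vs + ld$s_intra[k] * vS + ld$lambda[k] * vsS)
  structure(list(u = u, N_k = rep(length(idx), K),
                 phi = as.vector(samples$phi[idx, , drop = FALSE]),
                 origin = rep(seq_len(K), each = length(idx)),
                 states = data.frame(s_intra = ld$s_intra,
                                     lambda = ld$lambda),
                 RT = samples$system$R_gas * samples$system$T0,
                 subsample = subsample),
            class = "reduced_energy_matrix")
}

## log(sum(exp(x))) down matrix columns, numerically safe
col_log_sum_exp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx))))
}

#' Solve the MBAR self-consistent equations
#'
#' Estimates the dimensionless free energies f_k of all states from the
#' pooled samples by damped self-consistent iteration followed by a Newton
#' polish on the log-sum-exp gradient; every exponential goes through
#' log-sum-exp so 40 kcal/mol energy scales cannot overflow.  Gauge is
#' fixed by f_1 = 0.
#'
#' @param mat a `reduced_energy_matrix`, or a plain K x N matrix of reduced
#'   energies (then `N_k` must be given)
#' @param N_k samples contributed by each state (defaults to the matrix's)
#' @param tol convergence threshold on max |delta f|
#' @param max_iter iteration cap
#' @param damping self-consistent step damping factor
#' @return object of class `mbar_result`: list with `f_k`, `converged`,
#'   `residual`, `iterations`, `log_denom` (per-sample log denominators)
#' @export
mbar_solve <- function(mat, N_k = NULL, tol = 1e-10, max_iter = 2000,
                       damping = 0.5) {
  if (inherits(mat, "reduced_energy_matrix")) {
    u <- mat$u
    if (is.null(N_k)) N_k <- mat$N_k
  } else {
    u <- mat
    if (is.null(N_k)) stop("estimator error: N_k required for a bare matrix")
  }
  K <- nrow(u)
  if (sum(N_k > 0) < 1) stop("estimator error: no states with samples")
  if (any(!is.finite(u))) stop("estimator error: non-finite reduced energies")
  logN <- ifelse(N_k > 0, log(N_k), -Inf)
  f <- numeric(K)
  log_denom <- function(f) col_log_sum_exp(sweep(u, 1, f + logN, function(a, b) b - a))
  resid <- Inf; it <- 0
  while (it < max_iter) {
    it <- it + 1
    ld <- log_denom(f)
    fn <- -apply(sweep(-u, 2, ld, "-"), 1, log_sum_exp)
    fn <- fn - fn[1]
    resid <- max(abs(fn - f))
    if (resid < tol) { f <- fn; break }
    if (resid < 1e-2 && K > 1) {
      ## Newton polish on the reduced (f_1 fixed) gradient
      f <- fn
      for (nw in 1:50) {
        ld <- log_denom(f)
        W <- exp(sweep(sweep(u, 1, f, function(a, b) b - a), 2, ld))  # K x N
        grad <- N_k * (rowSums(W) - 1)
        NW <- N_k * W
        H <- diag(N_k * rowSums(W), K) - NW %*% t(NW)
        step <- tryCatch(solve(H[-1, -1, drop = FALSE], -grad[-1]),
                         error = function(e) NULL)
        if (is.null(step)) break
        f[-1] <- f[-1] + step
        resid <- max(abs(step))
        if (resid < tol) break
      }
      ld <- log_denom(f)
      fn <- -apply(sweep(-u, 2, ld, "-"), 1, log_sum_exp)
      fn <- fn - fn[1]
      resid <- max(abs(fn - f))
      f <- fn
      break
    }
    f <- f + damping * (fn - f)
  }
  if (resid >= tol * 10 && resid > 1e-8)
    stop(sprintf("estimator error: MBAR did not converge (residual %.3g)",
                 resid))
  structure(list(f_k = f, converged = resid < max(tol * 10, 1e-8),
                 residual = resid, iterations = it,
                 log_denom = log_denom(f), N_k = N_k),
            class = "mbar_result")
}

#' Per-sample weights of a target state from an MBAR solution
#' @param mat a `reduced_energy_matrix`
#' @param mbar an `mbar_result`
#' @param target target state index
#' @return normalized weights (sum to 1)
#' @export
mbar_weights <- function(mat, mbar, target = 1) {
  lw <- -mat$u[target, ] - mbar$log_denom
  w <- exp(lw - log_sum_exp(lw))
  w / sum(w)
}

#' Two-state Bennett acceptance ratio (Crooks instantaneous switching)
#'
#' Solves the Bennett self-consistency equation for the dimensionless free
#' energy difference f_2 - f_1 from forward work values (u_2 - u_1 on
#' state-1 samples) and reverse work values (u_1 - u_2 on state-2 samples).
#' Equals the two-state MBAR solution; the test suite asserts that
#' equivalence rather than sharing code.
#'
#' @param w_f forward reduced work values
#' @param w_r reverse reduced work values
#' @return list with `delta_f` (RT units) and `overlap_warning`
#' @export
bar_delta_f <- function(w_f, w_r) {
  if (!length(w_f) || !length(w_r))
    stop("estimator error: empty work sample")
  M <- log(length(w_f) / length(w_r))
  h <- function(x)
    sum(stats::plogis(-(M + w_f - x))) - sum(stats::plogis(-(-M + w_r + x)))
  ## bracket from the two one-sided exponential-averaging estimates
  ef <- -log_sum_exp(-w_f) + log(length(w_f))
  er <- log_sum_exp(-w_r) - log(length(w_r))
  lo <- min(ef, er) - 5; hi <- max(ef, er) + 5
  root <- uniroot(h, lower = lo, upper = hi, extendInt = "yes",
                  tol = 1e-12)$root
  overlap <- min(max(w_f), max(-w_r)) - max(min(w_f), min(-w_r))
  list(delta_f = root, overlap_warning = !is.finite(overlap) || overlap <= 0)
}

#' Neighbour free-energy increments along a ladder
#'
#' For each edge k -> k+1 computes the dimensionless free-energy difference
#' f_{k+1} - f_k, either by per-edge BAR on the stored energy components
#' (instantaneous switches; no extra sampling since u is linear in
#' (s, lambda)) or from a full MBAR solution.
#'
#' @param mat a `reduced_energy_matrix`
#' @param method `"bar"` or `"mbar"`
#' @return numeric vector of length K - 1 (RT units)
#' @export
neighbor_delta_f <- function(mat, method = c("bar", "mbar")) {
  method <- match.arg(method)
  K <- nrow(mat$u)
  if (method == "mbar") return(diff(mbar_solve(mat)$f_k))
  vapply(seq_len(K - 1), function(k) {
    ik <- mat$origin == k
    ik1 <- mat$origin == k + 1
    bar_delta_f(mat$u[k + 1, ik] - mat$u[k, ik],
                mat$u[k, ik1] - mat$u[k + 1, ik1])$delta_f
  }, numeric(1))
}

#' Stratified free-energy total and its hydration-scale value
#'
#' Plain telescoping sum of the per-edge increments f_{k+1} - f_k down the
#' ladder (the stratification identity).  For a lambda ladder ordered from
#' full coupling (state 1) to the quasi-gaseous state, the coupling free
#' energy F(lambda = 1) - F(lambda_min) -- the surrogate analogue of the
#' hydration free energy -- is minus RT times that total.
#'
#' @param delta_f_k vector of per-edge dimensionless increments
#' @param RT RT in kcal/mol (to convert; default 300 K value)
#' @return list with `delta_f_total` (RT units) and `delta_g` (kcal/mol)
#' @export
stratified_delta_f <- function(delta_f_k, RT = R_GAS * 300) {
  tot <- sum(delta_f_k)
  list(delta_f_total = tot, delta_g = -RT * tot)
}

#' MBAR-reweighted free-energy profile along the torsional angle
#'
#' Minus RT log of the target-state-weighted bin masses over (-pi, pi],
#' shifted so the minimum is zero.  Bins with zero weight are reported as
#' `NA` (missing), not infinite.
#'
#' @param mat a `reduced_energy_matrix`
#' @param mbar an `mbar_result` for `mat`
#' @param target target state index
#' @param n_bins number of phi bins
#' @return data.frame with `phi`, `free_energy`, `mass`
#' @export
mbar_pmf <- function(mat, mbar, target = 1, n_bins = 72) {
  w <- mbar_weights(mat, mbar, target)
  br <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(mat$phi, br, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
  if (sum(mass > 0) <= 1)
    warning("degenerate profile: all weight in one bin")
  fe <- ifelse(mass > 0, -mat$RT * log(mass), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  data.frame(phi = (br[-1] + br[-(n_bins + 1)]) / 2,
             free_energy = fe, mass = mass)
}

#' Mixture (de)coupling free energy from per-isomer values (as printed)
#'
#' Evaluates
#' \deqn{\Delta G = \Delta G_E - RT \ln\left[\frac{1}{1 + R_{Z/E}} +
#'   \frac{e^{-\beta(\Delta G_Z - \Delta G_E)}}{1 + R_{E/Z}}\right]}
#' with \eqn{R_{E/Z} = 1 / R_{Z/E}}.  This combines the hydration free
#' energies of the two isomers into that of the thermodynamic mixture.  The
#' expression is an exact identity when `r_ze` is the Z/E population ratio
#' of the DECOUPLED (quasi-gaseous) end state; evaluated with the
#' fully-coupled (solution) target-state ratio it reproduces the source
#' material's printed worked examples.  See
#' [transport_ratio_to_decoupled()] for converting one into the other.
#'
#' @param dg_E,dg_Z per-isomer hydration free energies, kcal/mol
#' @param r_ze Z/E population ratio (> 0)
#' @param T temperature, K
#' @export
mixture_delta_g <- function(dg_E, dg_Z, r_ze, T = 300) {
  if (!is.finite(r_ze) || r_ze <= 0)
    stop("estimator error: r_ze must be positive")
  RT <- R_GAS * T
  dg_E - RT * log(1 / (1 + r_ze) + exp(-(dg_Z - dg_E) / RT) / (1 + 1 / r_ze))
}

#' E/Z ratio implied by a free-energy gap
#'
#' Under the convention delta_g_ez = RT log(P_E/P_Z) (positive favours E),
#' R_E/Z = exp(delta_g_ez / RT); R_Z/E is its reciprocal.
#' @param dg_ez E/Z free-energy gap, kcal/mol
#' @param T temperature, K
#' @return R_E/Z
#' @export
ratio_from_delta_g_ez <- function(dg_ez, T = 300) {
  stopifnot(is.finite(dg_ez))
  exp(dg_ez / (R_GAS * T))
}

#' Transport a coupled-state Z/E ratio to the decoupled end state
#'
#' Thermodynamic-cycle identity
#' \deqn{R^{gas}_{Z/E} = R^{sol}_{Z/E}\, e^{\beta(\Delta G_Z - \Delta G_E)}}
#' connecting the isomer ratio at full coupling to the ratio at the
#' decoupled end through the per-isomer (de)coupling free energies.  The
#' result is the ratio for which [mixture_delta_g()] is an exact identity.
#'
#' @param r_ze_coupled Z/E ratio at full coupling (target state)
#' @param dg_E,dg_Z per-isomer hydration free energies, kcal/mol
#' @param T temperature, K
#' @export
transport_ratio_to_decoupled <- function(r_ze_coupled, dg_E, dg_Z, T = 300) {
  r_ze_coupled * exp((dg_Z - dg_E) / (R_GAS * T))
}

#' Full stratified hydration pipeline for one run
#'
#' Convenience wrapper: reduced-energy matrix (with decorrelation), MBAR
#' solve, per-edge increments (MBAR and BAR routes), Eq.-2-style total, and
#' the hydration-scale free energy.  Uncertainty, when requested, is a
#' bootstrap over decorrelated samples (resampling within each state,
#' fixed seed).
#'
#' @param samples a `sample_set` from a lambda ladder
#' @param subsample passed to [reduced_energy_matrix()]
#' @param n_boot bootstrap resamples (0 to skip)
#' @param boot_seed bootstrap RNG seed
#' @return list with `delta_f_k` (BAR route), `delta_f_k_mbar`,
#'   `delta_f_total`, `delta_g`, `delta_g_se`, `mbar`, `mat`
#' @export
hydration_from_samples <- function(samples, subsample = "auto", n_boot = 0,
                                   boot_seed = 1L) {
  mat <- reduced_energy_matrix(samples, subsample = subsample)
  mbar <- mbar_solve(mat)
  dfk_bar <- neighbor_delta_f(mat, "bar")
  dfk_mbar <- diff(mbar$f_k)
  strat <- stratified_delta_f(dfk_mbar, RT = mat$RT)
  se <- NA_real_
  if (n_boot > 0) {
    K <- nrow(mat$u); n <- mat$N_k[1]
    boot <- withr_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- as.vector(vapply(seq_len(K), function(k)
          (k - 1) * n + sample.int(n, n, replace = TRUE), numeric(n)))
        m2 <- mat; m2$u <- mat$u[, idx, drop = FALSE]
        -m2$RT * sum(diff(mbar_solve(m2, tol = 1e-8)$f_k))
      }, numeric(1))
    })
    se <- sd(boot)
  }
  list(delta_f_k = dfk_bar, delta_f_k_mbar = dfk_mbar,
       delta_f_total = strat$delta_f_total, delta_g = strat$delta_g,
       delta_g_se = se, mbar = mbar, mat = mat)
}

## evaluate expr under a temporary RNG seed, restoring the caller's state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}
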