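#' Metropolis swap acceptance probability
#'
#' @param delta dimensionless swap energy
#'   beta * (U_i(x_j) + U_j(x_i) - U_i(x_i) - U_j(x_j))
#' @return min(1, exp(-delta))
#' @export
swap_acceptance <- function(delta) pmin(1, exp(-delta))

#' One Metropolis sweep (reference R implementation)
#'
#' A single canonical pass at ladder point (s, lambda): one wrapped uniform
#' proposal on phi of half-width `dphi`, then a Gaussian random-walk proposal
#' on each solvent coordinate.  Leaves the Boltzmann distribution at
#' (s, lambda) invariant.  This is the readable reference for the compiled
#' kernel used by [run_replica_exchange()]; the two are checked against each
#' other distributionally in the test suite.
#'
#' @param system a `surrogate_system`
#' @param config list with `phi` (scalar) and `y` (length `N_s`)
#' @param s_intra,lambda ladder point
#' @param dphi torsional proposal half-width, radians
#' @param sigma_y solvent proposal standard deviation
#' @return updated config
#' @export
mc_sweep <- function(system, config, s_intra, lambda,
                     dphi = 0.3, sigma_y = 0.5) {
  beta <- beta_of(system)
  vphi <- function(phi)
    s_intra * (0.5 * system$K_b * (1 - cos(2 * phi)) +
               0.5 * system$a * (1 - cos(phi))) -
      lambda * 0.5 * system$d_eps * (1 - cos(phi))
  if (dphi > 0) {
    phin <- wrap_phi(config$phi + runif(1, -dphi, dphi))
    du <- beta * (vphi(phin) - vphi(config$phi))
    if (du <= 0 || runif(1) < exp(-du)) config$phi <- phin
  }
  if (system$N_s > 0 && sigma_y > 0) {
    keff <- 0.5 * beta * (system$k_s + lambda * system$g)
    yn <- config$y + rnorm(system$N_s, 0, sigma_y)
    acc <- log(runif(system$N_s)) < -keff * (yn^2 - config$y^2)
    config$y[acc] <- yn[acc]
  }
  config
}

## per-slot torsional proposal widths: scaled with the thermal width of the
## state (prop. 1/sqrt(s)), clamped, so hot replicas diffuse across the
## barrier at a useful rate; lambda-hopping ladders (s == 1) keep the base
## width everywhere.
dphi_schedule <- function(s_intra, dphi, scale_dphi, dphi_max) {
  if (!scale_dphi) return(rep(dphi, length(s_intra)))
  pmin(dphi / sqrt(s_intra), dphi_max)
}

#' Run a replica-exchange Monte Carlo simulation
#'
#' Canonically samples every ladder point with Metropolis Monte Carlo and
#' attempts Metropolis-regulated configuration swaps between neighbouring
#' slots every `swap_interval` sweeps, on alternating even/odd edge sets.
#' All replicas start at the bottom of the `init` isomer's well (phi = 0 for
#' Z, phi = pi for E) with the solvent coordinates at zero; `burn_in` sweeps
#' are discarded before sampling.  Deterministic given `seed`.
#'
#' @param system a `surrogate_system`
#' @param ladder a `rem_ladder`
#' @param n_sweeps number of MC sweeps per replica
#' @param swap_interval sweeps between swap-attempt rounds
#' @param init initial isomer, `"E"` or `"Z"`
#' @param seed integer RNG seed
#' @param sample_interval sweeps between stored samples
#' @param burn_in sweeps discarded before sampling starts
#' @param dphi base torsional proposal half-width, radians
#' @param sigma_y solvent proposal standard deviation
#' @param scale_dphi widen hot-replica proposals as 1/sqrt(s)?
#' @param dphi_max cap on the scaled proposal width
#' @return list with elements `samples` (a `sample_set`) and `trace`
#'   (a `swap_trace`)
#' @export
run_replica_exchange <- function(system, ladder, n_sweeps,
                                 swap_interval = 10, init = c("Z", "E"),
                                 seed = 1L, sample_interval = 10,
                                 burn_in = 1000, dphi = 0.3, sigma_y = 0.5,
                                 scale_dphi = TRUE, dphi_max = 1.5) {
  init <- match.arg(init)
  if (!inherits(ladder, "rem_ladder")) stop("protocol error: need a rem_ladder")
  if (n_sweeps < swap_interval || swap_interval < 1)
    stop("protocol error: need n_sweeps >= swap_interval >= 1")
  if (any(ladder$s_intra <= 0) || any(ladder$lambda < 0 | ladder$lambda > 1))
    stop("protocol error: invalid ladder scaling factors")
  K <- ladder$N_rep
  phi0 <- rep(if (init == "Z") 0 else pi, K)
  dphi_vec <- dphi_schedule(ladder$s_intra, dphi, scale_dphi, dphi_max)
  raw <- .rem_run_cpp(system$K_b, system$a, system$d_eps, system$N_s,
                      system$k_s, system$g, beta_of(system),
                      ladder$s_intra, ladder$lambda, dphi_vec, sigma_y,
                      as.double(n_sweeps), as.integer(swap_interval),
                      as.integer(sample_interval), as.integer(burn_in),
                      phi0, as.double(seed))
  meta <- list(protocol = ladder$protocol, init = init, seed = seed,
               n_sweeps = n_sweeps, swap_interval = swap_interval,
               sample_interval = sample_interval, burn_in = burn_in,
               dphi = dphi_vec, sigma_y = sigma_y,
               phi_move_rate = raw$phi_move_rate,
               y_move_rate = raw$y_move_rate)
  samples <- structure(
    list(phi = raw$phi, v_s = raw$v_s, v_S = raw$v_S, v_sS = raw$v_sS,
         sweep = raw$sample_sweep, ladder = ladder, system = system,
         meta = meta),
    class = "sample_set")
  trace <- structure(
    list(attempts = raw$attempts, accepts = raw$accepts,
         walker_slot = raw$walker_slot, round_sweep = raw$round_sweep,
         swap_interval = swap_interval, N_rep = K, meta = meta),
    class = "swap_trace")
  list(samples = samples, trace = trace)
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %s, %d slots x %d samples (interval %d, init %s)\n",
              x$meta$protocol, ncol(x$phi), nrow(x$phi),
              x$meta$sample_interval, x$meta$init))
  invisible(x)
}

#' @export
print.swap_trace <- function(x, ...) {
  cat(sprintf("swap_trace: %d edges, %d swap rounds\n",
              length(x$attempts), nrow(x$walker_slot)))
  if (length(x$attempts))
    cat("  acceptance per edge:",
        paste(sprintf("%.2f", x$accepts / pmax(x$attempts, 1)),
              collapse = " "), "\n")
  invisible(x)
}

#' Persist a sample set as gzipped TSV plus a JSON metadata sidecar
#' @param samples a `sample_set`
#' @param path output path (".tsv.gz" recommended); the sidecar is
#'   `paste0(path, ".json")`
#' @export
write_sample_set <- function(samples, path) {
  K <- ncol(samples$phi)
  df <- data.frame(
    sweep = rep(samples$sweep, K),
    slot = rep(seq_len(K), each = nrow(samples$phi)),
    phi = as.vector(samples$phi), v_s = as.vector(samples$v_s),
    v_S = as.vector(samples$v_S), v_sS = as.vector(samples$v_sS))
  con <- gzfile(path, "w")
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  meta <- samples$meta
  meta$ladder <- as.data.frame(samples$ladder)
  meta$ladder_info <- samples$ladder[c("protocol", "S_min", "lambda_min", "T0")]
  meta$system <- unclass(samples$system)[c("K_b", "a", "d_eps", "N_s",
                                           "k_s", "g", "T0")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sample set written by [write_sample_set()]
#' @param path path given to [write_sample_set()]
#' @export
read_sample_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(gzfile(path), header = TRUE, sep = "\t")
  K <- max(df$slot)
  n <- nrow(df) / K
  li <- meta$ladder_info
  ladder <- new_ladder(li$protocol, meta$ladder$s_intra, meta$ladder$lambda,
                       li$S_min, li$lambda_min, li$T0)
  system <- surrogate_system(meta$system$K_b, meta$system$a,
                             meta$system$d_eps, meta$system$N_s,
                             meta$system$k_s, meta$system$g, meta$system$T0)
  shape <- function(v) matrix(v, nrow = n, ncol = K)
  structure(list(phi = shape(df$phi), v_s = shape(df$v_s),
                 v_S = shape(df$v_S), v_sS = shape(df$v_sS),
                 sweep = df$sweep[seq_len(n)], ladder = ladder,
                 system = system,
                 meta = meta[setdiff(names(meta),
                                     c("ladder", "ladder_info", "system"))]),
            class = "sample_set")
}
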