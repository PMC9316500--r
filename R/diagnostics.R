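#' Per-edge exchange ratios
#'
#' The exchange ratio (accepted / attempted swaps per neighbour pair) is the
#' standard proxy for the overlap of the energy distributions that regulate
#' the exchange.
#'
#' @param trace a `swap_trace`
#' @return list with `ratios` (per edge), `range` (min, max) and a
#'   `summary` string formatted "min-max%"
#' @export
exchange_ratios <- function(trace) {
  if (length(trace$attempts) == 0)
    return(list(ratios = numeric(0), range = c(NA_real_, NA_real_),
                summary = "n/a"))
  if (any(trace$attempts == 0))
    stop("diagnostics error: zero swap attempts on some edge")
  r <- trace$accepts / trace$attempts
  list(ratios = r, range = range(r),
       summary = sprintf("%.0f-%.0f%%", 100 * min(r), 100 * max(r)))
}

#' Round-trip times of the replica walkers
#'
#' A round trip is one walker's journey slot 1 -> slot N_rep -> slot 1
#' (target end to most-scaled end and back).  Durations are pooled over all
#' walkers; the standard error is that of the pooled sample.  Times are
#' reported in sweeps (and swap rounds); they are not comparable to
#' physical-time round-trip times of a molecular-dynamics run.
#'
#' @param trace a `swap_trace`
#' @return list with `mean`, `stderr`, `count`, and per-trip durations
#'   `trips` (sweeps); `mean` is `NA` when `count` is 0
#' @export
round_trip_times <- function(trace) {
  K <- trace$N_rep
  if (K < 2) stop("diagnostics error: need N_rep >= 2")
  H <- trace$walker_slot             # rounds x walkers, entries in 1..K
  trips <- numeric(0)
  for (w in seq_len(ncol(H))) {
    pos <- H[, w]
    ## state machine: wait for slot 1, then slot K, then slot 1 again
    t_start <- NA_real_
    seen_top <- FALSE
    for (r in seq_along(pos)) {
      if (pos[r] == 1) {
        if (seen_top && !is.na(t_start)) {
          trips <- c(trips, trace$round_sweep[r] - t_start)
          seen_top <- FALSE
        }
        t_start <- trace$round_sweep[r]
      } else if (pos[r] == K && !is.na(t_start)) {
        seen_top <- TRUE
      }
    }
  }
  n <- length(trips)
  list(mean = if (n) mean(trips) else NA_real_,
       stderr = if (n > 1) sd(trips) / sqrt(n) else NA_real_,
       count = n, trips = trips,
       mean_rounds = if (n) mean(trips) / trace$swap_interval else NA_real_)
}

#' Normalized torsional-angle histogram for one ladder slot
#'
#' @param samples a `sample_set`
#' @param slot slot index (1 = target state)
#' @param n_bins number of bins over (-pi, pi] (>= 8)
#' @return data.frame with `phi` (bin centers) and `p` (probability mass)
#' @export
dihedral_histogram <- function(samples, slot = 1, n_bins = 72) {
  stopifnot(n_bins >= 8)
  phi <- samples$phi[, slot]
  if (length(phi) == 0) stop("diagnostics error: empty sample set")
  br <- seq(-pi, pi, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(phi, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  data.frame(phi = (br[-1] + br[-(n_bins + 1)]) / 2, p = cnt / sum(cnt))
}

#' Detect initial-condition dependence between an E-start and a Z-start run
#'
#' Computes the target-state E/Z free-energy gap for both runs.  If either
#' run never visits one of the isomers in its target state the verdict is
#' `"n/a"` (the convention used for pathological lambda-hopping runs);
#' otherwise the pair is `"converged"` when the two estimates agree within
#' `n_sigma` combined standard errors.
#'
#' @param run_E,run_Z `sample_set`s started from the E and Z isomer
#' @param slot target-state slot
#' @param n_sigma agreement threshold in combined standard errors
#' @param n_blocks blocks for the block-averaged errors
#' @return list with `verdict` ("converged", "not converged" or "n/a"),
#'   `gap`, `gap_se`, and both per-run estimates
#' @export
initial_condition_dependence <- function(run_E, run_Z, slot = 1,
                                         n_sigma = 3, n_blocks = 10) {
  dE <- delta_g_ez_from_populations(run_E, slot = slot, n_blocks = n_blocks)
  dZ <- delta_g_ez_from_populations(run_Z, slot = slot, n_blocks = n_blocks)
  if (is.na(dE$value) || is.na(dZ$value))
    return(list(verdict = "n/a", gap = NA_real_, gap_se = NA_real_,
                estimate_E = dE, estimate_Z = dZ))
  gap <- dE$value - dZ$value
  se <- sqrt(dE$stderr^2 + dZ$stderr^2)
  list(verdict = if (abs(gap) <= n_sigma * se) "converged" else
         "not converged",
       gap = gap, gap_se = se, estimate_E = dE, estimate_Z = dZ)
}

#' Per-slot isomer populations
#' @param samples a `sample_set`
#' @return data.frame with slot, P(E), P(Z)
#' @export
isomer_populations <- function(samples) {
  pe <- colMeans(abs(samples$phi) >= pi / 2)
  data.frame(slot = seq_along(pe), p_E = pe, p_Z = 1 - pe)
}
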