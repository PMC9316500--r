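#' Geometric scaling schedule
#'
#' The standard replica-exchange scaling rule
#' \deqn{s_m = S_{min}^{(m-1)/(N_{rep}-1)}, \qquad m = 1, \dots, N_{rep},}
#' strictly decreasing from 1 to `S_min` and log-linear in m.
#'
#' @param S_min minimum scaling factor, in (0, 1]
#' @param N_rep number of replicas (>= 2)
#' @export
geometric_schedule <- function(S_min, N_rep) {
  if (!is.numeric(S_min) || S_min <= 0 || S_min > 1)
    stop("protocol error: S_min must be in (0, 1]")
  if (N_rep < 2) stop("protocol error: N_rep must be >= 2")
  S_min^((seq_len(N_rep) - 1) / (N_rep - 1))
}

new_ladder <- function(protocol, s_intra, lambda, S_min, lambda_min, T0 = 300) {
  stopifnot(length(s_intra) == length(lambda))
  ld <- list(protocol = protocol,
             m = seq_along(s_intra),
             s_intra = s_intra,
             lambda = lambda,
             S_min = S_min,
             lambda_min = lambda_min,
             N_rep = length(s_intra),
             T0 = T0)
  class(ld) <- "rem_ladder"
  ld
}

#' Temperature-REM ladder (gas phase)
#'
#' Solute intramolecular scaling descends geometrically; the solute-solvent
#' coupling is off (lambda = 0) everywhere.  Slot 1 is the target state.
#' @inheritParams geometric_schedule
#' @param T0 target temperature, K
#' @export
trem_ladder <- function(S_min, N_rep, T0 = 300)
  new_ladder("t-REM", geometric_schedule(S_min, N_rep),
             rep(0, N_rep), S_min, 0, T0)

#' Solute-tempering HREM ladder (solution)
#'
#' Only the solute intramolecular potential is scaled (descending
#' geometrically); solvent and solute-solvent terms stay cold (lambda = 1).
#' @inheritParams trem_ladder
#' @export
st_hrem_ladder <- function(S_min, N_rep, T0 = 300)
  new_ladder("ST-HREM", geometric_schedule(S_min, N_rep),
             rep(1, N_rep), S_min, 1, T0)

#' Pure lambda-hopping ladder
#'
#' The ladder states are the alchemical lambda states themselves:
#' lambda descends geometrically from 1 to `lambda_min` while the solute
#' intramolecular potential is never scaled (s = 1 everywhere).
#' @param lambda_min minimum coupling, in (0, 1]
#' @inheritParams trem_ladder
#' @export
lambda_hop_ladder <- function(lambda_min, N_rep, T0 = 300)
  new_ladder("lambda-hop", rep(1, N_rep),
             geometric_schedule(lambda_min, N_rep), 1, lambda_min, T0)

#' FEP+-style ladder: lambda stratification plus hot zone
#'
#' lambda descends as in [lambda_hop_ladder()]; on top of it the solute
#' intramolecular potential is scaled with a "tent in log-space" profile
#' \deqn{s_m = S_{min}^{\,1 - |m - c|/(c - 1)}, \qquad c = (N_{rep}+1)/2,}
#' equal to 1 at both end states and reaching `S_min` at the ladder center
#' (for even `N_rep` the two central slots share the near-minimum value).
#' The shape between the stated endpoints and center is a package choice:
#' it reuses the geometric rule on each half, symmetric about the center.
#'
#' @inheritParams lambda_hop_ladder
#' @param S_min minimum hot-zone scaling at the ladder center
#' @export
feplus_ladder <- function(lambda_min, S_min, N_rep, T0 = 300) {
  if (N_rep < 3) stop("protocol error: FEP+ ladder needs N_rep >= 3")
  if (S_min <= 0 || S_min > 1) stop("protocol error: S_min must be in (0, 1]")
  m <- seq_len(N_rep)
  cc <- (N_rep + 1) / 2
  s <- S_min^(1 - abs(m - cc) / (cc - 1))
  new_ladder("FEP+", s, geometric_schedule(lambda_min, N_rep),
             S_min, lambda_min, T0)
}

#' Single-state "ladder" (plain Monte Carlo, no exchanges)
#' @param s_intra,lambda the one ladder point
#' @param T0 target temperature, K
#' @export
single_state_ladder <- function(s_intra = 1, lambda = 1, T0 = 300)
  new_ladder("single", s_intra, lambda, s_intra, lambda, T0)

#' Effective solute temperature of a scaling factor
#'
#' Scaling a potential-energy term by s is equivalent to sampling it at
#' temperature T0 / s: S = 0.1 at 300 K corresponds to 3000 K.
#' @param s scaling factor in (0, 1]
#' @param T0 target temperature, K
#' @export
effective_temperature <- function(s, T0 = 300) {
  if (any(s <= 0)) stop("protocol error: s must be positive")
  T0 / s
}

#' @export
as.data.frame.rem_ladder <- function(x, ...) {
  data.frame(m = x$m, s_intra = x$s_intra, lambda = x$lambda,
             T_eff = effective_temperature(x$s_intra, x$T0))
}

#' @export
print.rem_ladder <- function(x, ...) {
  cat(sprintf("%s ladder, %d replicas (S_min = %g, lambda_min = %g)\n",
              x$protocol, x$N_rep, x$S_min, x$lambda_min))
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a ladder as delimited text (with a metadata header)
#' @param ladder a `rem_ladder`
#' @param path file path
#' @export
write_ladder <- function(ladder, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protocol=%s S_min=%.17g lambda_min=%.17g T0=%.17g",
                     ladder$protocol, ladder$S_min, ladder$lambda_min,
                     ladder$T0), con)
  df <- as.data.frame(ladder)
  df$s_intra <- sprintf("%.17g", df$s_intra)
  df$lambda <- sprintf("%.17g", df$lambda)
  df$T_eff <- sprintf("%.17g", df$T_eff)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ladder written by [write_ladder()]; the round trip is exact.
#' @param path file path
#' @export
read_ladder <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[A-Za-z0-9_]+=[^ ]+", hdr))[[1]]
  meta <- setNames(lapply(kv, function(s) sub("^[^=]+=", "", s)),
                   sub("=.*$", "", kv))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          colClasses = c("integer", rep("numeric", 3)))
  new_ladder(meta$protocol, df$s_intra, df$lambda,
             as.numeric(meta$S_min), as.numeric(meta$lambda_min),
             as.numeric(meta$T0))
}
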