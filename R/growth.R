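# Scalar elongation kinetics.
#
# Main axes follow the negative-exponential law G(t) = k (1 - exp(-r t / k)):
# growth starts at rate r (cm/day) and saturates at the maximal length k
# (cm). A strand's realized length is EF(t) = G(t) * LD * SL_effect, where LD
# is its per-strand normalized length multiplier and SL_effect the hormone
# multiplier, both fixed at strand initiation. Laterals use the same law with
# their own maximal length k_lat and the decaying initial rate
# r_lat(t) = 6.4 exp(-0.8 t).

#' Main-axis growth function G(t)
#'
#' `G(t) = k (1 - exp(-r t / k))`: strictly increasing from 0, initial slope
#' `r`, asymptote `k`.
#'
#' @param t time since strand initiation (days, >= 0; vectorised).
#' @param k maximal root length (cm).
#' @param r initial growth rate (cm/day).
#' @return Length(s) in cm.
#' @examples
#' growth_G(30, 22.67, 2)
#' @export
growth_G <- function(t, k, r) {
  if (any(t < 0)) stop("t must be >= 0")
  k * (1 - exp(-r * t / k))
}

#' Lateral-root initial growth rate r_lat(t)
#'
#' Exponentially decaying rate `coeff * exp(-decay * t)`, 6.4 cm/day at
#' emergence under the default profile.
#'
#' @param t lateral age (days, >= 0; vectorised).
#' @param coeff rate at t = 0 (cm/day).
#' @param decay decay constant (1/day).
#' @return Rate(s) in cm/day.
#' @export
lateral_rate <- function(t, coeff = 6.4, decay = 0.8) {
  if (any(t < 0)) stop("t must be >= 0")
  coeff * exp(-decay * t)
}

#' Lateral-root growth function G_lat(t)
#'
#' The axis growth law with maximal length `k_lat` and the time-dependent
#' rate [lateral_rate()] substituted at the same `t`:
#' `k_lat (1 - exp(-r_lat(t) t / k_lat))`. Bounded above by `k_lat`.
#'
#' @param t lateral age (days, >= 0; vectorised).
#' @param k_lat maximal lateral length (cm).
#' @param coeff,decay parameters of [lateral_rate()].
#' @return Length(s) in cm.
#' @export
growth_Glat <- function(t, k_lat, coeff = 6.4, decay = 0.8) {
  if (any(t < 0)) stop("t must be >= 0")
  k_lat * (1 - exp(-lateral_rate(t, coeff, decay) * t / k_lat))
}

#' Elongation function EF(t)
#'
#' Cumulative strand length `G(t) * LD * sl_mult`. `LD` (normalized length
#' multiplier) and `sl_mult` (SL effect) are drawn once per strand and held
#' fixed for its lifetime.
#'
#' @param t time (days, vectorised).
#' @param k,r kinetic parameters of [growth_G()].
#' @param ld normalized length multiplier (> 0).
#' @param sl_mult SL effect multiplier (> 0).
#' @return Length(s) in cm.
#' @export
elongation_EF <- function(t, k, r, ld, sl_mult) {
  if (ld <= 0 || sl_mult <= 0) stop("ld and sl_mult must be > 0")
  growth_G(t, k, r) * ld * sl_mult
}

#' Per-iteration arc-length increments of a strand
#'
#' Splits \[0, tf\] into `n` equal steps `t_i = i tf / n` and returns the
#' elongation increments `EF(t_i) - EF(t_{i-1})`. The increments are positive,
#' strictly decreasing (G is concave), and telescope exactly to `EF(tf)`
#' whatever `n` is — so a strand's final length does not depend on the grid
#' resolution.
#'
#' @param n number of iterations (>= 1).
#' @param tf final time (days).
#' @inheritParams elongation_EF
#' @return Numeric vector of `n` positive increments (cm).
#' @export
segment_increments <- function(n, tf, k, r, ld, sl_mult) {
  stopifnot(n >= 1, tf > 0)
  diff(elongation_EF(seq(0, tf, length.out = n + 1), k, r, ld, sl_mult))
}
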