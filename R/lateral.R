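# Lateral root branching: candidate branch points along a parent axis, the
# stochastic branch/no-branch rule (LRF) against the stop-branching threshold
# SBT = MedL * SL_effect, and stochastic lateral elongation governed by the
# lateral root growth threshold LRGT.

#' Locate candidate branch points on a parent axis
#'
#' Draws a branching density B (branches per cm) from the parent class's
#' distribution; the maximum possible branch count is
#' `m = round(B * length)`. The median scale MedL is the 1000-draw bootstrap
#' median of the same density distribution times the parent length. The `m`
#' candidate points are placed at equal arc-length spacing along the parent
#' polyline (strictly interior, at arc positions `p * L / (m + 1)`).
#'
#' @param parent_axis a `root_axis`.
#' @param profile a validated `rsa_profile`.
#' @param stream a [rand_stream()].
#' @return An object of class `branching_state`: `m`, `MedL`, `density`,
#'   arc `positions` and an `m` x 3 matrix `points`. A zero-length parent
#'   yields `m = 0`.
#' @export
locate_branch_points <- function(parent_axis, profile, stream = NULL) {
  L <- axis_length(parent_axis$points)
  spec <- profile$dists[[parent_axis$root_class]]$lateral_density_per_cm
  if (L <= 0) {
    return(structure(list(m = 0L, MedL = 0, density = 0,
                          positions = numeric(0),
                          points = matrix(numeric(0), 0, 3)),
                     class = "branching_state"))
  }
  dr <- stream_eval_or(stream, {
    density <- sample_trait(spec, 1, NULL)
    medl_density <- bootstrap_median(spec, profile$params$medl_bootstrap_n, NULL)
    list(density = density, medl = medl_density)
  })
  m <- as.integer(round(dr$density * L))
  positions <- if (m > 0) seq_len(m) * L / (m + 1) else numeric(0)
  structure(list(m = m,
                 MedL = dr$medl * L,
                 density = dr$density,
                 positions = positions,
                 points = polyline_interpolate(parent_axis$points, positions)),
            class = "branching_state")
}

# points at given arc-length positions along a polyline (rows of pts)
polyline_interpolate <- function(pts, positions) {
  if (length(positions) == 0) return(matrix(numeric(0), 0, 3,
                                            dimnames = list(NULL, c("x", "y", "z"))))
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  idx <- findInterval(positions, cum, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(seg)] <- nrow(seg)
  frac <- (positions - cum[idx]) / pmax(seg_len[idx], .Machine$double.eps)
  out <- pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Branch/no-branch decision at a candidate point
#'
#' Draws `P ~ U[0, MaxL]` per decision and branches when `P < SBT`, so the
#' branch probability is `min(SBT / MaxL, 1)`. `SBT = MedL * SL_effect` is
#' the stop-branching threshold.
#'
#' @param MaxL maximum possible branch count of the strand (> 0).
#' @param SBT stop-branching threshold (>= 0).
#' @param stream a [rand_stream()].
#' @param n number of independent decisions.
#' @return Logical vector: `TRUE` = branch.
#' @export
decide_branching <- function(MaxL, SBT, stream = NULL, n = 1) {
  stopifnot(MaxL > 0, SBT >= 0)
  u <- if (is.null(stream)) stats::runif(n, 0, MaxL)
  else stream_eval(stream, stats::runif(n, 0, MaxL))
  u < SBT
}

#' Grow one lateral root from a branch point
#'
#' Samples the radial angle `R ~ U[0, 180]` degrees, a fair-coin sign, the
#' growth threshold `LRGT ~ U[lrgt_range]` and the normalized lateral length
#' LLD. Points are laid down iteratively: point q sits at distance
#' `G_lat(t_q) * LLD` from the branch point along the fixed direction given
#' by the angles `(A +/- R, B +/- R)`, with `t_q = q * tf / n` the lateral's
#' age at iteration q. After each point a uniform draw is compared to LRGT:
#' growth continues while the draw falls below the threshold, and is capped
#' at `n` iterations.
#'
#' @param branch_point numeric length-3 anchor on the parent axis (cm).
#' @param A,B the parent axis's axial angles (degrees).
#' @param root_class parent root class (selects the LLD distribution).
#' @param profile a validated `rsa_profile`.
#' @param stream a [rand_stream()].
#' @param branch_index index of the branch point on the parent (metadata).
#' @return An object of class `lateral_root`: angles, sign, LRGT, LLD and a
#'   point matrix whose first row is the branch point.
#' @export
grow_lateral <- function(branch_point, A, B, root_class, profile,
                         stream = NULL, branch_index = NA_integer_) {
  p <- profile$params
  dt <- p$tf / p$n
  res <- stream_eval_or(stream, {
    R <- sample_radial_angle(NULL)
    sgn <- if (stats::runif(1) < 0.5) -1 else 1
    lrgt <- sample_lrgt(NULL, range = p$lrgt_range)
    lld <- sample_normalized_length(root_class, "lateral", profile$dists, NULL)
    q <- 1L
    while (q < p$n && stats::runif(1) < lrgt) q <- q + 1L
    list(R = R, sgn = sgn, lrgt = lrgt, lld = lld, q = q)
  })
  dists <- growth_Glat(seq_len(res$q) * dt, p$k_lat, p$rlat_coeff,
                       p$rlat_decay) * res$lld
  d <- axis_direction(A + res$sgn * res$R, B + res$sgn * res$R)
  pts <- rbind(branch_point,
               cbind(branch_point[1] + dists * d[1],
                     branch_point[2] + dists * d[2],
                     branch_point[3] + dists * d[3]))
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(list(branch_index = branch_index,
                 branch_point = branch_point,
                 R = res$R, sign = res$sgn,
                 LRGT = res$lrgt, LLD = res$lld,
                 points = pts),
            class = "lateral_root")
}

#' Attach lateral roots to a parent axis
#'
#' Computes the SL branching multiplier, builds the branching state
#' ([locate_branch_points()]), then visits each candidate point in order:
#' [decide_branching()] against `SBT = MedL * SL_effect`, and on a positive
#' decision grows a lateral ([grow_lateral()]). The realized lateral count
#' never exceeds the maximum `m`.
#'
#' @param parent_axis a `root_axis`.
#' @param profile a validated `rsa_profile`.
#' @param sl SL concentration in uM.
#' @param stream a [rand_stream()] owning all lateral draws of this axis.
#' @return The parent axis with its `laterals` list filled and a
#'   `branching` element recording `m`, `MedL` and `SBT`.
#' @export
attach_laterals <- function(parent_axis, profile, sl = 0, stream = NULL) {
  sl_branch_mult <- sl_effect(profile$sl_response, "branching_density", sl)
  bs <- locate_branch_points(parent_axis, profile, stream)
  laterals <- list()
  if (bs$m > 0) {
    SBT <- bs$MedL * sl_branch_mult
    branch <- decide_branching(bs$m, SBT, stream, n = bs$m)
    idx <- which(branch)
    laterals <- vector("list", length(idx))
    for (j in seq_along(idx)) {
      pnt <- bs$points[idx[j], ]
      laterals[[j]] <- grow_lateral(pnt, parent_axis$A, parent_axis$B,
                                    parent_axis$root_class, profile,
                                    stream, branch_index = idx[j])
    }
    parent_axis$branching <- list(m = bs$m, MedL = bs$MedL, SBT = SBT,
                                  density = bs$density)
  } else {
    parent_axis$branching <- list(m = 0L, MedL = bs$MedL, SBT = 0,
                                  density = bs$density)
  }
  parent_axis$laterals <- laterals
  parent_axis
}
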