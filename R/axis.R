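# Single main-axis construction: origin placement by whorl rules, direction
# from axial angles, and point propagation along per-iteration increments.

#' Direction vector from axial angles
#'
#' Unit vector `(cos A cos B, cos B sin A, -sin B)` for angles in degrees.
#' For B in \[0, 180\] the z component is non-positive, so strands never grow
#' upward.
#'
#' @param A axial angle in degrees (\[180, 360\] for sampled axes).
#' @param B axial angle in degrees (\[0, 180\]).
#' @return Numeric length-3 unit vector.
#' @export
axis_direction <- function(A, B) {
  a <- A * pi / 180
  b <- B * pi / 180
  c(cos(a) * cos(b), cos(b) * sin(a), -sin(b))
}

#' Place the origin of a main axis
#'
#' Level ground is the plane z = 0 (cm). The primary root starts exactly at
#' the origin; seminal roots start at a uniform depth in \[-wd, 0\]; brace
#' roots start on one of the above-ground whorls z in {wd, 2 wd}; crown roots
#' on one of the below-ground whorls z in {0, -wd, ..., -5 wd} (uniform whorl
#' choice). `wd` is the whorl distance of the plant, drawn once per root
#' system.
#'
#' @param root_class one of primary, seminal, crown, brace.
#' @param wd whorl distance in cm (> 0).
#' @param stream a [rand_stream()].
#' @param brace_levels,crown_levels number of whorl levels available.
#' @return Numeric length-3 point (x, y, z) in cm.
#' @export
place_origin <- function(root_class, wd, stream = NULL,
                         brace_levels = 2L, crown_levels = 6L) {
  if (wd <= 0) stop("wd must be > 0")
  draw <- function() {
    switch(root_class,
           primary = c(0, 0, 0),
           seminal = c(0, 0, -stats::runif(1, 0, wd)),
           brace   = c(0, 0, wd * sample.int(brace_levels, 1)),
           crown   = c(0, 0, -wd * (sample.int(crown_levels, 1) - 1L)),
           stop("unknown root class: ", root_class))
  }
  if (is.null(stream)) draw() else stream_eval(stream, draw())
}

#' Propagate a strand polyline from increments
#'
#' Starting at `origin`, each iteration advances by its arc-length increment
#' along the fixed direction given by the axial angles, yielding the points
#' P_0 ... P_n. With `jitter_sd > 0` the angles instead perform a small
#' random walk (sd in degrees per step, B clamped to \[0, 180\]) for visual
#' realism; default off.
#'
#' @param origin numeric length-3 start point (cm).
#' @param A,B axial angles in degrees.
#' @param increments positive per-iteration arc lengths (cm), from
#'   [segment_increments()].
#' @param jitter_sd per-step angular jitter sd in degrees (default 0).
#' @param stream a [rand_stream()] (only used when `jitter_sd > 0`).
#' @return Numeric (n+1) x 3 matrix of points, first row `origin`.
#' @export
extend_axis <- function(origin, A, B, increments, jitter_sd = 0,
                        stream = NULL) {
  n <- length(increments)
  if (n == 0) stop("increments must be non-empty")
  if (jitter_sd > 0) {
    jit <- function() list(a = stats::rnorm(n, 0, jitter_sd),
                           b = stats::rnorm(n, 0, jitter_sd))
    j <- if (is.null(stream)) jit() else stream_eval(stream, jit())
    Ai <- A + cumsum(j$a)
    Bi <- pmin(pmax(B + cumsum(j$b), 0), 180)
    ar <- Ai * pi / 180
    br <- Bi * pi / 180
    dx <- cos(ar) * cos(br)
    dy <- cos(br) * sin(ar)
    dz <- -sin(br)
    pts <- cbind(origin[1] + c(0, cumsum(increments * dx)),
                 origin[2] + c(0, cumsum(increments * dy)),
                 origin[3] + c(0, cumsum(increments * dz)))
  } else {
    d <- axis_direction(A, B)
    s <- c(0, cumsum(increments))
    pts <- cbind(origin[1] + s * d[1],
                 origin[2] + s * d[2],
                 origin[3] + s * d[3])
  }
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  pts
}

#' Build one main root axis
#'
#' Samples the axial angles A and B and the normalized length multiplier LD,
#' fixes the SL length multiplier for the class (taproot curve for
#' primary/seminal, nodal curve for crown/brace), places the origin by the
#' whorl rules, and propagates the polyline over the profile's time grid. No
#' laterals are attached at this stage (see [attach_laterals()]).
#'
#' @param root_class one of primary, seminal, crown, brace.
#' @param profile a validated `rsa_profile`.
#' @param sl SL concentration in uM (>= 0).
#' @param stream a [rand_stream()] owning all of this axis's draws.
#' @param wd whorl distance of the plant (cm).
#' @return An object of class `root_axis`: origin, angles, LD, SL multiplier,
#'   point matrix, empty lateral list.
#' @examples
#' prof <- default_maize_profile()
#' ax <- build_axis("primary", prof, sl = 0, stream = rand_stream(1, "ax"),
#'                  wd = 2)
#' axis_length(ax$points)
#' @export
build_axis <- function(root_class, profile, sl = 0, stream = NULL, wd = 2) {
  p <- profile$params
  draws <- stream_eval_or(stream, {
    ang <- sample_axial_angles(NULL)
    ld <- sample_trait(profile$dists[[root_class]]$axis_length_norm, 1, NULL)
    org <- place_origin(root_class, wd, NULL,
                        p$brace_whorl_levels, p$crown_whorl_levels)
    list(ang = ang, ld = ld, org = org)
  })
  sl_mult <- sl_effect(profile$sl_response, length_trait_class(root_class), sl)
  k <- k_for_class(p, root_class)
  inc <- segment_increments(p$n, p$tf, k, p$r, draws$ld, sl_mult)
  pts <- if (p$jitter_sd > 0) {
    stream_eval_or(stream,
      extend_axis(draws$org, draws$ang["A"], draws$ang["B"], inc,
                  jitter_sd = p$jitter_sd, stream = NULL))
  } else {
    extend_axis(draws$org, draws$ang["A"], draws$ang["B"], inc)
  }
  structure(list(root_class = root_class,
                 origin = draws$org,
                 A = unname(draws$ang["A"]), B = unname(draws$ang["B"]),
                 LD = draws$ld,
                 sl = sl,
                 sl_length_mult = sl_mult,
                 points = pts,
                 laterals = list()),
            class = "root_axis")
}

# evaluate under the stream if one is given, else directly
stream_eval_or <- function(stream, expr) {
  if (is.null(stream)) expr else stream_eval(stream, expr)
}

#' @export
print.root_axis <- function(x, ...) {
  cat(sprintf(
    "<root_axis> %s: length %.2f cm, %d points, %d laterals (A=%.1f, B=%.1f, LD=%.3f)\n",
    x$root_class, axis_length(x$points), nrow(x$points), length(x$laterals),
    x$A, x$B, x$LD))
  invisible(x)
}
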