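# Reproducible hierarchical random streams.
#
# Every stochastic unit of a simulation (one RSA, one axis, the laterals of
# one axis) draws from its own named stream, derived from (seed, path). Two
# simulators with the same seed produce bit-identical architectures, and
# adding an axis never perturbs draws of previously created ones, because
# streams are keyed by path rather than by global draw order.

#' Create a named random stream
#'
#' A stream is identified by an integer seed and a path of labels (e.g.
#' `c("rsa_17", "crown_axis_3")`). Identical (seed, path) pairs replay
#' identical draw sequences; distinct paths behave as statistically
#' independent generators. Streams hold their own RNG state, so interleaving
#' draws from several streams is safe.
#'
#' @param seed integer master seed.
#' @param path character vector of labels naming the unit.
#' @return An object of class `rand_stream`.
#' @examples
#' s <- rand_stream(42, "demo")
#' stream_eval(s, runif(2))
#' @export
rand_stream <- function(seed, path = character()) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$path <- as.character(path)
  env$state <- NULL
  class(env) <- "rand_stream"
  env
}

#' Derive a child stream
#'
#' @param stream parent `rand_stream`.
#' @param label character label appended to the parent path.
#' @return A new independent `rand_stream`.
#' @export
child_stream <- function(stream, label) {
  rand_stream(stream$seed, c(stream$path, as.character(label)))
}

# 31-ary polynomial hash of "seed/path" onto [1, 2^31 - 2]; deterministic
# across platforms and cheap enough to run once per axis.
stream_seed <- function(stream) {
  key <- paste(c(format(stream$seed), stream$path), collapse = "/")
  h <- 7
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483629
  as.integer(h + 1)
}

#' Evaluate an expression under a stream's RNG state
#'
#' Swaps the stream's private RNG state in, evaluates `expr`, then restores
#' the previous global state. Successive calls on the same stream continue
#' its sequence.
#'
#' @param stream a `rand_stream`.
#' @param expr expression performing random draws.
#' @return The value of `expr`.
#' @export
stream_eval <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(stream$state)) {
    set.seed(stream_seed(stream), kind = "Mersenne-Twister")
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' @export
print.rand_stream <- function(x, ...) {
  cat(sprintf("<rand_stream> seed=%d path=%s\n", x$seed,
              paste(x$path, collapse = "/")))
  invisible(x)
}

# --- trait sampling ----------------------------------------------------------

draw_raw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
         gamma    = stats::rgamma(n, shape = p$shape, scale = p$scale),
         normal   = stats::rnorm(n, mean = p$mean, sd = p$sd),
         binomial = stats::rbinom(n, size = p$trials, prob = p$prob),
         stop("unknown family: ", spec$family))
}

#' Draw from a trait distribution
#'
#' Draws `n` values from a [trait_dist()] under a stream. Truncation below
#' `spec$lower` is applied by rejection (the draw follows the conditional
#' distribution), then the rounding rule; `raw = TRUE` bypasses both and
#' returns the untransformed family draw.
#'
#' @param spec a [trait_dist()].
#' @param n number of draws.
#' @param stream a [rand_stream()]; `NULL` uses the current RNG.
#' @param raw skip truncation and rounding.
#' @return Numeric vector of length `n`.
#' @export
sample_trait <- function(spec, n = 1, stream = NULL, raw = FALSE) {
  draw <- function() {
    x <- draw_raw(spec, n)
    if (!raw) {
      for (guard in 1:100) {
        bad <- x < spec$lower
        if (!any(bad)) break
        x[bad] <- draw_raw(spec, sum(bad))
      }
      x[x < spec$lower] <- spec$lower   # pathological specs only
      if (spec$rounding == "integer") x <- round(x)
    }
    x
  }
  if (is.null(stream)) draw() else stream_eval(stream, draw())
}

#' Sample the number of axes of a root class
#'
#' Integer draw from the class's axis-count distribution, after truncation at
#' zero and rounding to the nearest integer. The primary class is rejected:
#' every root system carries exactly one primary axis by construction.
#'
#' @param root_class `"seminal"`, `"crown"` or `"brace"`.
#' @param dists the `dists` element of a profile.
#' @param stream a [rand_stream()].
#' @param n number of draws.
#' @param raw bypass truncation/rounding (for distribution diagnostics).
#' @return Integer-valued numeric vector.
#' @export
sample_axis_count <- function(root_class, dists, stream = NULL, n = 1,
                              raw = FALSE) {
  if (identical(root_class, "primary"))
    stop("primary axis count is fixed at 1; it is not sampled")
  spec <- dists[[root_class]]$axis_count
  if (is.null(spec)) stop("no axis_count spec for class ", root_class)
  sample_trait(spec, n, stream, raw = raw)
}

#' Sample a normalized length multiplier (LD or LLD)
#'
#' Per-strand dimensionless multiplier applied to the kinetic length scale:
#' `kind = "axis"` draws LD for a main axis, `kind = "lateral"` draws LLD for
#' a lateral root. Draws are truncated just above zero.
#'
#' @param root_class one of primary, seminal, crown, brace.
#' @param kind `"axis"` or `"lateral"`.
#' @inheritParams sample_axis_count
#' @return Positive numeric vector.
#' @export
sample_normalized_length <- function(root_class, kind = c("axis", "lateral"),
                                     dists, stream = NULL, n = 1) {
  kind <- match.arg(kind)
  trait <- if (kind == "axis") "axis_length_norm" else "lateral_length_norm"
  spec <- dists[[root_class]][[trait]]
  if (is.null(spec)) stop("no ", trait, " spec for class ", root_class)
  sample_trait(spec, n, stream)
}

#' Sample a lateral branching density (branches per cm)
#'
#' @inheritParams sample_axis_count
#' @return Positive numeric vector (per cm of parent axis).
#' @export
sample_lateral_density <- function(root_class, dists, stream = NULL, n = 1,
                                   raw = FALSE) {
  spec <- dists[[root_class]]$lateral_density_per_cm
  if (is.null(spec)) stop("no lateral_density_per_cm spec for class ", root_class)
  sample_trait(spec, n, stream, raw = raw)
}

#' Bootstrap median of a trait distribution
#'
#' Median of `n_samples` independent draws from `spec` (default 1000). Used
#' for the median branch-count scale MedL that enters the stop-branching
#' threshold.
#'
#' @param spec a [trait_dist()].
#' @param n_samples number of draws (>= 1).
#' @param stream a [rand_stream()].
#' @return A single number.
#' @export
bootstrap_median <- function(spec, n_samples = 1000, stream = NULL) {
  stopifnot(n_samples >= 1)
  stats::median(sample_trait(spec, n_samples, stream))
}

#' Sample axial angles for a main axis
#'
#' A uniform on \[180, 360\] degrees and B uniform on \[0, 180\] degrees;
#' together they set the fixed 3D direction of one root strand.
#'
#' @param stream a [rand_stream()].
#' @return Named numeric vector `c(A = , B = )` in degrees.
#' @export
sample_axial_angles <- function(stream = NULL) {
  u <- if (is.null(stream)) stats::runif(2) else stream_eval(stream, stats::runif(2))
  c(A = 180 + 180 * u[1], B = 180 * u[2])
}

#' Sample a lateral radial angle
#'
#' Uniform on \[0, 180\] degrees; added to or subtracted from the parent's
#' axial angles to orient a lateral root.
#'
#' @param stream a [rand_stream()].
#' @param n number of draws.
#' @return Numeric vector of degrees.
#' @export
sample_radial_angle <- function(stream = NULL, n = 1) {
  if (is.null(stream)) stats::runif(n, 0, 180)
  else stream_eval(stream, stats::runif(n, 0, 180))
}

#' Sample a lateral root growth threshold (LRGT)
#'
#' Uniform on `range` (default \[0.4, 0.9\]); the per-lateral probability of
#' continuing growth at each iteration.
#'
#' @param stream a [rand_stream()].
#' @param n number of draws.
#' @param range length-2 numeric, the LRGT bounds.
#' @return Numeric vector in `range`.
#' @export
sample_lrgt <- function(stream = NULL, n = 1, range = c(0.4, 0.9)) {
  if (is.null(stream)) stats::runif(n, range[1], range[2])
  else stream_eval(stream, stats::runif(n, range[1], range[2]))
}
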