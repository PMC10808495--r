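# Whole root-system assembly: one primary axis, sampled numbers of seminal,
# crown and brace axes with whorl-rule origins, laterals on every axis.

#' Build one complete root system architecture
#'
#' Draws the plant's whorl distance `wd`, builds exactly one primary axis,
#' samples the seminal/crown/brace axis counts from their distributions,
#' builds each axis with an independent named stream, and (by default)
#' attaches lateral roots to every axis. Identical `(seed, sl, profile)`
#' reproduce the architecture bit for bit.
#'
#' @param profile a validated `rsa_profile`.
#' @param sl SL concentration in uM (>= 0, constant for the run).
#' @param seed integer seed (ignored when `stream` is given).
#' @param stream optionally, a [rand_stream()] naming this plant.
#' @param laterals build lateral roots (`TRUE`, default). `FALSE` yields the
#'   axis skeleton only, which is much faster and sufficient for axis-level
#'   phenotyping (axis lengths and origins do not depend on laterals).
#' @return An object of class `rsa`: `axes` (list per class), `wd`, `sl`,
#'   `seed`, `path`.
#' @examples
#' prof <- default_maize_profile()
#' rsa <- build_rsa(prof, sl = 0, seed = 1, laterals = FALSE)
#' rsa
#' @export
build_rsa <- function(profile, sl = 0, seed = 1L, stream = NULL,
                      laterals = TRUE) {
  if (sl < 0) stop("SL concentration must be >= 0")
  if (is.null(stream)) stream <- rand_stream(seed, "rsa")
  p <- profile$params

  plant <- child_stream(stream, "plant")
  wd <- stream_eval(plant, sample_trait(p$whorl_spec, 1, NULL))
  counts <- c(primary = 1L,
              seminal = as.integer(stream_eval(plant,
                sample_axis_count("seminal", profile$dists, NULL))),
              crown = as.integer(stream_eval(plant,
                sample_axis_count("crown", profile$dists, NULL))),
              brace = as.integer(stream_eval(plant,
                sample_axis_count("brace", profile$dists, NULL))))

  axes <- lapply(ROOT_CLASSES, function(cls) {
    nax <- counts[[cls]]
    if (nax == 0) return(list())
    lapply(seq_len(nax), function(j) {
      ax_stream <- child_stream(stream, sprintf("%s_axis_%d", cls, j))
      ax <- build_axis(cls, profile, sl, ax_stream, wd)
      if (laterals) {
        lat_stream <- child_stream(stream, sprintf("%s_lat_%d", cls, j))
        ax <- attach_laterals(ax, profile, sl, lat_stream)
      }
      ax
    })
  })
  names(axes) <- ROOT_CLASSES

  structure(list(axes = axes, wd = wd, sl = sl,
                 seed = stream$seed, path = stream$path),
            class = "rsa")
}

#' @export
print.rsa <- function(x, ...) {
  n_ax <- vapply(x$axes, length, integer(1))
  n_lat <- sum(vapply(unlist(x$axes, recursive = FALSE),
                      function(a) length(a$laterals), integer(1)))
  cat(sprintf("<rsa> maize root system at SL = %g uM (seed %d, wd %.2f cm)\n",
              x$sl, x$seed, x$wd))
  cat(sprintf("  axes: %s; %d lateral roots\n",
              paste(sprintf("%s=%d", names(n_ax), n_ax), collapse = ", "),
              n_lat))
  invisible(x)
}

#' Build an ensemble of independent root systems
#'
#' `n_rsa` architectures from child streams `rsa_1 ... rsa_n` of the master
#' seed: reproducible and order-independent (RSA i is identical whether or
#' not the others are built).
#'
#' @inheritParams build_rsa
#' @param n_rsa ensemble size (>= 1).
#' @return A list of `rsa` objects of class `rsa_ensemble`.
#' @export
build_ensemble <- function(profile, sl = 0, n_rsa = 100, seed = 1L,
                           laterals = TRUE) {
  stopifnot(n_rsa >= 1)
  out <- lapply(seq_len(n_rsa), function(i) {
    build_rsa(profile, sl, stream = rand_stream(seed, sprintf("rsa_%d", i)),
              laterals = laterals)
  })
  class(out) <- "rsa_ensemble"
  out
}

#' Flatten the axes of one root class
#'
#' @param rsa an `rsa`.
#' @param root_class class name, or `NULL` for all axes.
#' @return List of `root_axis` objects.
#' @export
rsa_axes <- function(rsa, root_class = NULL) {
  if (is.null(root_class)) unlist(rsa$axes, recursive = FALSE)
  else rsa$axes[[root_class]]
}
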