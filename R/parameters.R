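ROOT_CLASSES <- c("primary", "seminal", "crown", "brace")
AXIS_TRAITS  <- c("axis_length_norm", "lateral_length_norm", "axis_count",
                  "lateral_density_per_cm")

#' Trait distribution specification
#'
#' A small container describing one univariate trait distribution: the family
#' (gamma, normal or binomial), its parameters, a lower truncation bound and
#' an optional rounding rule. These are the building blocks of the maize trait
#' registry (see [default_maize_profile()]).
#'
#' Truncation is applied by rejection, so draws follow the distribution
#' conditioned on exceeding `lower`. Rounding (for count traits) is applied
#' after truncation.
#'
#' @param family `"gamma"`, `"normal"` or `"binomial"`.
#' @param ... family parameters: `shape`/`scale` (gamma), `mean`/`sd` (normal)
#'   or `trials`/`prob` (binomial).
#' @param lower lower truncation bound (default 0; lengths use a small
#'   epsilon to exclude non-positive normal draws).
#' @param rounding `"none"` or `"integer"` (nearest integer, for counts).
#' @return An object of class `trait_dist`.
#' @examples
#' trait_dist("gamma", shape = 5, scale = 0.22)
#' trait_dist("normal", mean = 18.83, sd = 9.12, rounding = "integer")
#' @export
trait_dist <- function(family = c("gamma", "normal", "binomial"), ...,
                       lower = 0, rounding = c("none", "integer")) {
  family <- match.arg(family)
  rounding <- match.arg(rounding)
  params <- list(...)
  out <- structure(list(family = family, params = params,
                        lower = lower, rounding = rounding),
                   class = "trait_dist")
  out
}

#' @export
print.trait_dist <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<trait_dist> %s(%s), lower=%g, rounding=%s\n",
              x$family, p, x$lower, x$rounding))
  invisible(x)
}

#' Closed-form mean of a trait distribution
#'
#' Mean of the *raw* (untruncated, unrounded) distribution; used as the
#' reference value in parameter-recovery checks.
#'
#' @param spec a [trait_dist()].
#' @return A single number.
#' @export
trait_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
         gamma    = p$shape * p$scale,
         normal   = p$mean,
         binomial = p$trials * p$prob)
}

LEN_EPS <- 1e-6

#' Default maize parameter profile
#'
#' Returns the full simulation profile for maize: kinetic and structural
#' parameters, the trait-distribution registry for the four main root classes
#' (primary, seminal, crown, brace), and the strigolactone dose-response
#' anchor curves. All values ship with the package; nothing is fitted at run
#' time.
#'
#' The profile has three parts:
#' \describe{
#'   \item{params}{iteration count `n`, final time `tf` (days), maximal axis
#'     lengths `k_*` (cm), initial axis growth rate `r` (cm/day), lateral
#'     kinetics coefficients (`rlat_coeff`, `rlat_decay`), the lateral growth
#'     threshold range `lrgt_range`, bootstrap size for the median branch
#'     count, the whorl-distance distribution and whorl level counts.}
#'   \item{dists}{per root class: normalized axis length, normalized lateral
#'     length, axis count (absent for primary, which is always a single
#'     axis), and lateral branching density per cm.}
#'   \item{sl_response}{three piecewise-linear dose-response curves
#'     (taproot length, nodal length, branching density), each anchored at
#'     (0 uM, 1) for wild type; see [sl_effect()].}
#' }
#'
#' @return A list of class `rsa_profile` with elements `params`, `dists`,
#'   `sl_response`.
#' @examples
#' prof <- default_maize_profile()
#' prof$params$k_prim       # 22.67 cm
#' prof$dists$seminal$axis_count
#' @export
default_maize_profile <- function() {
  params <- list(
    n = 200L,
    tf = 35,
    k_prim = 22.67, k_sem = 22.67, k_cro = 22.67, k_bra = 22.67,
    k_lat = 2.0,
    r = 2,
    rlat_coeff = 6.4, rlat_decay = 0.8,
    lrgt_range = c(0.4, 0.9),
    medl_bootstrap_n = 1000L,
    whorl_spec = trait_dist("normal", mean = 2.0, sd = 0.3, lower = 0.1),
    brace_whorl_levels = 2L,
    crown_whorl_levels = 6L,
    jitter_sd = 0
  )

  dists <- list(
    primary = list(
      axis_length_norm       = trait_dist("gamma",  shape = 5, scale = 0.22, lower = LEN_EPS),
      lateral_length_norm    = trait_dist("normal", mean = 0.97, sd = 0.34, lower = LEN_EPS),
      lateral_density_per_cm = trait_dist("normal", mean = 6.65, sd = 0.63, lower = LEN_EPS)
    ),
    seminal = list(
      axis_length_norm       = trait_dist("gamma",  shape = 5, scale = 0.22, lower = LEN_EPS),
      lateral_length_norm    = trait_dist("normal", mean = 1.00, sd = 0.30, lower = LEN_EPS),
      axis_count             = trait_dist("binomial", trials = 19, prob = 0.16,
                                          rounding = "integer"),
      lateral_density_per_cm = trait_dist("normal", mean = 5.05, sd = 0.66, lower = LEN_EPS)
    ),
    crown = list(
      axis_length_norm       = trait_dist("normal", mean = 0.98, sd = 0.11, lower = LEN_EPS),
      lateral_length_norm    = trait_dist("normal", mean = 0.95, sd = 0.17, lower = LEN_EPS),
      axis_count             = trait_dist("gamma",  shape = 91.89, scale = 0.41,
                                          rounding = "integer"),
      lateral_density_per_cm = trait_dist("normal", mean = 7.05, sd = 1.99, lower = LEN_EPS)
    ),
    brace = list(
      axis_length_norm       = trait_dist("normal", mean = 1.00, sd = 0.38, lower = LEN_EPS),
      lateral_length_norm    = trait_dist("normal", mean = 0.95, sd = 0.17, lower = LEN_EPS),
      axis_count             = trait_dist("normal", mean = 18.83, sd = 9.12,
                                          rounding = "integer"),
      lateral_density_per_cm = trait_dist("normal", mean = 7.05, sd = 1.99, lower = LEN_EPS)
    )
  )
  class(dists) <- "rsa_distributions"

  anchors <- list(
    taproot_length = list(
      sl = c(0, 1.25, 2.5, 5, 10),
      multiplier = c(1, 1.25, 1.2, 1, 0.63)
    ),
    nodal_length = list(
      sl = c(0, 0.01, 0.1, 1, 10),
      multiplier = c(1, 1.01, 0.99, 1.10, 1.19)
    ),
    branching_density = list(
      sl = c(0, 1.25, 2.5, 5, 10),
      multiplier = c(1, 1.08, 1.08, 0.73, 0.83)
    )
  )

  structure(list(params = params,
                 dists = dists,
                 sl_response = build_response_curves(anchors)),
            class = "rsa_profile")
}

#' @export
print.rsa_profile <- function(x, ...) {
  p <- x$params
  cat("<rsa_profile> maize root architecture simulation profile\n")
  cat(sprintf("  n = %d iterations, tf = %g days\n", p$n, p$tf))
  cat(sprintf("  k (prim/sem/cro/bra) = %g/%g/%g/%g cm, k_lat = %g cm, r = %g cm/day\n",
              p$k_prim, p$k_sem, p$k_cro, p$k_bra, p$k_lat, p$r))
  cat(sprintf("  lateral rate %g*exp(-%g t) cm/day; LRGT in [%g, %g]\n",
              p$rlat_coeff, p$rlat_decay, p$lrgt_range[1], p$lrgt_range[2]))
  cat(sprintf("  trait registry: %d classes; SL curves: %s\n",
              length(x$dists), paste(names(x$sl_response$curves), collapse = ", ")))
  invisible(x)
}

# --- validation --------------------------------------------------------------

check_dist_spec <- function(spec, where) {
  msgs <- character()
  bad <- function(field, value, rule)
    sprintf("%s$%s = %s violates: %s", where, field, deparse(value), rule)
  if (!inherits(spec, "trait_dist"))
    return(sprintf("%s: not a trait_dist", where))
  p <- spec$params
  if (spec$family == "gamma") {
    if (is.null(p$shape) || p$shape <= 0) msgs <- c(msgs, bad("shape", p$shape, "shape > 0"))
    if (is.null(p$scale) || p$scale <= 0) msgs <- c(msgs, bad("scale", p$scale, "scale > 0"))
  } else if (spec$family == "normal") {
    if (is.null(p$sd) || p$sd <= 0) msgs <- c(msgs, bad("sd", p$sd, "sd > 0"))
    if (is.null(p$mean)) msgs <- c(msgs, bad("mean", p$mean, "mean required"))
  } else if (spec$family == "binomial") {
    if (is.null(p$trials) || p$trials < 0) msgs <- c(msgs, bad("trials", p$trials, "trials >= 0"))
    if (is.null(p$prob) || p$prob < 0 || p$prob > 1)
      msgs <- c(msgs, bad("prob", p$prob, "0 <= prob <= 1"))
  }
  msgs
}

#' List invariant violations of a profile
#'
#' Checks every structural and numeric invariant of a simulation profile and
#' returns a character vector naming each violated rule (empty when the
#' profile is valid). [validate_profile()] wraps this into an error.
#'
#' @param profile an `rsa_profile`.
#' @return Character vector of violation messages.
#' @export
profile_issues <- function(profile) {
  msgs <- character()
  p <- profile$params
  chk <- function(ok, field, value, rule) {
    if (!isTRUE(ok)) msgs <<- c(msgs, sprintf("params$%s = %s violates: %s",
                                              field, deparse(value), rule))
  }
  chk(is.numeric(p$n) && p$n >= 1, "n", p$n, "n >= 1")
  chk(is.numeric(p$tf) && p$tf > 0, "tf", p$tf, "tf > 0")
  for (kk in c("k_prim", "k_sem", "k_cro", "k_bra", "k_lat"))
    chk(is.numeric(p[[kk]]) && p[[kk]] > 0, kk, p[[kk]], "k > 0")
  chk(is.numeric(p$r) && p$r > 0, "r", p$r, "r > 0")
  chk(p$rlat_coeff > 0, "rlat_coeff", p$rlat_coeff, "rlat_coeff > 0")
  chk(p$rlat_decay > 0, "rlat_decay", p$rlat_decay, "rlat_decay > 0")
  lr <- p$lrgt_range
  chk(length(lr) == 2 && lr[1] >= 0 && lr[1] < lr[2] && lr[2] <= 1,
      "lrgt_range", lr, "0 <= min < max <= 1")
  chk(p$medl_bootstrap_n >= 1, "medl_bootstrap_n", p$medl_bootstrap_n, "n >= 1")
  chk(p$brace_whorl_levels >= 1, "brace_whorl_levels", p$brace_whorl_levels, ">= 1")
  chk(p$crown_whorl_levels >= 1, "crown_whorl_levels", p$crown_whorl_levels, ">= 1")
  msgs <- c(msgs, check_dist_spec(p$whorl_spec, "params$whorl_spec"))

  # trait registry: every non-primary class has all four traits; primary has
  # no axis_count (there is always exactly one primary axis)
  for (cls in ROOT_CLASSES) {
    entry <- profile$dists[[cls]]
    if (is.null(entry)) { msgs <- c(msgs, sprintf("dists$%s missing", cls)); next }
    need <- if (cls == "primary") setdiff(AXIS_TRAITS, "axis_count") else AXIS_TRAITS
    for (tr in need) {
      if (is.null(entry[[tr]]))
        msgs <- c(msgs, sprintf("dists$%s$%s missing", cls, tr))
      else
        msgs <- c(msgs, check_dist_spec(entry[[tr]], sprintf("dists$%s$%s", cls, tr)))
    }
    if (cls == "primary" && !is.null(entry$axis_count))
      msgs <- c(msgs, "dists$primary$axis_count present: primary count is fixed at 1")
  }

  msgs <- c(msgs, response_issues(profile$sl_response))
  msgs
}

#' Validate a simulation profile
#'
#' Returns the profile unchanged when every invariant holds, otherwise stops
#' with an error listing every violated rule (field, value, rule).
#'
#' @param profile an `rsa_profile` (e.g. from [default_maize_profile()] or
#'   [read_profile()]).
#' @return The validated profile, invisibly.
#' @export
validate_profile <- function(profile) {
  msgs <- profile_issues(profile)
  if (length(msgs))
    stop("invalid profile:\n  ", paste(msgs, collapse = "\n  "), call. = FALSE)
  invisible(profile)
}

k_for_class <- function(params, root_class) {
  switch(root_class,
         primary = params$k_prim, seminal = params$k_sem,
         crown = params$k_cro, brace = params$k_bra,
         stop("unknown root class: ", root_class))
}
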