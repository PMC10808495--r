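# Strigolactone dose-response multipliers.
#
# Literature effects of the SL analog GR24 on root traits are normalized to
# wild type (multiplier 1 at 0 uM) and tabulated as anchor points per trait
# class. Between anchors the trait multiplier RT(SL) follows the local linear
# form RT_initial + (dRT/dSL) * (SL - SL_initial), i.e. piecewise-linear
# interpolation whose segment slope is the experimentally determined dRT/dSL.

TRAIT_CLASSES <- c("taproot_length", "nodal_length", "branching_density")

#' Build validated SL dose-response curves
#'
#' Assembles an `sl_response` object from anchor tables, one per trait class:
#' `taproot_length` (primary and seminal axes), `nodal_length` (crown and
#' brace axes) and `branching_density` (lateral branches per cm, shared by
#' all classes). Each anchor list must contain the wild-type anchor
#' (SL = 0, multiplier = 1) and strictly increasing SL values; missing cells
#' of the source table are simply absent anchors.
#'
#' @param anchors named list; each element a list with numeric `sl` (uM) and
#'   `multiplier` vectors of equal length.
#' @param sl_initial reference SL concentration (uM), default 0.
#' @param rt_initial wild-type normalized trait value, default 1.
#' @return An object of class `sl_response`.
#' @examples
#' resp <- default_maize_profile()$sl_response
#' resp$curves$taproot_length
#' @export
build_response_curves <- function(anchors, sl_initial = 0, rt_initial = 1) {
  curves <- lapply(anchors, function(a) {
    o <- order(a$sl)
    data.frame(sl = a$sl[o], multiplier = a$multiplier[o])
  })
  out <- structure(list(curves = curves,
                        sl_initial = sl_initial, rt_initial = rt_initial),
                   class = "sl_response")
  msgs <- response_issues(out)
  if (length(msgs))
    stop("invalid SL response table:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  out
}

response_issues <- function(resp) {
  msgs <- character()
  if (!inherits(resp, "sl_response") || is.null(resp$curves))
    return("sl_response: not an sl_response object")
  for (nm in names(resp$curves)) {
    cv <- resp$curves[[nm]]
    if (any(duplicated(cv$sl)))
      msgs <- c(msgs, sprintf("sl_response$%s: duplicate SL anchors", nm))
    if (any(diff(cv$sl) <= 0))
      msgs <- c(msgs, sprintf("sl_response$%s: SL values not strictly increasing", nm))
    if (!any(cv$sl == 0 & cv$multiplier == 1))
      msgs <- c(msgs, sprintf("sl_response$%s: missing wild-type anchor (0, 1)", nm))
    if (any(cv$multiplier <= 0))
      msgs <- c(msgs, sprintf("sl_response$%s: non-positive multiplier", nm))
  }
  msgs
}

#' @export
print.sl_response <- function(x, ...) {
  cat("<sl_response> piecewise-linear dose-response curves (multiplier vs uM)\n")
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                paste(sprintf("(%g, %g)", cv$sl, cv$multiplier), collapse = " ")))
  }
  invisible(x)
}

#' Strigolactone effect multiplier for a trait
#'
#' Evaluates the dimensionless trait multiplier at an SL concentration. At an
#' anchor the tabulated value is returned exactly; between consecutive
#' anchors the multiplier is linearly interpolated (the local slope is the
#' experimental dRT/dSL); outside the anchored range the nearest anchor's
#' value is held constant, so high doses can never drive a length negative.
#'
#' @param resp an `sl_response` object (e.g. `profile$sl_response`).
#' @param trait_class `"taproot_length"`, `"nodal_length"` or
#'   `"branching_density"`.
#' @param sl SL concentration in uM (vectorised, must be >= 0).
#' @return Positive multiplier(s), 1 at SL = 0.
#' @examples
#' resp <- default_maize_profile()$sl_response
#' sl_effect(resp, "taproot_length", c(0, 1.25, 10))
#' @export
sl_effect <- function(resp, trait_class, sl) {
  if (!trait_class %in% names(resp$curves))
    stop("unknown trait class: ", trait_class)
  if (any(sl < 0)) stop("SL concentration must be >= 0")
  cv <- resp$curves[[trait_class]]
  if (nrow(cv) == 1) return(rep(cv$multiplier, length(sl)))
  stats::approx(cv$sl, cv$multiplier, xout = sl, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' Length trait class of a root class
#'
#' Primary and seminal axes respond through the taproot-length curve, crown
#' and brace axes through the nodal-length curve. Branching density uses one
#' shared curve for all classes.
#'
#' @param root_class one of primary, seminal, crown, brace.
#' @return The trait-class name for axis length.
#' @export
length_trait_class <- function(root_class) {
  switch(root_class,
         primary = , seminal = "taproot_length",
         crown = , brace = "nodal_length",
         stop("unknown root class: ", root_class))
}
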