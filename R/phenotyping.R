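# Trait extraction and ensemble statistics: per-RSA trait summaries, medians
# with percentile-bootstrap confidence intervals across an ensemble,
# wild-type normalisation, and SL dose sweeps.

#' Arc length of a polyline
#'
#' Sum of consecutive-point Euclidean distances; fewer than two points yield
#' zero. For a generated axis this equals `EF(tf)` up to floating error.
#'
#' @param points numeric matrix with 3 columns (x, y, z in cm).
#' @return Length in cm.
#' @examples
#' axis_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
axis_length <- function(points) {
  if (is.null(points) || nrow(points) < 2) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Realized lateral density of an axis
#'
#' Number of realized lateral roots per cm of the parent axis.
#'
#' @param axis a `root_axis` (after [attach_laterals()]).
#' @return Branches per cm.
#' @export
lateral_density <- function(axis) {
  L <- axis_length(axis$points)
  if (L <= 0) stop("zero-length axis has no defined lateral density")
  length(axis$laterals) / L
}

#' Per-class trait summary of one root system
#'
#' For each root class present: number of axes, the median axis length, the
#' total lateral count, and the median per-axis lateral density. Within one
#' RSA traits are aggregated by the median across that plant's axes of the
#' class.
#'
#' @param rsa an `rsa`.
#' @return A data.frame with one row per root class.
#' @export
rsa_summary <- function(rsa) {
  rows <- lapply(ROOT_CLASSES, function(cls) {
    axes <- rsa$axes[[cls]]
    if (length(axes) == 0)
      return(data.frame(root_class = cls, n_axes = 0L,
                        median_axis_length = NA_real_,
                        lateral_count = 0L,
                        median_lateral_density = NA_real_))
    lens <- vapply(axes, function(a) axis_length(a$points), numeric(1))
    nlat <- vapply(axes, function(a) length(a$laterals), integer(1))
    dens <- nlat / lens
    data.frame(root_class = cls, n_axes = length(axes),
               median_axis_length = stats::median(lens),
               lateral_count = sum(nlat),
               median_lateral_density = stats::median(dens))
  })
  do.call(rbind, rows)
}

#' Ensemble medians with bootstrap confidence intervals
#'
#' For each root class and trait (axis length in cm, lateral density per cm):
#' the per-RSA value is the median across that plant's axes of the class; the
#' ensemble statistic is the median of those per-RSA values, with a
#' percentile-bootstrap confidence interval of the median (default 99%,
#' 2000 resamples, deterministic internal seed).
#'
#' @param ensemble a list of `rsa` objects (e.g. [build_ensemble()]).
#' @param conf confidence level (default 0.99).
#' @param n_boot bootstrap resamples (default 2000).
#' @param boot_seed seed for the bootstrap resampling stream.
#' @return A data.frame of class `ensemble_stats`: one row per root class and
#'   trait with `median`, `ci_low`, `ci_high`, `n_rsa`.
#' @export
ensemble_statistics <- function(ensemble, conf = 0.99, n_boot = 2000,
                                boot_seed = 20260101L) {
  if (length(ensemble) == 0) stop("empty ensemble")
  summaries <- lapply(ensemble, rsa_summary)
  boot_stream <- rand_stream(boot_seed, "bootstrap")
  traits <- c(axis_length = "median_axis_length",
              lateral_density = "median_lateral_density")
  alpha <- (1 - conf) / 2
  rows <- list()
  for (cls in ROOT_CLASSES) {
    for (tr in names(traits)) {
      vals <- vapply(summaries, function(s) s[[traits[[tr]]]][s$root_class == cls],
                     numeric(1))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) next
      med <- stats::median(vals)
      if (length(unique(vals)) == 1) {
        ci <- c(med, med)
      } else {
        boots <- stream_eval(boot_stream, {
          vapply(seq_len(n_boot), function(b)
            stats::median(vals[sample.int(length(vals), replace = TRUE)]),
            numeric(1))
        })
        ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(root_class = cls, trait = tr, median = med,
                   ci_low = ci[1], ci_high = ci[2], n_rsa = length(vals))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ensemble_stats", class(out))
  out
}

#' Normalize ensemble statistics to a wild-type reference
#'
#' Element-wise ratio of medians (and interval bounds) to the wild-type
#' median of the same class and trait; the wild type itself normalizes to 1.
#'
#' @param stats,wt_stats `ensemble_stats` data.frames
#'   ([ensemble_statistics()]); `wt_stats` is the SL = 0 reference.
#' @return `stats` with unit-free columns `normalized`, `normalized_low`,
#'   `normalized_high` appended.
#' @export
normalize_to_wildtype <- function(stats, wt_stats) {
  key <- paste(wt_stats$root_class, wt_stats$trait)
  ref <- stats::setNames(wt_stats$median, key)
  denom <- ref[paste(stats$root_class, stats$trait)]
  if (any(is.na(denom) | denom == 0))
    stop("wild-type reference missing or zero for some class/trait")
  stats$normalized <- stats$median / denom
  stats$normalized_low <- stats$ci_low / denom
  stats$normalized_high <- stats$ci_high / denom
  stats
}

#' SL dose-response sweep over ensembles
#'
#' Builds a wild-type reference ensemble at SL = 0 and one ensemble per grid
#' concentration (default 0.25 to 10 uM in steps of 0.25, i.e. 40 levels),
#' computes ensemble statistics for each, and normalizes to the wild type.
#' Ensembles at different concentrations reuse the same stream layout, so
#' differences across SL levels reflect the dose response rather than
#' resampling noise.
#'
#' @param profile a validated `rsa_profile`.
#' @param sl_grid SL concentrations in uM (default `seq(0.25, 10, 0.25)`).
#' @param n_rsa ensemble size per concentration (default 100).
#' @param seed master seed.
#' @param laterals build laterals (needed for branching traits); `FALSE`
#'   restricts the sweep to axis-length traits.
#' @param conf,n_boot forwarded to [ensemble_statistics()].
#' @return A tidy data.frame: one row per SL level (including the SL = 0
#'   reference) x root class x trait, with median, CI bounds and normalized
#'   values.
#' @export
dose_response_sweep <- function(profile, sl_grid = seq(0.25, 10, by = 0.25),
                                n_rsa = 100, seed = 1L, laterals = TRUE,
                                conf = 0.99, n_boot = 2000) {
  if (length(sl_grid) == 0) stop("sl_grid must be non-empty")
  levels <- unique(c(0, sl_grid))
  stats_by_sl <- lapply(levels, function(sl) {
    ens <- build_ensemble(profile, sl, n_rsa, seed, laterals = laterals)
    st <- ensemble_statistics(ens, conf = conf, n_boot = n_boot)
    if (!laterals) st <- st[st$trait == "axis_length", ]  # no branching traits
    st
  })
  wt <- stats_by_sl[[1]]
  rows <- lapply(seq_along(levels), function(i) {
    st <- normalize_to_wildtype(stats_by_sl[[i]], wt)
    st$sl <- levels[i]
    st
  })
  out <- do.call(rbind, rows)
  out <- out[, c("sl", setdiff(names(out), "sl"))]
  rownames(out) <- NULL
  attr(out, "sl_grid") <- sl_grid
  out
}
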