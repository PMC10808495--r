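# Persistence: RSML (the community XML standard for root architecture
# exchange), flat point/summary CSVs, and YAML profile files. Coordinates are
# cm in a right-handed frame with z up and the ground plane at z = 0; angles
# are stored in degrees.

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write a root system to RSML
#'
#' Emits a standards-conformant RSML document: scene metadata (software,
#' seed, SL concentration, units), one plant, main axes as top-level `root`
#' elements and laterals as their child `root` elements, geometry as
#' polylines of `point` elements.
#'
#' @param rsa an `rsa`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(rsa, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rsml xmlns:po="http://www.plantontology.org/xml-dtd/po.dtd">',
    '  <metadata>',
    '    <version>1</version>',
    '    <unit>cm</unit>',
    '    <resolution>1</resolution>',
    sprintf('    <software>maizersa %s</software>',
            esc(as.character(utils::packageVersion("maizersa")))),
    '    <property-definitions>',
    '      <property-definition><label>seed</label><type>integer</type></property-definition>',
    '      <property-definition><label>sl_concentration_uM</label><type>number</type></property-definition>',
    '      <property-definition><label>whorl_distance_cm</label><type>number</type></property-definition>',
    '    </property-definitions>',
    '  </metadata>',
    '  <scene>',
    sprintf('    <plant id="1" label="Zea mays">'),
    '      <properties>',
    sprintf('        <property name="seed" value="%d"/>', rsa$seed),
    sprintf('        <property name="sl_concentration_uM" value="%s"/>', fmt_num(rsa$sl)),
    sprintf('        <property name="whorl_distance_cm" value="%s"/>', fmt_num(rsa$wd))
  )
  lines <- c(lines, '      </properties>')

  poly_lines <- function(pts, pad) {
    c(paste0(pad, "<geometry><polyline>"),
      sprintf('%s  <point x="%s" y="%s" z="%s"/>', pad,
              fmt_num(pts[, 1]), fmt_num(pts[, 2]), fmt_num(pts[, 3])),
      paste0(pad, "</polyline></geometry>"))
  }

  for (cls in names(rsa$axes)) {
    axes <- rsa$axes[[cls]]
    for (j in seq_along(axes)) {
      ax <- axes[[j]]
      id <- sprintf("%s_%d", cls, j)
      lines <- c(lines,
                 sprintf('      <root ID="%s" label="%s">', id, cls))
      lines <- c(lines, poly_lines(ax$points, "        "))
      for (l in seq_along(ax$laterals)) {
        lat <- ax$laterals[[l]]
        lines <- c(lines,
                   sprintf('        <root ID="%s_lat_%d" label="lateral">', id, l),
                   poly_lines(lat$points, "          "),
                   '        </root>')
      }
      lines <- c(lines, '      </root>')
    }
  }
  lines <- c(lines, '    </plant>', '  </scene>', '</rsml>')
  # parse once so malformed output can never be written silently
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read root geometry from an RSML file
#'
#' Reconstructs the axes (class label, point matrix) and their lateral
#' children from an RSML document written by [write_rsml()] (or any RSML
#' with polyline geometry one level of branching deep).
#'
#' @param path RSML file path.
#' @return A list with `metadata` (seed, sl, wd where present) and `axes`: a
#'   list of `list(root_class, id, points, laterals)`.
#' @export
read_rsml <- function(path) {
  doc <- xml2::read_xml(path)
  ns_free <- xml2::xml_ns_strip(doc)
  get_pts <- function(node) {
    pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
    m <- cbind(x = as.numeric(xml2::xml_attr(pts, "x")),
               y = as.numeric(xml2::xml_attr(pts, "y")),
               z = as.numeric(xml2::xml_attr(pts, "z")))
    m
  }
  prop <- function(name) {
    nd <- xml2::xml_find_first(
      doc, sprintf(".//plant/properties/property[@name='%s']", name))
    if (inherits(nd, "xml_missing")) NA_real_
    else as.numeric(xml2::xml_attr(nd, "value"))
  }
  top <- xml2::xml_find_all(doc, ".//plant/root")
  axes <- lapply(top, function(node) {
    kids <- xml2::xml_find_all(node, "./root")
    list(root_class = xml2::xml_attr(node, "label"),
         id = xml2::xml_attr(node, "ID"),
         points = get_pts(node),
         laterals = lapply(kids, function(kid)
           list(id = xml2::xml_attr(kid, "ID"), points = get_pts(kid))))
  })
  list(metadata = list(seed = prop("seed"),
                       sl = prop("sl_concentration_uM"),
                       wd = prop("whorl_distance_cm")),
       axes = axes)
}

#' Write all points of a root system to CSV
#'
#' One row per polyline point: `plant_id, root_class, axis_id, lateral_id`
#' (blank for axis points), `point_index` (0-based), `x, y, z` in cm.
#' Deterministic row and column order; identical seeds give byte-identical
#' files.
#'
#' @param rsa an `rsa`.
#' @param path output file path.
#' @param plant_id identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(rsa, path, plant_id = 1L) {
  blocks <- list()
  for (cls in names(rsa$axes)) {
    axes <- rsa$axes[[cls]]
    for (j in seq_along(axes)) {
      ax <- axes[[j]]
      axis_id <- sprintf("%s_%d", cls, j)
      blocks[[length(blocks) + 1L]] <- data.frame(
        plant_id = plant_id, root_class = cls, axis_id = axis_id,
        lateral_id = "", point_index = seq_len(nrow(ax$points)) - 1L,
        x = ax$points[, 1], y = ax$points[, 2], z = ax$points[, 3])
      for (l in seq_along(ax$laterals)) {
        lp <- ax$laterals[[l]]$points
        blocks[[length(blocks) + 1L]] <- data.frame(
          plant_id = plant_id, root_class = cls, axis_id = axis_id,
          lateral_id = sprintf("%s_lat_%d", axis_id, l),
          point_index = seq_len(nrow(lp)) - 1L,
          x = lp[, 1], y = lp[, 2], z = lp[, 3])
      }
    }
  }
  df <- if (length(blocks)) do.call(rbind, blocks)
  else data.frame(plant_id = integer(0), root_class = character(0),
                  axis_id = character(0), lateral_id = character(0),
                  point_index = integer(0), x = numeric(0), y = numeric(0),
                  z = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write an ensemble summary table to CSV
#'
#' @param stats a data.frame (e.g. from [ensemble_statistics()] or
#'   [dose_response_sweep()]); an empty data.frame yields a header-only file.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

# --- profile config files ----------------------------------------------------

spec_to_list <- function(spec) {
  list(family = spec$family, params = spec$params,
       lower = spec$lower, rounding = spec$rounding)
}

list_to_spec <- function(x) {
  do.call(trait_dist, c(list(family = x$family), x$params,
                        list(lower = x$lower, rounding = x$rounding)))
}

#' Write a simulation profile to a YAML config file
#'
#' Mirrors every field of the parameter set, trait registry and SL response
#' table, so a profile round-trips through write/[read_profile()] unchanged.
#'
#' @param profile an `rsa_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  p <- profile$params
  cfg <- list(
    params = c(p[setdiff(names(p), c("whorl_spec", "lrgt_range"))],
               list(lrgt_range = as.list(p$lrgt_range),
                    whorl_spec = spec_to_list(p$whorl_spec))),
    dists = lapply(profile$dists, function(entry) lapply(entry, spec_to_list)),
    sl_response = list(
      sl_initial = profile$sl_response$sl_initial,
      rt_initial = profile$sl_response$rt_initial,
      curves = lapply(profile$sl_response$curves, function(cv)
        list(sl = cv$sl, multiplier = cv$multiplier)))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a simulation profile from a YAML config file
#'
#' Fields present in the file override the default maize profile field by
#' field; anything omitted keeps its default. The merged profile is
#' validated before being returned.
#'
#' @param path YAML file path.
#' @param base profile supplying defaults (default
#'   [default_maize_profile()]).
#' @return A validated `rsa_profile`.
#' @export
read_profile <- function(path, base = default_maize_profile()) {
  cfg <- yaml::read_yaml(path)
  profile <- base
  if (!is.null(cfg$params)) {
    for (nm in names(cfg$params)) {
      val <- cfg$params[[nm]]
      if (nm == "whorl_spec") val <- list_to_spec(val)
      if (nm == "lrgt_range") val <- as.numeric(unlist(val))
      if (nm %in% c("n", "medl_bootstrap_n", "brace_whorl_levels",
                    "crown_whorl_levels")) val <- as.integer(val)
      profile$params[[nm]] <- val
    }
  }
  if (!is.null(cfg$dists)) {
    for (cls in names(cfg$dists))
      for (tr in names(cfg$dists[[cls]]))
        profile$dists[[cls]][[tr]] <- list_to_spec(cfg$dists[[cls]][[tr]])
  }
  if (!is.null(cfg$sl_response)) {
    sr <- cfg$sl_response
    anchors <- lapply(sr$curves, function(cv)
      list(sl = as.numeric(unlist(cv$sl)),
           multiplier = as.numeric(unlist(cv$multiplier))))
    profile$sl_response <- build_response_curves(
      anchors,
      sl_initial = sr$sl_initial %||% profile$sl_response$sl_initial,
      rt_initial = sr$rt_initial %||% profile$sl_response$rt_initial)
  }
  validate_profile(profile)
  profile
}

`%||%` <- function(a, b) if (is.null(a)) b else a
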