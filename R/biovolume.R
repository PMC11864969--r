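#' Geometric shapes recognised by the biovolume estimator
#'
#' Each foraminiferal species is approximated by the closest simple solid.
#' All axes are full lengths (diameters) in micrometres, as measured on a
#' calibrated microscope image; the closed-form volume formulas divide by
#' two internally.
#'
#' @return A character vector of the supported shape kinds.
#' @export
shape_kinds <- function() {
  c("sphere", "prolate_spheroid", "oblate_spheroid", "triaxial_ellipsoid",
    "elliptic_cone", "elliptic_cylinder", "half_ellipsoid")
}

# Required axis names, in order, for each shape. "major"/"minor" are the
# two principal full diameters of the elliptical cross-section; "height"
# is the third dimension (the one most often hidden on a plan-view image).
shape_axis_table <- list(
  sphere             = "diameter",
  prolate_spheroid   = c("major", "minor"),
  oblate_spheroid    = c("major", "minor"),
  triaxial_ellipsoid = c("major", "minor", "height"),
  elliptic_cone      = c("major", "minor", "height"),
  elliptic_cylinder  = c("major", "minor", "height"),
  half_ellipsoid     = c("major", "minor", "height")
)

#' Axis names required by a shape
#'
#' @param shape_kind One of [shape_kinds()].
#' @return Character vector of axis names in canonical order.
#' @export
required_axes <- function(shape_kind) {
  shape_kind <- match.arg(shape_kind, shape_kinds())
  shape_axis_table[[shape_kind]]
}

# Closed-form volumes in cubic micrometres from full-length axes.
# sphere pi d^3/6; spheroids & ellipsoid pi a b c/6; elliptic cone
# pi a b h/12; elliptic cylinder pi a b h/4; half-ellipsoid pi a b c/12.
shape_volume_um3 <- function(shape_kind, axes) {
  switch(shape_kind,
    sphere             = pi * axes[["diameter"]]^3 / 6,
    prolate_spheroid   = pi * axes[["major"]] * axes[["minor"]]^2 / 6,
    oblate_spheroid    = pi * axes[["major"]]^2 * axes[["minor"]] / 6,
    triaxial_ellipsoid = pi * axes[["major"]] * axes[["minor"]] * axes[["height"]] / 6,
    elliptic_cone      = pi * axes[["major"]] * axes[["minor"]] * axes[["height"]] / 12,
    elliptic_cylinder  = pi * axes[["major"]] * axes[["minor"]] * axes[["height"]] / 4,
    half_ellipsoid     = pi * axes[["major"]] * axes[["minor"]] * axes[["height"]] / 12
  )
}

#' Test volume of a single specimen
#'
#' Computes the external (test) volume of one specimen from its measured
#' axes and an assigned geometric shape. Axes are full lengths in
#' micrometres; the result is in litres (1 um^3 = 1e-15 l).
#'
#' @param shape_kind One of [shape_kinds()].
#' @param axes Named numeric vector or list of axis lengths (um). Must
#'   supply every axis named by [required_axes()] for the shape.
#' @return Test volume in litres (scalar).
#' @examples
#' compute_test_volume("sphere", c(diameter = 100))
#' compute_test_volume("elliptic_cone", c(major = 100, minor = 50, height = 133))
#' @export
compute_test_volume <- function(shape_kind, axes) {
  shape_kind <- match.arg(shape_kind, shape_kinds())
  axes <- unlist(axes)
  need <- required_axes(shape_kind)
  missing_ax <- setdiff(need, names(axes))
  if (length(missing_ax) > 0) {
    stop("missing required axis for shape '", shape_kind, "': ",
         paste(missing_ax, collapse = ", "), call. = FALSE)
  }
  vals <- axes[need]
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all axes must be positive and finite; got ",
         paste(sprintf("%s=%s", need, vals), collapse = ", "), call. = FALSE)
  }
  shape_volume_um3(shape_kind, as.list(vals)) * 1e-15
}

#' Infer a hidden specimen height
#'
#' Plan-view microscope images do not show the height of some test
#' morphologies. Two rules reconstruct it: a species mean height
#' (`fixed_height`, e.g. 133 um for *Bolivina spissa*), or the mean ratio
#' of the shortest visible diameter to the height (`diameter_ratio`,
#' e.g. 0.424 for *Cibicidoides wuellerstorfi*, so height = shortest
#' diameter / 0.424). A measurement that already carries a height is
#' returned unchanged.
#'
#' @param axes Named numeric vector of measured axes (um), possibly
#'   lacking `"height"`.
#' @param rule_kind `"fixed_height"` or `"diameter_ratio"`; may be `NA`
#'   when the height is already present.
#' @param value Height in um (`fixed_height`) or dimensionless ratio in
#'   (0, 1] (`diameter_ratio`).
#' @return The axes vector with `"height"` filled in.
#' @export
infer_hidden_height <- function(axes, rule_kind, value) {
  axes <- unlist(axes)
  if ("height" %in% names(axes) && is.finite(axes[["height"]])) {
    return(axes)
  }
  if (is.na(rule_kind)) {
    stop("height is missing and no height rule is available", call. = FALSE)
  }
  rule_kind <- match.arg(rule_kind, c("fixed_height", "diameter_ratio"))
  if (rule_kind == "fixed_height") {
    if (!is.finite(value) || value <= 0) {
      stop("fixed_height rule value must be a positive height in um", call. = FALSE)
    }
    h <- value
  } else {
    if (!is.finite(value) || value <= 0 || value > 1) {
      stop("diameter_ratio rule value must lie in (0, 1]", call. = FALSE)
    }
    diams <- axes[names(axes) != "height"]
    if (length(diams) == 0) {
      stop("diameter_ratio rule needs at least one measured diameter", call. = FALSE)
    }
    # ratio is shortest-diameter : height, so height = diameter / ratio
    h <- min(diams) / value
  }
  axes[["height"]] <- h
  axes
}

#' Cell volume from test volume
#'
#' The internal test volume holds the cytoplasm and is taken as a fixed
#' fraction (default 75%) of the external test volume.
#'
#' @param test_volume Test volume in litres (> 0), vectorised.
#' @param cytoplasm_fraction Fraction of the test volume occupied by
#'   cytoplasm, in (0, 1]. Default 0.75.
#' @return Cell volume in litres.
#' @export
cell_volume <- function(test_volume, cytoplasm_fraction = 0.75) {
  if (any(!is.finite(test_volume)) || any(test_volume <= 0)) {
    stop("test_volume must be positive", call. = FALSE)
  }
  if (!is.finite(cytoplasm_fraction) || cytoplasm_fraction <= 0 ||
      cytoplasm_fraction > 1) {
    stop("cytoplasm_fraction must lie in (0, 1]", call. = FALSE)
  }
  test_volume * cytoplasm_fraction
}

#' Default species-to-shape assignments
#'
#' Editable configuration table mapping species names to geometric shapes
#' and hidden-height rules. The shipped defaults cover the species with
#' measured phosphate contents; the shape column is a working assignment
#' that users should override from their own morphometric judgement
#' (`rbind` or `dplyr::rows_update` a corrected table). Species absent
#' from the table require explicit assignment.
#'
#' @return A tibble with columns `species`, `shape_kind`,
#'   `height_rule` (`NA`, `"fixed_height"` or `"diameter_ratio"`) and
#'   `height_value` (um or ratio).
#' @export
foram_shape_defaults <- function() {
  tibble::tribble(
    ~species,                      ~shape_kind,          ~height_rule,     ~height_value,
    "Ammonia confertitesta",       "oblate_spheroid",    NA_character_,    NA_real_,
    "Ammonia veneta",              "oblate_spheroid",    NA_character_,    NA_real_,
    "Bolivina costata",            "prolate_spheroid",   NA_character_,    NA_real_,
    "Bolivina interjuncta",        "prolate_spheroid",   NA_character_,    NA_real_,
    "Bolivina seminuda",           "prolate_spheroid",   NA_character_,    NA_real_,
    "Bolivina spissa",             "elliptic_cone",      "fixed_height",   133,
    "Cassidulina limbata",         "oblate_spheroid",    NA_character_,    NA_real_,
    "Cassidulina ovoidea",         "oblate_spheroid",    NA_character_,    NA_real_,
    "Cibiscides mundulus",         "triaxial_ellipsoid", "diameter_ratio", 0.424,
    "Cibicidoides wuellerstorfi",  "triaxial_ellipsoid", "diameter_ratio", 0.424,
    "Eggerella advena",            "elliptic_cone",      NA_character_,    NA_real_,
    "Eggerella bartletti",         "elliptic_cone",      NA_character_,    NA_real_,
    "Globobulimina affinis",       "prolate_spheroid",   NA_character_,    NA_real_,
    "Haynesina germanica",         "oblate_spheroid",    NA_character_,    NA_real_,
    "Hoeglundina elegans",         "oblate_spheroid",    NA_character_,    NA_real_,
    "Labrospira crassimarga",      "oblate_spheroid",    NA_character_,    NA_real_,
    "Rhizammina algaeformis",      "elliptic_cylinder",  NA_character_,    NA_real_,
    "Spiroplectammina biformis",   "half_ellipsoid",     NA_character_,    NA_real_,
    "Stainforthia fusiformis",     "prolate_spheroid",   NA_character_,    NA_real_,
    "Uvigerina akitaensis",        "prolate_spheroid",   NA_character_,    NA_real_,
    "Valvulineria inflata",        "oblate_spheroid",    NA_character_,    NA_real_
  )
}

#' Estimate biovolumes for a table of specimens
#'
#' Data-frame-first wrapper over [compute_test_volume()],
#' [infer_hidden_height()] and [cell_volume()]. Each row is one imaged
#' specimen; axis columns are full lengths in micrometres.
#'
#' @param measurements Data frame with columns `specimen_id`, `species`
#'   and one column per measured axis (`diameter`, `major`, `minor`,
#'   `height`; unused axes may be `NA`).
#' @param shapes Shape configuration table as returned by
#'   [foram_shape_defaults()]; must cover every species present.
#' @param cytoplasm_fraction Passed to [cell_volume()].
#' @return A tibble with one row per specimen: `specimen_id`, `species`,
#'   `shape_kind`, `test_volume_l`, `cell_volume_l`.
#' @examples
#' meas <- tibble::tibble(
#'   specimen_id = "sp1", species = "Bolivina spissa",
#'   major = 100, minor = 50, height = NA_real_
#' )
#' estimate_biovolume(meas)
#' @export
estimate_biovolume <- function(measurements, shapes = foram_shape_defaults(),
                               cytoplasm_fraction = 0.75) {
  stopifnot(is.data.frame(measurements),
            all(c("specimen_id", "species") %in% names(measurements)))
  axis_cols <- intersect(c("diameter", "major", "minor", "height"),
                         names(measurements))
  unknown <- setdiff(unique(measurements$species), shapes$species)
  if (length(unknown) > 0) {
    stop("no shape assignment for species: ",
         paste(unknown, collapse = ", "),
         "; extend the shapes table", call. = FALSE)
  }
  m <- dplyr::left_join(measurements, shapes, by = "species")
  vols <- purrr::pmap_dbl(m, function(...) {
    row <- list(...)
    ax <- unlist(row[axis_cols])
    ax <- ax[is.finite(ax)]
    if (!("height" %in% names(ax)) &&
        "height" %in% required_axes(row$shape_kind)) {
      ax <- infer_hidden_height(ax, row$height_rule, row$height_value)
    }
    compute_test_volume(row$shape_kind, ax)
  })
  tibble::tibble(
    specimen_id = measurements$specimen_id,
    species = measurements$species,
    shape_kind = m$shape_kind,
    test_volume_l = vols,
    cell_volume_l = cell_volume(vols, cytoplasm_fraction)
  )
}

#' Per-species biovolume summary
#'
#' @param biovolumes Output of [estimate_biovolume()].
#' @return A tibble with per-species mean and sd of test and cell
#'   volumes (sd is `NA` for single-specimen species) and `n_specimens`.
#' @export
summarize_biovolume <- function(biovolumes) {
  biovolumes |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_specimens = dplyr::n(),
      mean_test_volume_l = mean(.data$test_volume_l),
      sd_test_volume_l = ifelse(dplyr::n() > 1, stats::sd(.data$test_volume_l), NA_real_),
      mean_cell_volume_l = mean(.data$cell_volume_l),
      sd_cell_volume_l = ifelse(dplyr::n() > 1, stats::sd(.data$cell_volume_l), NA_real_),
      .groups = "drop"
    )
}
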