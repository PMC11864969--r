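#' Reference library of intracellular phosphate contents
#'
#' Mean per-individual intracellular phosphate contents (pmol per
#' individual), mean cell volumes and sampling regions for benthic
#' foraminifera measured by freeze-thaw extraction. *Ammonia veneta* is
#' excluded by default: its measurements come from laboratory cultures
#' only, not environmental samples. Entries with `content_pmol = NA`
#' could not be quantified and act as unmeasured species (candidates for
#' genus-mean imputation).
#'
#' @return A tibble with columns `species`, `mean_cell_volume_l`,
#'   `content_pmol`, `conc_mM`, `region`, `provenance`, `excluded`.
#' @export
foram_content_library <- function() {
  tibble::tribble(
    ~species, ~mean_cell_volume_l, ~content_pmol, ~conc_mM, ~region,
    "Ammonia confertitesta",      9.32e-9,  412,  42.7, "Friedrichskoog",
    "Ammonia veneta",             3.63e-9,   NA,    NA, "Culture",
    "Bolivina costata",           7.92e-10,  33,  41.2, "Peru (OMZ)",
    "Bolivina interjuncta",       1.56e-8,  321,  20.6, "Peru (OMZ)",
    "Bolivina seminuda",          1.69e-9,   69,  40.3, "Peru (OMZ)",
    "Bolivina spissa",            3.49e-9,   83,  23.8, "Sagami Bay",
    "Cassidulina limbata",        1.96e-8,  290,  14.9, "Peru (OMZ)",
    "Cassidulina ovoidea",        8.06e-9,   NA,    NA, "Sagami Bay",
    "Cibiscides mundulus",        6.79e-8,    2,   0.0, "Rainbow Vent Field",
    "Cibicidoides wuellerstorfi", 1.91e-8,    3,   0.2, "Rainbow Vent Field",
    "Eggerella advena",           2.59e-9,   31,  12.1, "Bedford Basin",
    "Eggerella bartletti",        2.94e-8,  478,  16.4, "Bedford Basin",
    "Globobulimina affinis",      1.76e-7, 1078,   6.3, "Sagami Bay",
    "Globobulimina affinis",      9.62e-8,  600,   6.2, "Bedford Basin",
    "Haynesina germanica",        1.15e-8,  165,  14.5, "Friedrichskoog",
    "Hoeglundina elegans",        1.28e-7,   88,   0.7, "Rainbow Vent Field",
    "Labrospira crassimarga",     3.97e-8,   56,   1.4, "Bedford Basin",
    "Rhizammina algaeformis",     7.40e-7,  108,   0.1, "Rainbow Vent Field",
    "Spiroplectammina biformis",  2.02e-9,   19,   9.3, "Bedford Basin",
    "Stainforthia fusiformis",    7.52e-10,   9,  12.3, "Bedford Basin",
    "Uvigerina akitaensis",       1.50e-8,  203,  13.6, "Sagami Bay",
    "Valvulineria inflata",       1.35e-7, 2603,  19.5, "Peru (OMZ)"
  ) |>
    dplyr::mutate(
      provenance = "measured",
      excluded = .data$species == "Ammonia veneta" | is.na(.data$content_pmol)
    )
}

#' Genus of a binomial species name
#'
#' The genus is the first whitespace-delimited token of the name.
#'
#' @param species Character vector of "Genus epithet" names.
#' @return Character vector of genera.
#' @export
parse_genus <- function(species) {
  if (any(is.na(species) | !nzchar(trimws(species)))) {
    stop("species names must be non-empty", call. = FALSE)
  }
  vapply(strsplit(trimws(species), "\\s+"), `[[`, character(1), 1)
}

#' Resolve a species' phosphate content against a library
#'
#' Resolution order: a non-excluded exact match returns the mean of its
#' library entries; otherwise the mean over all non-excluded congeners
#' (genus-mean imputation); otherwise the species is excluded and
#' contributes zero to assemblage stocks.
#'
#' @param species Character vector of species names.
#' @param library Content library (see [foram_content_library()]); must
#'   have columns `species`, `content_pmol`, `excluded`.
#' @return A tibble with one row per input species: `species`,
#'   `content_pmol` (`NA` when excluded) and `provenance` (`"measured"`,
#'   `"genus_mean"` or `"excluded"`).
#' @examples
#' lookup_content(c("Bolivina spissa", "Bolivina sp."))
#' @export
lookup_content <- function(species, library = foram_content_library()) {
  stopifnot(all(c("species", "content_pmol", "excluded") %in% names(library)))
  usable <- library |>
    dplyr::filter(!.data$excluded, !is.na(.data$content_pmol))
  by_species <- usable |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(content_pmol = mean(.data$content_pmol), .groups = "drop")
  by_genus <- usable |>
    dplyr::mutate(genus = parse_genus(.data$species)) |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(genus_content = mean(.data$content_pmol), .groups = "drop")
  tibble::tibble(species = species, genus = parse_genus(species)) |>
    dplyr::left_join(by_species, by = "species") |>
    dplyr::left_join(by_genus, by = "genus") |>
    dplyr::mutate(
      provenance = dplyr::case_when(
        !is.na(.data$content_pmol) ~ "measured",
        !is.na(.data$genus_content) ~ "genus_mean",
        TRUE ~ "excluded"
      ),
      content_pmol = dplyr::coalesce(.data$content_pmol, .data$genus_content)
    ) |>
    dplyr::select("species", "content_pmol", "provenance")
}

#' Convert assemblage abundances to individuals per square metre
#'
#' Source assemblage datasets report abundances in different dialects.
#' Supported units: `"ind_m2"` (identity), `"ind_cm2"` (x 1e4) and
#' `"ind_10cm3"` (individuals per 10 cm^3 of sediment; divided by 10 to
#' ind cm^-3, multiplied by the layer depth in cm, then x 1e4).
#'
#' @param abundance Numeric abundances.
#' @param units One of `"ind_m2"`, `"ind_cm2"`, `"ind_10cm3"`
#'   (vectorised).
#' @param layer_depth_cm Sediment layer depth for volumetric units
#'   (default 1 cm).
#' @param quiet Suppress the conversion message.
#' @return Abundances in ind m^-2.
#' @export
convert_abundance <- function(abundance, units = "ind_m2",
                              layer_depth_cm = 1, quiet = FALSE) {
  units <- rep_len(units, length(abundance))
  bad <- setdiff(unique(units), c("ind_m2", "ind_cm2", "ind_10cm3"))
  if (length(bad) > 0) {
    stop("unknown abundance units: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor <- dplyr::case_when(
    units == "ind_m2" ~ 1,
    units == "ind_cm2" ~ 1e4,
    units == "ind_10cm3" ~ layer_depth_cm / 10 * 1e4
  )
  if (!quiet && any(units != "ind_m2")) {
    message("converted ", sum(units != "ind_m2"),
            " abundances to ind m^-2 (x1e4 per cm^2; x",
            format(layer_depth_cm / 10 * 1e4), " per 10 cm^3 over ",
            layer_depth_cm, " cm)")
  }
  abundance * factor
}

#' Assemblage-based phosphate stock per station
#'
#' Sums per-species standing stocks over each station's living
#' assemblage: `mmol m^-2 = sum(A_n * content_n * 1e-9)` where `A_n` is
#' living abundance in ind m^-2 and `content_n` the species' mean
#' intracellular phosphate content in pmol per individual, resolved via
#' [lookup_content()] (exact match, then genus mean, else excluded).
#' The mass stock uses the molar mass of phosphate, `g m^-2 =
#' mmol m^-2 * 1e-3 * molar_mass`.
#'
#' @param assemblage Data frame with columns `station_id`, `species`,
#'   `abundance` plus optionally `latitude`, `longitude`,
#'   `abundance_units` (see [convert_abundance()]).
#' @param library Content library, see [foram_content_library()].
#' @param molar_mass Molar mass of phosphate in g/mol (default 95).
#' @param layer_depth_cm Passed to [convert_abundance()].
#' @return A tibble with one row per station: `station_id`,
#'   (`latitude`, `longitude` if supplied), `stock_mmol_m2`,
#'   `stock_g_m2`, `n_species`, and `excluded_abundance_share` (the
#'   fraction of total living abundance carried by species without a
#'   resolvable content, bounding the unaccounted stock).
#' @export
station_stocks <- function(assemblage, library = foram_content_library(),
                           molar_mass = 95, layer_depth_cm = 1) {
  stopifnot(is.data.frame(assemblage),
            all(c("station_id", "species", "abundance") %in% names(assemblage)))
  if (any(assemblage$abundance < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(assemblage[c("station_id", "species")]) > 0) {
    stop("duplicated (station, species) pairs in assemblage", call. = FALSE)
  }
  if ("abundance_units" %in% names(assemblage)) {
    assemblage$abundance <- convert_abundance(
      assemblage$abundance, assemblage$abundance_units,
      layer_depth_cm = layer_depth_cm, quiet = TRUE)
  }
  contents <- lookup_content(unique(assemblage$species), library)
  coord_cols <- intersect(c("latitude", "longitude"), names(assemblage))
  assemblage |>
    dplyr::left_join(contents, by = "species") |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(coord_cols), dplyr::first),
      stock_mmol_m2 = sum(.data$abundance * .data$content_pmol * 1e-9,
                          na.rm = TRUE),
      n_species = dplyr::n(),
      excluded_abundance_share =
        sum(.data$abundance[.data$provenance == "excluded"]) /
          max(sum(.data$abundance), .Machine$double.eps),
      .groups = "drop"
    ) |>
    dplyr::mutate(stock_g_m2 = .data$stock_mmol_m2 * 1e-3 * molar_mass,
                  .after = "stock_mmol_m2")
}

#' Regional mean stock with standard error
#'
#' Weighted mean of per-station stocks (default equal weights) with its
#' standard error: `sd / sqrt(n)` under equal weights, and the weighted
#' analogue `sqrt(sum(w^2 (x - m)^2)) / sum(w)` otherwise.
#'
#' @param stocks Numeric vector of station stocks (g m^-2), or the
#'   tibble returned by [station_stocks()] (column `stock_g_m2` used).
#' @param weights Optional station weights (e.g. area of influence).
#' @return A tibble with `mean_stock_g_m2`, `se_stock_g_m2` (`NA` for a
#'   single station) and `n_stations`.
#' @export
regional_summary <- function(stocks, weights = NULL) {
  if (is.data.frame(stocks)) stocks <- stocks$stock_g_m2
  n <- length(stocks)
  if (n == 0) stop("no station stocks supplied", call. = FALSE)
  if (is.null(weights)) {
    m <- mean(stocks)
    se <- if (n > 1) stats::sd(stocks) / sqrt(n) else NA_real_
  } else {
    if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
      stop("weights must be non-negative, match stocks in length and not all be zero",
           call. = FALSE)
    }
    w <- weights / sum(weights)
    m <- sum(w * stocks)
    se <- if (n > 1) sqrt(sum(w^2 * (stocks - m)^2)) else NA_real_
  }
  tibble::tibble(mean_stock_g_m2 = m, se_stock_g_m2 = se, n_stations = n)
}

#' Regional phosphate budget against riverine runoff
#'
#' Scales a mean areal stock to a regional total and expresses it as
#' days of riverine phosphorus runoff that the standing stock could
#' buffer: `total (t) = mean_stock (g m^-2) * area (m^2) * 1e-6` and
#' `buffer_days = total / runoff * 365`.
#'
#' @param mean_stock_g_m2 Regional mean stock (g m^-2).
#' @param area_m2 Region area (m^2).
#' @param runoff_t_yr Riverine phosphorus runoff (t/yr, > 0).
#' @param se_stock_g_m2 Optional standard error of the mean stock,
#'   propagated linearly to the total and the buffer days.
#' @return A `region_budget` object (also a tibble) with columns
#'   `mean_stock_g_m2`, `se_stock_g_m2`, `area_m2`, `total_stock_t`,
#'   `se_total_stock_t`, `runoff_t_yr`, `buffer_days`, `se_buffer_days`.
#' @examples
#' buffer_budget(0.0059, 4.44e10, 2583)
#' @export
buffer_budget <- function(mean_stock_g_m2, area_m2, runoff_t_yr,
                          se_stock_g_m2 = NA_real_) {
  if (mean_stock_g_m2 < 0) stop("mean stock must be >= 0", call. = FALSE)
  if (area_m2 <= 0) stop("area must be positive", call. = FALSE)
  if (runoff_t_yr <= 0) stop("runoff must be positive", call. = FALSE)
  total_t <- mean_stock_g_m2 * area_m2 * 1e-6
  se_total <- se_stock_g_m2 * area_m2 * 1e-6
  out <- tibble::tibble(
    mean_stock_g_m2 = mean_stock_g_m2,
    se_stock_g_m2 = se_stock_g_m2,
    area_m2 = area_m2,
    total_stock_t = total_t,
    se_total_stock_t = se_total,
    runoff_t_yr = runoff_t_yr,
    buffer_days = total_t / runoff_t_yr * 365,
    se_buffer_days = se_total / runoff_t_yr * 365
  )
  class(out) <- c("region_budget", class(out))
  out
}

#' Areal extrapolation of a single-species phosphate reservoir
#'
#' Extrapolates a volumetric population density over a sediment layer
#' and a region area to a total standing stock in tonnes of phosphate:
#' `ind m^-2 = density * depth * 1e4`, then
#' `tonnes = ind m^-2 * content * 1e-12 * molar_mass * area * 1e-6`.
#'
#' @param density_ind_cm3 Living population density (ind cm^-3).
#' @param depth_cm Sediment layer depth (cm), default 1.
#' @param content_pmol Individual phosphate content (pmol/ind).
#' @param area_m2 Region area (m^2).
#' @param molar_mass Molar mass of phosphate (g/mol), default 95.
#' @return Total stock in tonnes.
#' @examples
#' # bloom density over the top cm of a 11,500 km^2 tidal flat
#' areal_extrapolation(417, 1, 413, 1.15e10)
#' @export
areal_extrapolation <- function(density_ind_cm3, depth_cm = 1, content_pmol,
                                area_m2, molar_mass = 95) {
  stopifnot(density_ind_cm3 >= 0, depth_cm > 0, content_pmol >= 0,
            molar_mass > 0)
  if (area_m2 < 1) {
    warning("area below 1 m^2; check that area_m2 is in square metres")
  }
  ind_m2 <- density_ind_cm3 * depth_cm * 1e4
  ind_m2 * content_pmol * 1e-12 * molar_mass * area_m2 * 1e-6
}

#' Living population density from a split sediment count
#'
#' Rose-Bengal-stained individuals are counted in a dry-splitter
#' fraction of a known bulk sediment volume taken over a known layer
#' depth.
#'
#' @param counted Number of stained individuals counted (>= 0).
#' @param split_fraction Fraction of the sample counted, in (0, 1].
#' @param sediment_volume_cm3 Bulk sediment volume (cm^3, > 0).
#' @param depth_cm Sampled layer depth (cm).
#' @return A tibble with `density_ind_cm3` and `density_ind_cm2`
#'   (volumetric density integrated over the layer).
#' @export
population_density <- function(counted, split_fraction, sediment_volume_cm3,
                               depth_cm = 1) {
  stopifnot(counted >= 0, counted == round(counted))
  if (split_fraction <= 0 || split_fraction > 1) {
    stop("split_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (sediment_volume_cm3 <= 0) {
    stop("sediment volume must be positive", call. = FALSE)
  }
  d3 <- counted / split_fraction / sediment_volume_cm3
  tibble::tibble(density_ind_cm3 = d3, density_ind_cm2 = d3 * depth_cm)
}
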