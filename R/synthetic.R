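#' @importFrom rlang .data
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Independent per-generator streams derived from one master seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 2039 + 104729 * offset) %% 2147483000L
}

#' Generate synthetic specimen measurement tables
#'
#' Draws per-specimen axis lengths from species-specific lognormal
#' distributions and records the exact test volume implied by the
#' assigned shape, so that downstream biovolume estimation can be
#' checked for exact recovery.
#'
#' @param n Specimens per species.
#' @param species_params Tibble with columns `species`, `shape_kind`,
#'   `meanlog`, `sdlog` (lognormal parameters of the axis lengths in
#'   um). Default: three species covering 1-, 2- and 3-axis shapes.
#' @param seed Integer seed.
#' @return A list: `measurements` (tibble with `specimen_id`, `species`
#'   and axis columns), `shapes` (configuration table for
#'   [estimate_biovolume()]) and `truth` (tibble with the exact
#'   `test_volume_l` per specimen).
#' @export
gen_specimens <- function(n = 20,
                          species_params = default_specimen_params(),
                          seed = 1) {
  stopifnot(all(c("species", "shape_kind", "meanlog", "sdlog")
                %in% names(species_params)))
  bad <- setdiff(species_params$shape_kind, shape_kinds())
  if (length(bad) > 0) {
    stop("unknown shape kinds: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  with_seed(derive_seed(seed, 1), {
    rows <- purrr::pmap(species_params, function(species, shape_kind,
                                                 meanlog, sdlog) {
      need <- required_axes(shape_kind)
      purrr::map(seq_len(n), function(i) {
        # descending sorted draws keep major >= minor >= height plausible
        ax <- sort(stats::rlnorm(length(need), meanlog, sdlog),
                   decreasing = TRUE)
        names(ax) <- need
        list(species = species, shape_kind = shape_kind, axes = ax,
             volume = compute_test_volume(shape_kind, ax))
      })
    }) |> purrr::flatten()
    axis_names <- c("diameter", "major", "minor", "height")
    empty <- tibble::tibble(
      specimen_id = character(), species = character(),
      diameter = numeric(), major = numeric(), minor = numeric(),
      height = numeric())
    measurements <- purrr::map_dfr(seq_along(rows), function(i) {
      r <- rows[[i]]
      vals <- stats::setNames(rep(NA_real_, length(axis_names)), axis_names)
      vals[names(r$axes)] <- r$axes
      tibble::tibble(specimen_id = sprintf("syn%04d", i),
                     species = r$species, !!!as.list(vals))
    })
    if (length(rows) == 0) measurements <- empty
    shapes <- species_params |>
      dplyr::distinct(.data$species, .data$shape_kind) |>
      dplyr::mutate(height_rule = NA_character_, height_value = NA_real_)
    truth <- tibble::tibble(
      specimen_id = measurements$specimen_id,
      species = measurements$species,
      test_volume_l = purrr::map_dbl(rows, "volume")
    )
    list(measurements = measurements, shapes = shapes, truth = truth)
  })
}

#' @rdname gen_specimens
#' @export
default_specimen_params <- function() {
  tibble::tribble(
    ~species,              ~shape_kind,          ~meanlog,  ~sdlog,
    "Sphaerina exempli",   "sphere",             log(150),  0.25,
    "Prolatina exempli",   "prolate_spheroid",   log(250),  0.30,
    "Triaxella exempli",   "triaxial_ellipsoid", log(300),  0.30
  )
}

#' Generate synthetic extraction samples
#'
#' Simulates pooled freeze-thaw extracts of a species with known true
#' per-individual phosphate content. The measured autoanalyser
#' concentration is the exact pooled concentration perturbed by
#' multiplicative Gaussian noise (the natural model for small positive
#' autoanalyser signals):
#' `measured = content * n / (volume * 1e6) * (1 + noise)`.
#'
#' @param true_content_pmol True per-individual content (pmol/ind).
#' @param n_samples Number of pooled samples.
#' @param n_individuals Individuals per sample; scalar or vector
#'   (recycled). Field samples pool between one and 75 individuals.
#' @param noise_sd Relative noise standard deviation (default 0.05).
#' @param extract_volume_l Extract volume (default 0.003 l).
#' @param species Species label.
#' @param seed Integer seed.
#' @return A tibble of extraction samples (`sample_id`, `species`,
#'   `n_individuals`, `extract_volume_l`, `conc_umol_l`) with the true
#'   content attached as attribute `"true_content_pmol"`.
#' @export
gen_extractions <- function(true_content_pmol, n_samples = 10,
                            n_individuals = 10, noise_sd = 0.05,
                            extract_volume_l = 0.003,
                            species = "Synthetica exempli", seed = 1) {
  stopifnot(true_content_pmol >= 0, noise_sd >= 0,
            all(n_individuals >= 1), all(n_individuals <= 1000))
  n_ind <- rep_len(n_individuals, n_samples)
  with_seed(derive_seed(seed, 2), {
    true_conc <- true_content_pmol * n_ind / (extract_volume_l * 1e6)
    measured <- pmax(true_conc * (1 + stats::rnorm(n_samples, 0, noise_sd)), 0)
    out <- tibble::tibble(
      sample_id = sprintf("ext%04d", seq_len(n_samples)),
      species = species,
      n_individuals = n_ind,
      extract_volume_l = extract_volume_l,
      conc_umol_l = measured
    )
    attr(out, "true_content_pmol") <- true_content_pmol
    out
  })
}

#' Default synthetic species pool for assemblage generation
#'
#' Mixes three resolution classes: species measured in the content
#' library, unmeasured congeners of measured species (resolved by
#' genus-mean imputation; their true content is set to the genus mean,
#' matching the imputation model), and species with no measured
#' congener (excluded from stock estimates). `median_abundance` is the
#' lognormal median abundance in ind m^-2, scaled to productive shelf
#' assemblages.
#'
#' @param library Content library used to derive genus means.
#' @return A tibble with `species`, `class`, `true_content_pmol`,
#'   `median_abundance`.
#' @export
default_species_pool <- function(library = foram_content_library()) {
  genus_mean <- function(genus) {
    usable <- library[!library$excluded & !is.na(library$content_pmol), ]
    mean(usable$content_pmol[parse_genus(usable$species) == genus])
  }
  lib_content <- function(sp) {
    mean(library$content_pmol[library$species == sp])
  }
  measured <- tibble::tribble(
    ~species,                    ~median_abundance,
    "Ammonia confertitesta",     60000,
    "Haynesina germanica",       50000,
    "Eggerella advena",          30000,
    "Stainforthia fusiformis",   40000,
    "Bolivina seminuda",         20000,
    "Eggerella bartletti",        5000,
    "Spiroplectammina biformis", 15000,
    "Labrospira crassimarga",     3000
  ) |>
    dplyr::mutate(class = "measured",
                  true_content_pmol = purrr::map_dbl(.data$species, lib_content))
  imputable <- tibble::tibble(
    species = c("Ammonia batava", "Bolivina pseudopunctata"),
    median_abundance = c(25000, 10000),
    class = "genus_imputable",
    true_content_pmol = c(genus_mean("Ammonia"), genus_mean("Bolivina"))
  )
  excluded <- tibble::tibble(
    species = c("Elphidium excavatum", "Textularia earlandi"),
    median_abundance = c(30000, 8000),
    class = "excluded",
    true_content_pmol = c(120, 25)
  )
  dplyr::bind_rows(measured, imputable, excluded) |>
    dplyr::select("species", "class", "true_content_pmol", "median_abundance")
}

#' Generate a synthetic living assemblage with known regional stock
#'
#' Draws station-by-species living abundances from lognormal
#' distributions (the ecological convention for abundance variation)
#' and computes the implied true phosphate stocks by direct summation
#' with the generator's own contents.
#'
#' @param n_stations Number of stations (default 135, a dense shelf
#'   survey).
#' @param species_pool See [default_species_pool()].
#' @param sigma_log Lognormal sdlog of abundances across stations
#'   (default 0.5).
#' @param bbox Region bounding box `c(lon_min, lon_max, lat_min,
#'   lat_max)`; stations are placed uniformly.
#' @param molar_mass Molar mass of phosphate (g/mol).
#' @param seed Integer seed.
#' @return A list: `assemblage` (tibble ready for [station_stocks()]),
#'   `pool`, and `truth` with per-station true stocks (total and
#'   recoverable, g m^-2), the realized regional means, and
#'   `expected_mean_stock_g_m2` (the analytic expectation
#'   `sum(exp(meanlog + sigma^2/2) * content) * molar_mass * 1e-12`
#'   over recoverable species).
#' @export
gen_assemblage <- function(n_stations = 135,
                           species_pool = default_species_pool(),
                           sigma_log = 0.5,
                           bbox = c(2, 10, 51, 55),
                           molar_mass = 95,
                           seed = 1) {
  stopifnot(n_stations >= 1, sigma_log >= 0,
            all(c("species", "class", "true_content_pmol",
                  "median_abundance") %in% names(species_pool)))
  with_seed(derive_seed(seed, 3), {
    stations <- tibble::tibble(
      station_id = sprintf("st%03d", seq_len(n_stations)),
      longitude = stats::runif(n_stations, bbox[1], bbox[2]),
      latitude = stats::runif(n_stations, bbox[3], bbox[4])
    )
    grid <- tidyr::expand_grid(stations, species_pool)
    grid$abundance <- stats::rlnorm(nrow(grid),
                                    meanlog = log(grid$median_abundance),
                                    sdlog = sigma_log)
    assemblage <- grid |>
      dplyr::select("station_id", "latitude", "longitude", "species",
                    "abundance")
    recoverable <- species_pool$class != "excluded"
    truth_stations <- grid |>
      dplyr::group_by(.data$station_id) |>
      dplyr::summarise(
        stock_g_m2_total = sum(.data$abundance * .data$true_content_pmol) *
          1e-12 * molar_mass,
        stock_g_m2_recoverable = sum(
          (.data$abundance * .data$true_content_pmol)[.data$class != "excluded"]) *
          1e-12 * molar_mass,
        .groups = "drop"
      )
    expected_mean <- sum(
      exp(log(species_pool$median_abundance[recoverable]) + sigma_log^2 / 2) *
        species_pool$true_content_pmol[recoverable]) * 1e-12 * molar_mass
    list(
      assemblage = assemblage,
      pool = species_pool,
      truth = list(
        stations = truth_stations,
        realized_mean_stock_g_m2 = mean(truth_stations$stock_g_m2_recoverable),
        expected_mean_stock_g_m2 = expected_mean,
        molar_mass = molar_mass
      )
    )
  })
}

#' Generate a synthetic EDS phantom with known signal and background
#'
#' Builds per-element count maps over a smooth, spatially varying
#' bremsstrahlung background whose per-channel spectral shape is fixed
#' (the same weights at every pixel), plus disc-shaped enrichments of a
#' target element. The background under the target's characteristic
#' peak is constructed equal to the background outside all peaks, so
#' the analytic intensity-to-noise ratio is exactly `S/B + 1` and the
#' denominator of the ratio transform recovers it by construction.
#' Counts are optionally Poisson-sampled (the physics of X-ray
#' counting).
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param elements Element labels; the first carries the enrichments.
#' @param bg_level Mean outside-peak background (counts per pixel).
#' @param bg_relief Relative amplitude of the smooth background bump.
#' @param peak_weights Background weight under each element's peak
#'   relative to the outside-peak background; the target's weight is
#'   forced to 1.
#' @param signal_frac Outside-disc signal-to-background ratio of the
#'   target element (must be > 0 so contrast is identifiable).
#' @param contrast Inside/outside signal ratio of the enrichment discs
#'   (> 1).
#' @param other_signal_frac Signal-to-background ratio of the
#'   non-target elements (uniform).
#' @param n_discs,disc_radius Number and radius (px) of enrichment
#'   discs.
#' @param poisson Poisson-sample the counts?
#' @param seed Integer seed.
#' @return A list: `stack` (an [eds_stack()]), `truth` (latent `S` and
#'   `B` per element, outside-peak background `B_out`, `R_analytic` for
#'   the target, `disc_mask`, `signal_frac`, `contrast`).
#' @export
gen_eds_phantom <- function(shape = c(64, 64),
                            elements = c("P", "Ca", "S", "Cl", "Na"),
                            bg_level = 200,
                            bg_relief = 0.6,
                            peak_weights = NULL,
                            signal_frac = 0.5,
                            contrast = 4,
                            other_signal_frac = 0.3,
                            n_discs = 3,
                            disc_radius = 6,
                            poisson = TRUE,
                            seed = 1) {
  stopifnot(length(elements) >= 1, bg_level > 0, signal_frac > 0)
  if (contrast <= 0) stop("contrast must be positive", call. = FALSE)
  target <- elements[1]
  if (is.null(peak_weights)) {
    peak_weights <- stats::setNames(
      seq(1, 0.4, length.out = length(elements)), elements)
  }
  peak_weights[target] <- 1
  nr <- shape[1]; nc <- shape[2]
  with_seed(derive_seed(seed, 4), {
    # smooth positive background field: unit mean, fixed spatial shape
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    bump <- exp(-(((rr - nr * 0.35) / (nr * 0.35))^2 +
                    ((cc - nc * 0.6) / (nc * 0.35))^2))
    field <- 1 + bg_relief * (bump - mean(bump))
    b_out <- bg_level * field
    # enrichment discs of the target element; the radius shrinks on
    # small images so discs always fit inside the frame
    disc_mask <- matrix(FALSE, nr, nc)
    radius <- min(disc_radius, floor((min(nr, nc) - 3) / 2))
    if (radius < 1 && n_discs > 0) {
      stop("image too small to place enrichment discs", call. = FALSE)
    }
    centres <- cbind(stats::runif(n_discs, radius + 1, nr - radius),
                     stats::runif(n_discs, radius + 1, nc - radius))
    for (d in seq_len(n_discs)) {
      disc_mask <- disc_mask |
        ((rr - centres[d, 1])^2 + (cc - centres[d, 2])^2 <= radius^2)
    }
    B <- lapply(elements, function(el) peak_weights[[el]] * b_out)
    names(B) <- elements
    S <- lapply(elements, function(el) {
      if (el == target) {
        s <- signal_frac * B[[el]]
        s[disc_mask] <- contrast * s[disc_mask]
        s
      } else {
        other_signal_frac * B[[el]]
      }
    })
    names(S) <- elements
    expected_I <- purrr::map2(S, B, `+`)
    expected_cps_extra <- b_out  # outside-peak background completes CPS
    if (poisson) {
      count_maps <- lapply(expected_I, function(m) {
        matrix(stats::rpois(length(m), m), nr, nc)
      })
      extra <- matrix(stats::rpois(length(b_out), expected_cps_extra), nr, nc)
    } else {
      count_maps <- expected_I
      extra <- expected_cps_extra
    }
    cps <- Reduce(`+`, count_maps) + extra
    r_analytic <- S[[target]] / B[[target]] + 1
    list(
      stack = eds_stack(count_maps, cps),
      truth = list(S = S, B = B, B_out = b_out,
                   R_analytic = r_analytic, disc_mask = disc_mask,
                   signal_frac = signal_frac, contrast = contrast)
    )
  })
}
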