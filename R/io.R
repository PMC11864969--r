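#' Read a specimen measurement table
#'
#' CSV/TSV with columns `specimen_id`, `species` and axis columns in
#' micrometres (`diameter`, `major`, `minor`, `height`).
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, else comma).
#' @return A tibble.
#' @export
read_measurements <- function(path) {
  x <- read_delim_auto(path)
  need <- c("specimen_id", "species")
  if (!all(need %in% names(x))) {
    stop("measurement table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read an extraction sample table
#'
#' CSV/TSV with columns `sample_id`, `species`, `n_individuals`,
#' `conc_umol_l` and optionally `extract_volume_l`, `region`.
#'
#' @inheritParams read_measurements
#' @return A tibble.
#' @export
read_extractions <- function(path) {
  x <- read_delim_auto(path)
  need <- c("sample_id", "species", "n_individuals", "conc_umol_l")
  if (!all(need %in% names(x))) {
    stop("extraction table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read a living-assemblage table
#'
#' CSV/TSV with columns `station_id`, `latitude`, `longitude`,
#' `species`, `abundance` and optionally `abundance_units`
#' (see [convert_abundance()]).
#'
#' @inheritParams read_measurements
#' @return A tibble.
#' @export
read_assemblage <- function(path) {
  x <- read_delim_auto(path)
  need <- c("station_id", "species", "abundance")
  if (!all(need %in% names(x))) {
    stop("assemblage table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read a content library table
#'
#' CSV/TSV with columns `species`, `content_pmol` and optionally
#' `excluded`, `provenance`, `mean_cell_volume_l`.
#'
#' @inheritParams read_measurements
#' @return A tibble with `excluded` filled (default `FALSE`).
#' @export
read_content_library <- function(path) {
  x <- read_delim_auto(path)
  need <- c("species", "content_pmol")
  if (!all(need %in% names(x))) {
    stop("content library must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!("excluded" %in% names(x))) x$excluded <- FALSE
  x$excluded <- x$excluded | is.na(x$content_pmol)
  x
}

#' Read a region specification
#'
#' YAML-less plain key,value CSV or JSON file with fields `area_m2`,
#' `runoff_t_per_yr` and optionally `molar_mass`, `name`, bounding-box
#' fields.
#'
#' @param path Path to a JSON file (`.json`) or two-column `key,value`
#'   CSV.
#' @return A named list.
#' @export
read_region_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    kv <- read_delim_auto(path)
    stopifnot(ncol(kv) >= 2)
    cfg <- as.list(kv[[2]])
    names(cfg) <- kv[[1]]
    cfg <- lapply(cfg, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    })
  }
  if (!all(c("area_m2", "runoff_t_per_yr") %in% names(cfg))) {
    stop("region config needs area_m2 and runoff_t_per_yr", call. = FALSE)
  }
  cfg
}

read_delim_auto <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Write a tibble as CSV
#'
#' Thin wrapper kept for a stable output dialect across the package's
#' result tables.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
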