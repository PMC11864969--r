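#' Blank-correct autoanalyser phosphate concentrations
#'
#' Subtracts the mean of procedural blanks from measured concentrations,
#' flooring at zero, and flags values below the instrument detection
#' limit. Blank correction is optional and off by default for phosphate
#' (procedural blanks are typically run for the nitrate channel); enable
#' it explicitly when blanks apply to the phosphate channel.
#'
#' @param measured Measured concentrations in umol/l (vectorised).
#' @param blanks Numeric vector of procedural blank concentrations
#'   (umol/l); required when `correct = TRUE`.
#' @param correct Apply the correction? Default `FALSE` (identity).
#' @param detection_limit Instrument detection limit in umol/l
#'   (default 0.004). Values below it are flagged, not censored.
#' @return A tibble with columns `measured_umol_l`, `corrected_umol_l`
#'   and `below_detection`.
#' @export
blank_correct <- function(measured, blanks = NULL, correct = FALSE,
                          detection_limit = 0.004) {
  if (any(!is.finite(measured)) || any(measured < 0)) {
    stop("measured concentrations must be non-negative", call. = FALSE)
  }
  if (correct) {
    if (is.null(blanks) || length(blanks) == 0) {
      stop("blank correction enabled but no blanks supplied", call. = FALSE)
    }
    if (any(blanks < 0)) stop("blank concentrations must be >= 0", call. = FALSE)
    corrected <- pmax(measured - mean(blanks), 0)
  } else {
    corrected <- measured
  }
  tibble::tibble(
    measured_umol_l = measured,
    corrected_umol_l = corrected,
    below_detection = corrected < detection_limit
  )
}

#' Per-individual phosphate content of a pooled extract
#'
#' A pooled sample of `n_individuals` specimens is extracted by
#' freeze-thaw cycles into `extract_volume` litres of reverse-osmosis
#' water (default 3 ml) and the extract measured on an autoanalyser.
#' Content per individual is
#' `conc (umol/l) * volume (l) * 1e6 / n`, in pmol per individual.
#'
#' @param conc_umol_l Phosphate concentration of the extract (umol/l).
#' @param n_individuals Number of pooled individuals (>= 1).
#' @param extract_volume_l Extract volume in litres (default 0.003).
#' @return Content in pmol per individual (vectorised).
#' @examples
#' individual_content(1.0, 1)        # 3000 pmol/ind
#' individual_content(0.01, 10)      # 3 pmol/ind
#' @export
individual_content <- function(conc_umol_l, n_individuals,
                               extract_volume_l = 0.003) {
  if (any(!is.finite(conc_umol_l)) || any(conc_umol_l < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  if (any(n_individuals < 1) || any(n_individuals != round(n_individuals))) {
    stop("n_individuals must be a positive integer", call. = FALSE)
  }
  if (any(extract_volume_l <= 0)) {
    stop("extract_volume_l must be positive", call. = FALSE)
  }
  conc_umol_l * extract_volume_l * 1e6 / n_individuals
}

#' Intracellular phosphate concentration
#'
#' Converts a per-individual content and a mean cell volume into an
#' intracellular concentration:
#' `mM = content (pmol) * 1e-9 (mmol/pmol) / cell_volume (l)`.
#'
#' @param content_pmol Phosphate content in pmol per individual.
#' @param cell_volume_l Cell (cytoplasm) volume in litres (> 0).
#' @return Concentration in mM (vectorised).
#' @examples
#' intracellular_concentration(83, 3.49e-9)   # ~23.8 mM
#' @export
intracellular_concentration <- function(content_pmol, cell_volume_l) {
  if (any(!is.finite(cell_volume_l)) || any(cell_volume_l <= 0)) {
    stop("cell_volume_l must be positive", call. = FALSE)
  }
  if (any(content_pmol < 0)) {
    stop("content must be non-negative", call. = FALSE)
  }
  content_pmol * 1e-9 / cell_volume_l
}

#' Quantify phosphate extracts per sample
#'
#' Converts a table of extraction samples to per-sample contents and
#' intracellular concentrations, joining per-species mean cell volumes.
#'
#' @param samples Data frame with columns `sample_id`, `species`,
#'   `n_individuals`, `conc_umol_l`, optionally `extract_volume_l`
#'   (default 0.003) and `region`.
#' @param volumes Data frame with columns `species` and
#'   `mean_cell_volume_l` (e.g. from [summarize_biovolume()] or the
#'   shipped [foram_content_library()]). Optional: without it only
#'   contents are computed.
#' @param blanks,blank_correction Passed to [blank_correct()].
#' @param detection_limit Detection limit in umol/l.
#' @return A tibble: one row per sample with `content_pmol_ind`,
#'   `conc_mM` (NA when no volume is known) and `below_detection`.
#' @export
quantify_phosphate <- function(samples, volumes = NULL, blanks = NULL,
                               blank_correction = FALSE,
                               detection_limit = 0.004) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "species", "n_individuals", "conc_umol_l")
                %in% names(samples)))
  if (!("extract_volume_l" %in% names(samples))) {
    samples$extract_volume_l <- 0.003
  }
  bc <- blank_correct(samples$conc_umol_l, blanks = blanks,
                      correct = blank_correction,
                      detection_limit = detection_limit)
  out <- samples |>
    dplyr::mutate(
      corrected_umol_l = bc$corrected_umol_l,
      below_detection = bc$below_detection,
      content_pmol_ind = individual_content(
        .data$corrected_umol_l, .data$n_individuals, .data$extract_volume_l)
    )
  if (!is.null(volumes)) {
    stopifnot(all(c("species", "mean_cell_volume_l") %in% names(volumes)))
    if (any(volumes$mean_cell_volume_l <= 0, na.rm = TRUE)) {
      stop("cell volumes must be positive", call. = FALSE)
    }
    out <- out |>
      dplyr::left_join(
        dplyr::select(volumes, "species", "mean_cell_volume_l"),
        by = "species") |>
      dplyr::mutate(conc_mM = ifelse(
        is.na(.data$mean_cell_volume_l), NA_real_,
        .data$content_pmol_ind * 1e-9 / .data$mean_cell_volume_l))
  } else {
    out$conc_mM <- NA_real_
  }
  tibble::as_tibble(out)
}

#' Summarise per-sample contents and concentrations by species
#'
#' Means and standard deviations are taken over per-sample values (mean
#' of ratios, not ratio of means); sd uses the n-1 denominator and is
#' `NA` for single-sample species.
#'
#' @param quantified Output of [quantify_phosphate()].
#' @return A tibble with one row per species: `n_samples`,
#'   `mean_content_pmol`, `sd_content_pmol`, `mean_conc_mM`,
#'   `sd_conc_mM`.
#' @export
summarize_phosphate <- function(quantified) {
  stopifnot(is.data.frame(quantified), nrow(quantified) > 0,
            all(c("species", "content_pmol_ind") %in% names(quantified)))
  if (!("conc_mM" %in% names(quantified))) quantified$conc_mM <- NA_real_
  quantified |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_content_pmol = mean(.data$content_pmol_ind),
      sd_content_pmol = ifelse(dplyr::n() > 1,
                               stats::sd(.data$content_pmol_ind), NA_real_),
      mean_conc_mM = mean(.data$conc_mM),
      sd_conc_mM = ifelse(dplyr::n() > 1 && !anyNA(.data$conc_mM),
                          stats::sd(.data$conc_mM), NA_real_),
      .groups = "drop"
    )
}
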