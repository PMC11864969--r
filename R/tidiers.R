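#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a regional budget
#'
#' One row per budget component (stock, total, buffer), with estimate
#' and standard error.
#'
#' @param x A `region_budget` from [buffer_budget()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `unit`.
#' @method tidy region_budget
#' @export
tidy.region_budget <- function(x, ...) {
  tibble::tibble(
    term = c("mean_stock", "total_stock", "buffer_days"),
    estimate = c(x$mean_stock_g_m2, x$total_stock_t, x$buffer_days),
    std.error = c(x$se_stock_g_m2, x$se_total_stock_t, x$se_buffer_days),
    unit = c("g m-2", "t", "days")
  )
}

#' Glance at a regional budget
#'
#' @param x A `region_budget`.
#' @param ... Unused.
#' @return A one-row tibble with the headline figures.
#' @method glance region_budget
#' @export
glance.region_budget <- function(x, ...) {
  tibble::tibble(
    total_stock_t = x$total_stock_t,
    buffer_days = x$buffer_days,
    runoff_t_yr = x$runoff_t_yr,
    area_m2 = x$area_m2
  )
}

#' Tidy a similarity transform
#'
#' @param x A `similarity_transform` from [register_similarity()].
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` for scale, rotation and
#'   translation.
#' @method tidy similarity_transform
#' @export
tidy.similarity_transform <- function(x, ...) {
  tibble::tibble(
    term = c("scale", "rotation_deg", "tx", "ty"),
    estimate = c(x$scale, x$rotation_deg, x$translation[1], x$translation[2])
  )
}

#' @rdname tidy.similarity_transform
#' @method glance similarity_transform
#' @export
glance.similarity_transform <- function(x, ...) {
  tibble::tibble(rms_residual = x$rms_residual, n_points = x$n_points)
}

#' Tidy a ratio map into long pixel form
#'
#' @param x A `ratio_map`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `value` (NA on masked pixels).
#' @method tidy ratio_map
#' @export
tidy.ratio_map <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}
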