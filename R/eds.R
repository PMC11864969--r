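#' Bundle co-registered EDS element count maps
#'
#' An EDS acquisition yields one X-ray count image per mapped element
#' plus a total counts-per-second (CPS) image. All maps must share one
#' shape and hold non-negative counts. Pixels where the summed element
#' counts exceed CPS are physically inconsistent (the background cannot
#' be negative); they are masked, not silently clipped.
#'
#' @param count_maps Named list of numeric matrices, one per element
#'   (names are element labels, e.g. `"P"`, `"Ca"`).
#' @param cps Numeric matrix of total counts per pixel, same shape.
#' @return An `eds_stack` object (list with `count_maps`, `cps`,
#'   `elements`, `shape`, `valid` mask).
#' @export
eds_stack <- function(count_maps, cps) {
  if (is.null(names(count_maps)) || any(!nzchar(names(count_maps)))) {
    stop("count_maps must be a named list of element matrices", call. = FALSE)
  }
  shp <- dim(cps)
  for (el in names(count_maps)) {
    m <- count_maps[[el]]
    if (!is.matrix(m) || !identical(dim(m), shp)) {
      stop("shape mismatch: map '", el, "' does not match the CPS map",
           call. = FALSE)
    }
    if (any(m < 0, na.rm = TRUE)) {
      stop("negative counts in map '", el, "'", call. = FALSE)
    }
  }
  if (any(cps < 0, na.rm = TRUE)) stop("negative CPS values", call. = FALSE)
  total <- Reduce(`+`, count_maps)
  valid <- is.finite(cps) & (cps >= total)
  structure(
    list(count_maps = count_maps, cps = cps,
         elements = names(count_maps), shape = shp, valid = valid),
    class = "eds_stack"
  )
}

#' @export
print.eds_stack <- function(x, ...) {
  cat("<eds_stack> ", x$shape[1], "x", x$shape[2], " px, elements: ",
      paste(x$elements, collapse = ", "),
      sprintf(" (%.1f%% valid)\n", 100 * mean(x$valid)), sep = "")
  invisible(x)
}

#' Per-pixel intensity-to-noise ratio map
#'
#' The raw count of an element mixes its characteristic X-ray signal
#' with a position-dependent bremsstrahlung background. Assuming the
#' spectral shape of the background is the same at every position, the
#' background under the element's peak is proportional to the
#' background outside all characteristic peaks, estimated per pixel as
#' CPS minus the summed element counts. The intensity-to-noise ratio
#'
#'   `R(m,n) = I_i(m,n) / (CPS(m,n) - sum_i I_i(m,n))`
#'
#' equals `S_i/B_i + 1` under that assumption, so enrichments of a
#' minor element stand out above a flat `R = const` background.
#'
#' @param stack An [eds_stack()].
#' @param element Element label to transform.
#' @param epsilon Minimum admissible denominator in counts (> 0,
#'   default 1); pixels below it are masked.
#' @param denominator `"all"` (default) subtracts every mapped element
#'   from CPS; `"exclude_target"` leaves the target element's own counts
#'   in the denominator.
#' @return A `ratio_map` object: list with `values` (matrix, `NA` on
#'   masked pixels), `mask` (TRUE = valid), `element`, `epsilon`.
#' @export
ratio_map <- function(stack, element, epsilon = 1,
                      denominator = c("all", "exclude_target")) {
  stopifnot(inherits(stack, "eds_stack"))
  denominator <- match.arg(denominator)
  if (!(element %in% stack$elements)) {
    stop("element '", element, "' not in stack (have: ",
         paste(stack$elements, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.finite(epsilon) || epsilon <= 0) {
    stop("epsilon must be positive", call. = FALSE)
  }
  subtract <- if (denominator == "all") stack$elements
              else setdiff(stack$elements, element)
  denom <- stack$cps - Reduce(`+`, stack$count_maps[subtract])
  mask <- stack$valid & is.finite(denom) & (denom >= epsilon)
  values <- stack$count_maps[[element]] / denom
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, element = element,
                 epsilon = epsilon),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat("<ratio_map> element ", x$element, ", ", nrow(x$values), "x",
      ncol(x$values), " px, ",
      sprintf("%.1f%% valid, range [%.3g, %.3g]\n", 100 * mean(x$mask),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)),
      sep = "")
  invisible(x)
}

#' Mask-aware median filter
#'
#' Replaces each valid pixel by the median of the valid pixels in its
#' `(2 radius + 1)^2` neighbourhood. The window is clipped at image
#' borders (no padding) and masked pixels are excluded from the window;
#' the mask itself is preserved. One-pixel (radius 1) median filtering
#' smooths elemental distribution maps so that enriched ultrastructures
#' stand out from single-pixel count noise.
#'
#' @param map A `ratio_map` (or plain numeric matrix, filtered with an
#'   all-valid mask).
#' @param radius Window radius in pixels (>= 1, default 1).
#' @return Same type as the input, with filtered values.
#' @export
median_filter <- function(map, radius = 1) {
  if (radius < 1 || radius != round(radius)) {
    stop("radius must be a positive integer", call. = FALSE)
  }
  plain <- !inherits(map, "ratio_map")
  values <- if (plain) map else map$values
  nr <- nrow(values); nc <- ncol(values)
  offsets <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  stackarr <- array(NA_real_, dim = c(nr, nc, nrow(offsets)))
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets$dr[k]; dc <- offsets$dc[k]
    src_r <- seq_len(nr) + dr
    src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    stackarr[which(ok_r), which(ok_c), k] <-
      values[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  filt <- apply(stackarr, c(1, 2), stats::median, na.rm = TRUE)
  filt[is.nan(filt)] <- NA_real_
  if (plain) return(filt)
  filt[!map$mask] <- NA_real_
  out <- map
  out$values <- filt
  out
}

# Fixed 16-entry colour ramp (dark blue -> cyan -> green -> yellow ->
# red -> white), in the spirit of ImageJ's "16 colors" LUT.
default_lut16 <- function() {
  grDevices::colorRampPalette(
    c("#000080", "#0000FF", "#0080FF", "#00FFFF", "#00FF80", "#00FF00",
      "#80FF00", "#FFFF00", "#FF8000", "#FF0000", "#FF0080", "#FFFFFF")
  )(16)
}

#' Quantize a ratio map into discrete colour classes
#'
#' Bins the valid value range linearly into `n_colours` classes for
#' display under a fixed look-up table. The underlying values are not
#' modified; only the rendering is discretised. Masked pixels get class
#' `NA` (rendered transparent/black).
#'
#' @param map A `ratio_map` or numeric matrix.
#' @param n_colours Number of classes (default 16).
#' @param range Optional `c(lo, hi)` absolute range for cross-map
#'   comparability; default is the valid-pixel range.
#' @param palette Character vector of `n_colours` colours.
#' @return A `lut_image`: list with `classes` (integer matrix in
#'   `1..n_colours`), `breaks`, `palette` and the untouched `values`.
#' @export
lut_quantize <- function(map, n_colours = 16, range = NULL,
                         palette = default_lut16()) {
  values <- if (inherits(map, "ratio_map")) map$values else map
  if (all(is.na(values))) {
    stop("cannot quantize an all-masked map", call. = FALSE)
  }
  stopifnot(n_colours >= 2, length(palette) >= n_colours)
  if (is.null(range)) range <- base::range(values, na.rm = TRUE)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    classes <- ifelse(is.na(values), NA_integer_, 1L)
    breaks <- c(lo, lo)
  } else {
    breaks <- seq(lo, hi, length.out = n_colours + 1)
    idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    classes <- ifelse(is.na(values), NA_integer_, as.integer(idx))
  }
  dim(classes) <- dim(values)
  structure(list(classes = classes, breaks = breaks,
                 palette = palette[seq_len(n_colours)], values = values),
            class = "lut_image")
}

#' Render a quantized map to an RGB array
#'
#' @param lut A `lut_image` from [lut_quantize()].
#' @param na_colour Colour for masked pixels (default black).
#' @return Numeric array `rows x cols x 3` in `[0, 1]`.
#' @export
render_lut <- function(lut, na_colour = "#000000") {
  stopifnot(inherits(lut, "lut_image"))
  cls <- lut$classes
  cols <- lut$palette[cls]
  cols[is.na(cls)] <- na_colour
  rgb <- grDevices::col2rgb(cols) / 255
  array(t(rgb), dim = c(dim(cls), 3))
}

#' Least-squares similarity transform from control points
#'
#' Fits scale, rotation and translation (no shear or warping: 4 degrees
#' of freedom) mapping moving-image control points onto fixed-image
#' points, by linear least squares. Used to colocalize an EDS elemental
#' map with the SEM image of the same region, typically via the calcium
#' map of the calcitic test.
#'
#' Coordinates are pixel units with x = column and y = row (row 0 at
#' the top of the image); rotation is measured in the (x, y) plane.
#'
#' @param points Data frame with columns `x_mov`, `y_mov`, `x_fix`,
#'   `y_fix`; at least 2 non-coincident pairs.
#' @return A `similarity_transform`: list with `scale`, `rotation_deg`,
#'   `translation` (length-2), `rms_residual`, `n_points`.
#' @export
register_similarity <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("x_mov", "y_mov", "x_fix", "y_fix") %in% names(points)))
  if (nrow(points) < 2) {
    stop("need at least 2 control-point pairs", call. = FALSE)
  }
  z_mov <- complex(real = points$x_mov, imaginary = points$y_mov)
  z_fix <- complex(real = points$x_fix, imaginary = points$y_fix)
  if (max(Mod(z_mov - mean(z_mov))) < .Machine$double.eps^0.5) {
    stop("control points are coincident; geometry is degenerate",
         call. = FALSE)
  }
  # similarity = complex-linear map z_fix ~ a * z_mov + b
  zc <- z_mov - mean(z_mov)
  a <- sum(Conj(zc) * (z_fix - mean(z_fix))) / sum(Conj(zc) * zc)
  b <- mean(z_fix) - a * mean(z_mov)
  resid <- z_fix - (a * z_mov + b)
  structure(
    list(scale = Mod(a),
         rotation_deg = Arg(a) * 180 / pi,
         translation = c(Re(b), Im(b)),
         rms_residual = sqrt(mean(Mod(resid)^2)),
         n_points = nrow(points)),
    class = "similarity_transform"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> scale %.4g, rotation %.2f deg, translation (%.2f, %.2f), RMS %.3g px (n = %d)\n",
    x$scale, x$rotation_deg, x$translation[1], x$translation[2],
    x$rms_residual, x$n_points))
  invisible(x)
}

# forward map of (x, y) points under a similarity transform
transform_points <- function(tf, x, y) {
  a <- complex(modulus = tf$scale, argument = tf$rotation_deg * pi / 180)
  z <- a * complex(real = x, imaginary = y) +
    complex(real = tf$translation[1], imaginary = tf$translation[2])
  list(x = Re(z), y = Im(z))
}

#' Resample a moving map onto the fixed grid
#'
#' Applies a fitted similarity transform by inverse mapping with
#' bilinear interpolation: each fixed-grid pixel centre is pulled back
#' into moving-image coordinates and interpolated there. Pixels that
#' fall outside the moving image (or next to masked values) are `NA`.
#'
#' @param moving Numeric matrix (moving image).
#' @param tf A `similarity_transform` mapping moving to fixed
#'   coordinates.
#' @param output_dim `c(rows, cols)` of the fixed grid; default the
#'   moving image's own shape.
#' @return Numeric matrix of the resampled image.
#' @export
apply_similarity <- function(moving, tf, output_dim = dim(moving)) {
  stopifnot(inherits(tf, "similarity_transform"), is.matrix(moving))
  a <- complex(modulus = tf$scale, argument = tf$rotation_deg * pi / 180)
  b <- complex(real = tf$translation[1], imaginary = tf$translation[2])
  nr <- output_dim[1]; nc <- output_dim[2]
  # fixed-grid pixel centres, x = column index, y = row index (0-based)
  grid <- expand.grid(x = seq_len(nc) - 1, y = seq_len(nr) - 1)
  z <- (complex(real = grid$x, imaginary = grid$y) - b) / a
  xs <- Re(z); ys <- Im(z)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  get_px <- function(r0, c0) {
    ok <- r0 >= 0 & r0 <= nrow(moving) - 1 & c0 >= 0 & c0 <= ncol(moving) - 1
    v <- rep(NA_real_, length(r0))
    v[ok] <- moving[cbind(r0[ok] + 1, c0[ok] + 1)]
    v
  }
  v00 <- get_px(y0, x0);     v01 <- get_px(y0, x0 + 1)
  v10 <- get_px(y0 + 1, x0); v11 <- get_px(y0 + 1, x0 + 1)
  # zero-weight corners must not poison exact-integer coordinates
  wmul <- function(w, v) ifelse(w == 0, 0, w * v)
  vals <- wmul(1 - fy, wmul(1 - fx, v00) + wmul(fx, v01)) +
    wmul(fy, wmul(1 - fx, v10) + wmul(fx, v11))
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Alpha-blend an element map over a base image
#'
#' @param base Grayscale matrix in `[0, 1]` or RGB array
#'   (`rows x cols x 3`).
#' @param lut A `lut_image` (from [lut_quantize()]) co-registered with
#'   the base.
#' @param alpha Blend weight of the element map in `[0, 1]`; masked
#'   pixels always show the base alone.
#' @return RGB array `rows x cols x 3`.
#' @export
overlay <- function(base, lut, alpha = 0.5) {
  stopifnot(inherits(lut, "lut_image"), alpha >= 0, alpha <= 1)
  if (is.matrix(base)) {
    base <- array(rep(base, 3), dim = c(dim(base), 3))
  }
  if (!identical(dim(base)[1:2], dim(lut$classes))) {
    stop("base image and element map shapes differ", call. = FALSE)
  }
  top <- render_lut(lut)
  masked <- is.na(lut$classes)
  out <- (1 - alpha) * base + alpha * top
  for (ch in 1:3) {
    plane_out <- out[, , ch]; plane_base <- base[, , ch]
    plane_out[masked] <- plane_base[masked]
    out[, , ch] <- plane_out
  }
  out
}

#' Read an EDS stack from a directory of map files
#'
#' Expects one file per element named `<Element>.<ext>` plus a
#' `cps.<ext>` file, where `<ext>` is `tif`/`tiff` (via the tiff
#' package) or `txt`/`tsv`/`csv` (delimited numeric matrices).
#'
#' @param path Directory containing the map files.
#' @param elements Optional character vector restricting which elements
#'   to read; default all non-CPS files found.
#' @return An [eds_stack()].
#' @export
read_eds_stack <- function(path, elements = NULL) {
  files <- list.files(path, pattern = "\\.(tiff?|txt|tsv|csv)$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no map files found in ", path, call. = FALSE)
  labels <- sub("\\.[^.]+$", "", basename(files))
  cps_i <- which(tolower(labels) == "cps")
  if (length(cps_i) != 1) {
    stop("need exactly one cps map file in ", path, call. = FALSE)
  }
  read_one <- function(f) {
    if (grepl("\\.tiff?$", f)) {
      m <- tiff::readTIFF(f, as.is = TRUE)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    } else {
      sep <- if (grepl("\\.csv$", f)) "," else ""
      as.matrix(utils::read.table(f, sep = sep, header = FALSE))
    }
  }
  cps <- unname(read_one(files[cps_i]))
  el_files <- files[-cps_i]; el_labels <- labels[-cps_i]
  if (!is.null(elements)) {
    keep <- el_labels %in% elements
    el_files <- el_files[keep]; el_labels <- el_labels[keep]
  }
  maps <- lapply(el_files, function(f) unname(read_one(f)))
  names(maps) <- el_labels
  eds_stack(maps, cps)
}

#' Write a ratio map as a 32-bit TIFF
#'
#' TIFF grey values are stored normalized to `[0, 1]`, so the map is
#' written as `values / scale` with `scale` defaulting to the maximum
#' valid ratio; the scale is also written to a `<path>.scale.txt`
#' sidecar so [read_ratio_tiff()] can restore absolute ratios. Masked
#' pixels are written as 0.
#'
#' @param map A `ratio_map`.
#' @param path Output file path.
#' @param scale Normalization constant; defaults to the maximum valid
#'   value.
#' @return The scale used, invisibly.
#' @export
write_ratio_tiff <- function(map, path, scale = NULL) {
  stopifnot(inherits(map, "ratio_map"))
  v <- map$values
  v[is.na(v)] <- 0
  if (is.null(scale)) scale <- max(v)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32)
  writeLines(format(scale, digits = 17), paste0(path, ".scale.txt"))
  invisible(scale)
}

#' Read a ratio map written by [write_ratio_tiff()]
#'
#' @param path TIFF file path; the scale is read from the
#'   `<path>.scale.txt` sidecar unless given.
#' @param scale Normalization constant used at write time.
#' @return Numeric matrix of absolute ratio values.
#' @export
read_ratio_tiff <- function(path, scale = NULL) {
  if (is.null(scale)) {
    sidecar <- paste0(path, ".scale.txt")
    scale <- if (file.exists(sidecar)) as.numeric(readLines(sidecar)) else 1
  }
  tiff::readTIFF(path) * scale
}
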