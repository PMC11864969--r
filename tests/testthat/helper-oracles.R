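# Independent oracles used across the suite. Each recomputes a quantity
# by a different route than the package (numerical integration, brute
# force loops, closed-form linear algebra).

# Volume by numerical integration of elliptical cross-sections along
# one axis. Axes are full lengths in um; the result is in litres.
oracle_volume_l <- function(shape_kind, axes) {
  ax <- as.list(axes)
  area <- switch(shape_kind,
    sphere = {
      d <- ax$diameter
      list(f = function(z) pi * ((d / 2)^2 - z^2), lower = -d / 2, upper = d / 2)
    },
    prolate_spheroid = {
      l <- ax$major; w <- ax$minor
      list(f = function(z) pi * (w / 2)^2 * (1 - (2 * z / l)^2),
           lower = -l / 2, upper = l / 2)
    },
    oblate_spheroid = {
      d <- ax$major; t <- ax$minor
      list(f = function(z) pi * (d / 2)^2 * (1 - (2 * z / t)^2),
           lower = -t / 2, upper = t / 2)
    },
    triaxial_ellipsoid = {
      a <- ax$major; b <- ax$minor; c <- ax$height
      list(f = function(z) pi * (a / 2) * (b / 2) * (1 - (2 * z / c)^2),
           lower = -c / 2, upper = c / 2)
    },
    elliptic_cone = {
      a <- ax$major; b <- ax$minor; h <- ax$height
      list(f = function(z) pi * (a / 2) * (b / 2) * (1 - z / h)^2,
           lower = 0, upper = h)
    },
    elliptic_cylinder = {
      a <- ax$major; b <- ax$minor; h <- ax$height
      list(f = function(z) rep(pi * (a / 2) * (b / 2), length(z)),
           lower = 0, upper = h)
    },
    half_ellipsoid = {
      a <- ax$major; b <- ax$minor; c <- ax$height
      list(f = function(z) pi * (a / 2) * (b / 2) * (1 - (2 * z / c)^2),
           lower = 0, upper = c / 2)
    }
  )
  stats::integrate(area$f, area$lower, area$upper,
                   rel.tol = 1e-10)$value * 1e-15
}

# Brute-force mask-aware median filter: per-pixel loop over the
# clipped window, valid neighbours only.
oracle_median_filter <- function(values, radius = 1) {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      win <- values[max(1, r - radius):min(nr, r + radius),
                    max(1, c - radius):min(nc, c + radius)]
      win <- win[!is.na(win)]
      if (length(win) > 0) out[r, c] <- stats::median(win)
    }
  }
  out
}

# Closed-form 2D Umeyama/Procrustes similarity solution via SVD
# (rotation + isotropic scale + translation, no reflection).
oracle_similarity <- function(points) {
  P <- cbind(points$x_mov, points$y_mov)
  Q <- cbind(points$x_fix, points$y_fix)
  mp <- colMeans(P); mq <- colMeans(Q)
  Pc <- sweep(P, 2, mp); Qc <- sweep(Q, 2, mq)
  S <- crossprod(Qc, Pc) / nrow(P)
  sv <- svd(S)
  D <- diag(2)
  if (det(sv$u %*% t(sv$v)) < 0) D[2, 2] <- -1
  R <- sv$u %*% D %*% t(sv$v)
  var_p <- mean(rowSums(Pc^2))
  s <- sum(diag(D %*% diag(sv$d))) / var_p
  t_vec <- mq - s * as.vector(R %*% mp)
  list(scale = s,
       rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       translation = t_vec)
}

# Brute-force assemblage stock: plain row loop, manual genus imputation.
oracle_station_stock <- function(rows, library, molar_mass = 95) {
  usable <- library[!library$excluded & !is.na(library$content_pmol), ]
  genus_of <- function(s) strsplit(trimws(s), "\\s+")[[1]][1]
  total_pmol_m2 <- 0
  for (i in seq_len(nrow(rows))) {
    sp <- rows$species[i]
    hit <- usable$content_pmol[usable$species == sp]
    if (length(hit) > 0) {
      content <- mean(hit)
    } else {
      cong <- usable$content_pmol[
        vapply(usable$species, genus_of, "") == genus_of(sp)]
      if (length(cong) == 0) next
      content <- mean(cong)
    }
    total_pmol_m2 <- total_pmol_m2 + rows$abundance[i] * content
  }
  mmol <- total_pmol_m2 * 1e-9
  c(stock_mmol_m2 = mmol, stock_g_m2 = mmol * 1e-3 * molar_mass)
}

random_axes <- function(shape_kind) {
  need <- phosfor::required_axes(shape_kind)
  ax <- sort(stats::runif(length(need), 20, 400), decreasing = TRUE)
  stats::setNames(ax, need)
}
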