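make_stack <- function(I_P, I_Ca, cps) {
  eds_stack(list(P = I_P, Ca = I_Ca), cps)
}

test_that("stack construction validates shapes and masks CPS violations", {
  m <- matrix(10, 4, 4)
  expect_error(eds_stack(list(P = m, Ca = matrix(1, 3, 3)), m), "shape")
  expect_error(eds_stack(list(P = -m), m), "negative")
  expect_error(eds_stack(list(matrix(1, 2, 2)), matrix(1, 2, 2)), "named")
  # summed element counts above CPS are masked, not clipped
  cps <- matrix(30, 4, 4); cps[1, 1] <- 5
  s <- make_stack(m, m, cps)
  expect_false(s$valid[1, 1])
  expect_true(all(s$valid[-1]))
  expect_equal(s$count_maps$P[1, 1], 10)  # counts untouched
})

test_that("ratio map implements counts over out-of-peak background", {
  # single pixel worked example: I_P = 30, sum I = 80, CPS = 130
  s <- make_stack(matrix(30, 2, 2), matrix(50, 2, 2), matrix(130, 2, 2))
  r <- ratio_map(s, "P")
  expect_equal(r$values, matrix(30 / 50, 2, 2))
  # denominator at zero (CPS == sum I) is masked
  s2 <- make_stack(matrix(30, 2, 2), matrix(50, 2, 2), matrix(80, 2, 2))
  r2 <- ratio_map(s2, "P")
  expect_true(all(is.na(r2$values)))
  expect_false(any(r2$mask))
  expect_error(ratio_map(s, "Fe"), "not in stack")
  expect_error(ratio_map(s, "P", epsilon = 0), "positive")
  # exclude-target denominator keeps the element's own counts in CPS
  r3 <- ratio_map(s, "P", denominator = "exclude_target")
  expect_equal(r3$values, matrix(30 / 80, 2, 2))
})

test_that("ratio map is scale invariant and monotone in the signal", {
  set.seed(21)
  I_P <- matrix(rpois(64, 40), 8, 8)
  I_Ca <- matrix(rpois(64, 100), 8, 8)
  cps <- I_P + I_Ca + matrix(rpois(64, 60), 8, 8)
  s <- make_stack(I_P, I_Ca, cps)
  r <- ratio_map(s, "P")
  for (k in c(2, 7.5)) {
    sk <- make_stack(I_P * k, I_Ca * k, cps * k)
    rk <- ratio_map(sk, "P", epsilon = 1e-9)
    expect_equal(rk$values[r$mask], r$values[r$mask])
  }
  # increasing I_P at fixed denominator increases R
  s_up <- make_stack(I_P + 5, I_Ca, cps + 5)
  r_up <- ratio_map(s_up, "P")
  ok <- r$mask & r_up$mask
  expect_true(all(r_up$values[ok] > r$values[ok]))
})

test_that("phantom with known signal and background gives analytic R", {
  ph <- gen_eds_phantom(shape = c(32, 32), poisson = FALSE, seed = 2)
  r <- ratio_map(ph$stack, "P", epsilon = 1e-6)
  expect_true(all(r$mask))
  expect_equal(r$values, ph$truth$R_analytic, tolerance = 1e-12)
  # R = S/B + 1 inside and outside the enrichment discs
  inside <- ph$truth$disc_mask
  expect_equal(unique(round(r$values[!inside], 10)),
               ph$truth$signal_frac + 1)
  expect_equal(unique(round(r$values[inside], 10)),
               ph$truth$signal_frac * ph$truth$contrast + 1)
})

test_that("median filter equals the brute-force oracle", {
  set.seed(8)
  for (radius in c(1, 2)) {
    v <- matrix(runif(30 * 20), 30, 20)
    v[sample(600, 40)] <- NA  # masked pixels
    s <- make_stack(matrix(1, 30, 20), matrix(1, 30, 20),
                    matrix(10, 30, 20))
    r <- ratio_map(s, "P")
    r$values <- v
    r$mask <- !is.na(v)
    out <- median_filter(r, radius = radius)
    oracle <- oracle_median_filter(v, radius = radius)
    oracle[!r$mask] <- NA
    expect_equal(out$values, oracle)
  }
})

test_that("median filter: constants unchanged, salt pixel removed", {
  flat <- matrix(2.5, 9, 9)
  expect_equal(median_filter(flat), flat)
  salt <- flat; salt[5, 5] <- 50
  expect_equal(median_filter(salt), flat)
  expect_error(median_filter(flat, radius = 0), "positive integer")
})

test_that("16-colour quantization bins linearly and is idempotent", {
  v <- matrix(0:15, 4, 4)
  q <- lut_quantize(v)
  expect_equal(sort(unique(as.vector(q$classes))), 1:16)
  expect_equal(q$values, v)  # greys untouched
  # constant map collapses to one class
  qc <- lut_quantize(matrix(3, 2, 2))
  expect_equal(unique(as.vector(qc$classes)), 1L)
  # re-quantizing the class image reproduces the classes
  q2 <- lut_quantize(q$classes * 1.0)
  expect_equal(q2$classes, q$classes)
  # masked pixels stay NA and render as the NA colour
  v[1, 1] <- NA
  qm <- lut_quantize(v)
  expect_true(is.na(qm$classes[1, 1]))
  img <- render_lut(qm)
  expect_equal(img[1, 1, ], c(0, 0, 0))
  expect_error(lut_quantize(matrix(NA_real_, 2, 2)), "all-masked")
})

test_that("similarity registration recovers exact and noisy transforms", {
  pts <- data.frame(x_mov = c(0, 1, 0, 2), y_mov = c(0, 0, 1, 1))
  # identity
  tf <- register_similarity(cbind(pts, x_fix = pts$x_mov, y_fix = pts$y_mov))
  expect_equal(tf$scale, 1)
  expect_equal(tf$rotation_deg, 0)
  expect_equal(tf$translation, c(0, 0))
  expect_equal(tf$rms_residual, 0)
  # rotation by 90 degrees and scale 2: (x, y) -> (-2y, 2x)
  tf2 <- register_similarity(cbind(pts, x_fix = -2 * pts$y_mov,
                                   y_fix = 2 * pts$x_mov))
  expect_equal(tf2$scale, 2)
  expect_equal(tf2$rotation_deg, 90)
  expect_equal(tf2$rms_residual, 0, tolerance = 1e-12)
  # matches the closed-form Procrustes oracle on noisy pairs
  set.seed(13)
  for (rep in 1:10) {
    n <- 5
    mov <- data.frame(x_mov = runif(n, 0, 100), y_mov = runif(n, 0, 100))
    s_true <- runif(1, 0.5, 2); th <- runif(1, -pi, pi)
    tr <- runif(2, -20, 20)
    fx <- s_true * (cos(th) * mov$x_mov - sin(th) * mov$y_mov) + tr[1] +
      rnorm(n, 0, 0.5)
    fy <- s_true * (sin(th) * mov$x_mov + cos(th) * mov$y_mov) + tr[2] +
      rnorm(n, 0, 0.5)
    p <- cbind(mov, x_fix = fx, y_fix = fy)
    tf <- register_similarity(p)
    or <- oracle_similarity(p)
    expect_equal(tf$scale, or$scale, tolerance = 1e-8)
    expect_equal(tf$rotation_deg, or$rotation_deg, tolerance = 1e-6)
    expect_equal(tf$translation, or$translation, tolerance = 1e-6)
    # and stays within the jitter of the generating transform
    expect_equal(tf$scale, s_true, tolerance = 0.05)
  }
  expect_error(register_similarity(
    data.frame(x_mov = c(1, 1), y_mov = c(2, 2), x_fix = c(0, 1),
               y_fix = c(0, 1))), "coincident")
  expect_error(register_similarity(
    data.frame(x_mov = 1, y_mov = 2, x_fix = 0, y_fix = 0)), "at least 2")
})

test_that("resampling under the identity returns interior pixels unchanged", {
  set.seed(4)
  img <- matrix(runif(100), 10, 10)
  tf <- register_similarity(data.frame(
    x_mov = c(0, 9, 0, 9), y_mov = c(0, 0, 9, 9),
    x_fix = c(0, 9, 0, 9), y_fix = c(0, 0, 9, 9)))
  out <- apply_similarity(img, tf)
  expect_equal(out, img)
  # translation by one column shifts content
  tf_shift <- register_similarity(data.frame(
    x_mov = c(0, 9, 0, 9), y_mov = c(0, 0, 9, 9),
    x_fix = c(1, 10, 1, 10), y_fix = c(0, 0, 9, 9)))
  out2 <- apply_similarity(img, tf_shift)
  expect_equal(out2[, 2:10], img[, 1:9])
  expect_true(all(is.na(out2[, 1])))
})

test_that("overlay blends linearly and respects the mask", {
  base <- matrix(0.5, 4, 4)
  vals <- matrix(seq(0, 1, length.out = 16), 4, 4)
  vals[2, 2] <- NA
  q <- lut_quantize(vals)
  img0 <- overlay(base, q, alpha = 0)
  expect_equal(img0, array(0.5, c(4, 4, 3)))
  img1 <- overlay(base, q, alpha = 1)
  top <- render_lut(q)
  expect_equal(img1[4, 4, ], top[4, 4, ])
  # masked pixel shows the base at any alpha
  expect_equal(img1[2, 2, ], c(0.5, 0.5, 0.5))
  imgh <- overlay(base, q, alpha = 0.25)
  expect_equal(imgh[1, 1, ], 0.75 * c(0.5, 0.5, 0.5) + 0.25 * top[1, 1, ])
  expect_error(overlay(matrix(0, 2, 2), q), "differ")
})

test_that("phantom contrast is recovered within Poisson error across seeds", {
  # (mean R inside - 1) / (mean R outside - 1) estimates the injected
  # signal contrast; across seeds the estimator should straddle the
  # truth without systematic bias (sign test) and with small spread
  # regional R is taken as the denominator-weighted mean of the pixel
  # ratios (equivalently: summed counts over summed background), which
  # is free of the O(1/counts) Jensen bias of a plain pixel mean
  seeds <- 1:50
  contrast <- 4
  detected <- logical(length(seeds))
  est <- vapply(seeds, function(s) {
    ph <- gen_eds_phantom(shape = c(48, 48), contrast = contrast,
                          poisson = TRUE, seed = s)
    r <- ratio_map(ph$stack, "P")
    denom <- ph$stack$cps - Reduce(`+`, ph$stack$count_maps)
    inside <- ph$truth$disc_mask & r$mask
    outside <- !ph$truth$disc_mask & r$mask
    detected[s] <<- mean(r$values[inside]) > mean(r$values[outside])
    r_in <- stats::weighted.mean(r$values[inside], denom[inside])
    r_out <- stats::weighted.mean(r$values[outside], denom[outside])
    (r_in - 1) / (r_out - 1)
  }, numeric(1))
  expect_gt(stats::binom.test(sum(est > contrast), length(est))$p.value,
            1e-3)
  expect_lt(abs(mean(est) - contrast) / contrast, 0.05)
  # and the enrichment stands out of the background in every phantom
  expect_true(all(detected))
  expect_true(all(est > 1))
})
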