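test_that("content lookup resolves exact, genus-mean and excluded species", {
  lib <- tibble::tibble(
    species = c("Bolivina alpha", "Bolivina beta", "Ammonia gamma",
                "Textularia culta"),
    content_pmol = c(40, 60, 412, 999),
    excluded = c(FALSE, FALSE, FALSE, TRUE)
  )
  out <- lookup_content(
    c("Bolivina alpha", "Bolivina incognita", "Elphidium ignotum",
      "Textularia culta"), lib)
  expect_equal(out$content_pmol, c(40, 50, NA, NA))
  expect_equal(out$provenance,
               c("measured", "genus_mean", "excluded", "excluded"))
  expect_error(lookup_content(c("", "Bolivina alpha"), lib), "non-empty")
})

test_that("duplicate library entries for one species average before lookup", {
  # two regional entries for the same species (as in the reference
  # library for Globobulimina affinis)
  lib <- foram_content_library()
  ga <- lookup_content("Globobulimina affinis", lib)
  expect_equal(ga$content_pmol, mean(c(1078, 600)))
  # A. veneta is excluded by default, so Ammonia congener lookups use
  # only environmental entries
  av <- lookup_content("Ammonia veneta", lib)
  expect_equal(av$provenance, "genus_mean")
  expect_equal(av$content_pmol, 412)
})

test_that("station stocks match the brute-force oracle and hand arithmetic", {
  lib <- foram_content_library()
  # single species: 1e6 ind/m2 at 412 pmol/ind
  a1 <- tibble::tibble(station_id = "s1",
                       species = "Ammonia confertitesta",
                       abundance = 1e6)
  st <- station_stocks(a1, lib)
  expect_equal(st$stock_mmol_m2, 0.412)
  expect_equal(st$stock_g_m2, 0.412e-3 * 95)
  expect_equal(st$stock_g_m2, 0.03914)
  # empty-abundance station sums to zero
  a0 <- tibble::tibble(station_id = "s0", species = "Bolivina spissa",
                       abundance = 0)
  expect_equal(station_stocks(a0, lib)$stock_mmol_m2, 0)
  # random assemblages equal the row-by-row oracle exactly
  set.seed(31)
  pool <- c("Ammonia confertitesta", "Bolivina spissa", "Bolivina fragilis",
            "Haynesina germanica", "Elphidium ignotum", "Stainforthia fusiformis")
  for (rep in 1:5) {
    rows <- tibble::tibble(
      station_id = "x",
      species = sample(pool, 4),
      abundance = runif(4, 0, 1e5)
    )
    st <- station_stocks(rows, lib)
    or <- oracle_station_stock(rows, lib)
    expect_equal(st$stock_mmol_m2, unname(or["stock_mmol_m2"]))
    expect_equal(st$stock_g_m2, unname(or["stock_g_m2"]))
  }
})

test_that("stocks are additive over species and invariant to row order", {
  lib <- foram_content_library()
  rows <- tibble::tibble(
    station_id = "s",
    species = c("Ammonia confertitesta", "Bolivina spissa",
                "Haynesina germanica"),
    abundance = c(2e4, 5e4, 1e4)
  )
  whole <- station_stocks(rows, lib)$stock_mmol_m2
  parts <- sum(vapply(seq_len(nrow(rows)), function(i) {
    station_stocks(rows[i, ], lib)$stock_mmol_m2
  }, numeric(1)))
  expect_equal(whole, parts)
  shuffled <- rows[c(3, 1, 2), ]
  expect_equal(station_stocks(shuffled, lib)$stock_mmol_m2, whole)
  # negative abundance and duplicated pairs are rejected
  expect_error(station_stocks(dplyr::mutate(rows, abundance = -1), lib),
               "non-negative")
  expect_error(station_stocks(rows[c(1, 1), ], lib), "duplicated")
})

test_that("genus imputation uses congener means and only adds stock", {
  lib <- tibble::tibble(
    species = c("Bolivina alpha", "Bolivina beta"),
    content_pmol = c(40, 60), excluded = FALSE)
  rows <- tibble::tibble(
    station_id = "s",
    species = c("Bolivina alpha", "Bolivina incognita"),
    abundance = c(1e4, 1e4))
  with_imp <- station_stocks(rows, lib)
  expect_equal(with_imp$stock_mmol_m2, (1e4 * 40 + 1e4 * 50) * 1e-9)
  # when every congener shares content c the imputed value is c
  lib2 <- dplyr::mutate(lib, content_pmol = 55)
  expect_equal(lookup_content("Bolivina incognita", lib2)$content_pmol, 55)
  # removing the unmeasured species (no imputation) can only lower stock
  no_imp <- station_stocks(rows[1, ], lib)
  expect_lt(no_imp$stock_mmol_m2, with_imp$stock_mmol_m2)
  # excluded share reported for unaccounted species
  rows2 <- tibble::tibble(station_id = "s",
                          species = c("Bolivina alpha", "Elphidium ignotum"),
                          abundance = c(3e4, 1e4))
  expect_equal(station_stocks(rows2, lib)$excluded_abundance_share, 0.25)
})

test_that("abundance dialects convert to ind m^-2 explicitly", {
  expect_equal(convert_abundance(5, "ind_m2", quiet = TRUE), 5)
  expect_equal(convert_abundance(5, "ind_cm2", quiet = TRUE), 5e4)
  # 50 ind per 10 cm^3 over a 1 cm layer = 5 ind/cm^2 = 5e4 ind/m^2
  expect_equal(convert_abundance(50, "ind_10cm3", layer_depth_cm = 1,
                                 quiet = TRUE), 5e4)
  expect_message(convert_abundance(5, "ind_cm2"), "converted")
  expect_error(convert_abundance(5, "ind_furlong"), "unknown")
})

test_that("regional summary: weighted mean and standard error", {
  s <- regional_summary(c(0.004, 0.008))
  expect_equal(s$mean_stock_g_m2, 0.006)
  expect_equal(s$se_stock_g_m2, 0.002)
  # single station: mean passes through, s.e. undefined
  s1 <- regional_summary(0.0059)
  expect_equal(s1$mean_stock_g_m2, 0.0059)
  expect_true(is.na(s1$se_stock_g_m2))
  # degenerate weights select a single station exactly
  sw <- regional_summary(c(0.004, 0.008), weights = c(1, 0))
  expect_equal(sw$mean_stock_g_m2, 0.004)
  expect_error(regional_summary(c(1, 2), weights = c(0, 0)), "zero")
})

test_that("buffer budget converts stocks to tonnes and runoff days", {
  area <- 4.44e10
  b <- buffer_budget(262 * 1e6 / area, area, 2583)
  expect_equal(b$total_stock_t, 262)
  expect_equal(b$buffer_days, 262 / 2583 * 365)
  expect_equal(round(b$buffer_days), 37)
  # runoff equal to the stock buffers exactly one year
  b2 <- buffer_budget(1e-4, 1e12, 1e-4 * 1e12 * 1e-6)
  expect_equal(b2$buffer_days, 365)
  expect_error(buffer_budget(0.01, 1e10, 0), "positive")
  td <- tidy(b)
  expect_equal(td$estimate[td$term == "buffer_days"], b$buffer_days)
  expect_equal(glance(b)$total_stock_t, 262)
})

test_that("areal extrapolation is linear and unit-consistent", {
  t0 <- areal_extrapolation(417, 1, 413, 1.15e10)
  expect_equal(t0, 417 * 1e4 * 413 * 1e-12 * 95 * 1.15e10 * 1e-6)
  expect_equal(areal_extrapolation(0, 1, 413, 1.15e10), 0)
  expect_equal(areal_extrapolation(417, 1, 413, 2.3e10), 2 * t0)
  expect_warning(areal_extrapolation(1, 1, 1, 0.5), "square metres")
})

test_that("population density from split counts", {
  d <- population_density(50, 1 / 8, 100, depth_cm = 1)
  expect_equal(d$density_ind_cm3, 4)
  expect_equal(d$density_ind_cm2, 4)
  expect_equal(population_density(30, 1, 60)$density_ind_cm3, 0.5)
  expect_equal(population_density(0, 0.5, 10)$density_ind_cm3, 0)
  expect_error(population_density(10, 0, 100), "\\(0, 1\\]")
  expect_error(population_density(10, 0.5, 0), "positive")
})

test_that("synthetic region reproduces buffer days to machine precision", {
  syn <- gen_assemblage(n_stations = 30, seed = 5)
  st <- station_stocks(syn$assemblage)
  reg <- regional_summary(st)
  # Eq-2 estimate equals the generator's recoverable truth exactly
  expect_equal(reg$mean_stock_g_m2, syn$truth$realized_mean_stock_g_m2)
  area <- 4e10; runoff <- 2500
  b <- buffer_budget(reg$mean_stock_g_m2, area, runoff)
  expect_equal(b$buffer_days,
               syn$truth$realized_mean_stock_g_m2 * area * 1e-6 / runoff * 365)
})
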