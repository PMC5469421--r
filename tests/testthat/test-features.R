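test_that("catalogue enumeration is stable and counts 27 / 60 / 120", {
  cc <- channel_catalogue()
  expect_equal(nrow(cc), 27)
  expect_equal(length(unique(cc$family)), 9)
  expect_equal(unname(table(cc$family))[1], 3)

  fc <- feature_catalogue()
  expect_equal(nrow(fc), 120)
  expect_equal(sum(fc$variant == "unnorm"), 60)
  expect_equal(sum(fc$variant == "norm"), 60)
  expect_equal(sum(fc$statistic == "mean"), 54)
  expect_equal(sum(fc$statistic == "intensity_at_dw"), 54)
  expect_equal(sum(fc$statistic == "ratio576_610"), 12)
  expect_equal(anyDuplicated(fc$feature), 0)
  # enumeration order is reproducible
  expect_identical(fc, feature_catalogue())
})

test_that("combination channels follow their defining arithmetic", {
  grid <- wavelength_grid()
  # all six channels identical: gated == 0, ratios == 1, diffuse == 2x
  sp_eq <- flat_spectra(setNames(rep(1.5, 6), channel_names()))
  ch_eq <- build_channels(sp_eq)
  expect_equal(unname(ch_eq$mats$unnorm[["BF1-BF1per"]][1, ]), rep(0, 301))
  expect_equal(unname(ch_eq$mats$unnorm[["BF2/BF2per"]][1, ]), rep(1, 301))
  expect_equal(unname(ch_eq$mats$unnorm[["BF3+BF3per"]][1, ]), rep(3, 301))

  # hand arithmetic on the differential ratio
  vals <- c(BF1 = 2, BF2 = 1, BF3 = 0.25, BF1per = 1, BF2per = 0.5, BF3per = 0.2)
  ch2 <- build_channels(flat_spectra(vals))
  expect_equal(
    unname(ch2$mats$unnorm[["(BF1-BF2)/(BF1per-BF2per)"]][1, ]), rep(2, 301)
  )
  expect_equal(length(ch2$mats$unnorm), 27)
  expect_equal(length(ch2$mats$norm), 27)

  # reconstruction: gated + perpendicular == parallel, exactly
  co <- small_cohort(seed = 3)
  ch <- standardized_channels(co)
  for (k in 1:3) {
    expect_identical(
      ch$mats$unnorm[[paste0("BF", k, "-BF", k, "per")]] +
        ch$mats$unnorm[[paste0("BF", k, "per")]],
      ch$mats$unnorm[[paste0("BF", k)]]
    )
  }

  # near-zero denominators are masked, not infinite
  vals0 <- c(BF1 = 1, BF2 = 1, BF3 = 1, BF1per = 0, BF2per = 1, BF3per = 1)
  ch0 <- build_channels(flat_spectra(vals0))
  expect_true(all(is.na(ch0$mats$unnorm[["BF1/BF1per"]])))
})

test_that("area normalization yields unit-area spectra and is idempotent", {
  grid <- wavelength_grid()
  withr::with_seed(7, {
    y <- runif(length(grid), 0.5, 2)
    yn <- area_normalize(y, grid)
    expect_equal(pracma::trapz(grid, yn), 1, tolerance = 1e-12)
    expect_equal(area_normalize(yn, grid), yn, tolerance = 1e-12)
  })
  # flat spectrum over a 300-nm range normalizes to 1/300 per nm
  expect_equal(
    area_normalize(rep(4, length(grid)), grid),
    rep(1 / 300, length(grid))
  )
  expect_error(area_normalize(rep(0, length(grid)), grid), "positive")

  # the normalized variant in the channel object integrates to 1 as well
  co <- small_cohort(seed = 5)
  ch <- standardized_channels(co)
  areas <- apply(
    ch$mats$norm[["BF1"]], 1, function(y) pracma::trapz(ch$wavelength_nm, y)
  )
  expect_equal(unname(areas), rep(1, length(areas)), tolerance = 1e-9)
})

test_that("Welch t-statistic matches hand and brute-force computation", {
  # hand example: A = {1.0, 1.2, 1.4}, B = {2.0, 2.2}
  a <- matrix(c(1.0, 1.2, 1.4), ncol = 1)
  b <- matrix(c(2.0, 2.2), ncol = 1)
  expect_equal(
    welch_t_spectrum(a, b)[1],
    0.9 / sqrt(0.04 / 3 + 0.02 / 2),
    tolerance = 1e-12
  )
  expect_equal(welch_t_spectrum(a, b)[1], 5.892, tolerance = 1e-3)

  # identical means with nonzero variance: t == 0
  a2 <- matrix(c(1, 2, 3), ncol = 1)
  b2 <- matrix(c(0, 2, 4), ncol = 1)
  expect_equal(welch_t_spectrum(a2, b2)[1], 0)

  # translation invariance
  expect_equal(welch_t_spectrum(a + 10, b + 10), welch_t_spectrum(a, b))

  expect_error(welch_t_spectrum(a, b2[1, , drop = FALSE]), "two patients")

  # brute force on random small data sets
  brute_welch <- function(x, y) {
    abs(mean(x) - mean(y)) /
      sqrt(var(x) / length(x) + var(y) / length(y))
  }
  withr::with_seed(23, {
    for (i in 1:50) {
      na <- sample(2:6, 1)
      nb <- sample(2:6, 1)
      x <- rnorm(na)
      y <- rnorm(nb, 1)
      expect_equal(
        welch_t_spectrum(matrix(x, ncol = 1), matrix(y, ncol = 1))[1],
        brute_welch(x, y),
        tolerance = 1e-12
      )
    }
  })
})

test_that("discriminatory wavelength is the argmax with shortest-wavelength ties", {
  grid <- wavelength_grid()
  t1 <- dnorm(grid, 545, 4)
  expect_equal(discriminatory_wavelength(t1, grid), 545)
  expect_equal(discriminatory_wavelength(rep(1, length(grid)), grid), 450)
  expect_error(discriminatory_wavelength(rep(NA_real_, 301), grid), "finite")
})

test_that("a localized class difference is found near its true wavelength", {
  # two-class cohort whose only difference is a Gaussian bump at 576 nm
  grid <- wavelength_grid()
  withr::with_seed(31, {
    n_per <- 8
    mk <- function(id, bump) {
      base <- 1 + 0.3 * sin(grid / 50)
      df <- tibble::tibble(
        measurement_id = id, wavelength_nm = grid
      )
      for (ch in channel_names()) {
        # interpatient variation: smooth amplitude jitter + small white noise
        df[[ch]] <- (base + bump * exp(-(grid - 576)^2 / (2 * 8^2))) *
          rnorm(1, 1, 0.05) + rnorm(length(grid), 0, 0.002)
      }
      df
    }
    sp <- dplyr::bind_rows(
      lapply(1:n_per, function(i) mk(sprintf("a%d", i), 0)),
      lapply(1:n_per, function(i) mk(sprintf("b%d", i), 0.4))
    )
    ids <- unique(sp$measurement_id)
    patient <- setNames(ids, ids) # one patient per measurement
    labels <- setNames(rep(c("neg", "pos"), each = n_per), ids)
    ch <- build_channels(sp)
    rep_dw <- discriminatory_wavelengths(
      ch, patient[ch$measurement_id], labels[ch$measurement_id]
    )
    par_rows <- dplyr::filter(
      rep_dw, combo %in% parallel_channels(), variant == "unnorm"
    )
    expect_true(all(abs(par_rows$lambda_star_nm - 576) <= 5))
  })
})

test_that("feature extraction returns the 120 catalogue features", {
  co <- small_cohort(seed = 13)
  ch <- standardized_channels(co)
  ord <- match(ch$measurement_id, co$manifest$measurement_id)
  labels <- ifelse(co$manifest$class[ord] == "normal", "neg",
    ifelse(co$manifest$class[ord] == "SD", "pos", NA)
  )
  sub <- which(!is.na(labels))
  lam <- discriminatory_wavelengths(
    ch, co$manifest$patient_id[ord], labels, subset = sub
  )
  expect_equal(nrow(lam), 54)
  expect_true(all(lam$lambda_star_nm %in% ch$wavelength_nm))

  fv <- extract_features(ch, lam)
  expect_equal(ncol(fv), 121) # measurement_id + 120 features
  expect_equal(nrow(fv), length(ch$measurement_id))
  expect_setequal(setdiff(names(fv), "measurement_id"), feature_catalogue()$feature)

  # area-normalized 576/610 ratio equals the unnormalized one (scale cancels)
  for (ch_name in channel_names()) {
    expect_equal(
      fv[[paste0("r576/610(", ch_name, ")")]],
      fv[[paste0("r576/610(", ch_name, ").norm")]],
      tolerance = 1e-9
    )
  }

  # flat spectrum: mean == value, intensity-at-lambda* == value, ratio == 1
  flat <- flat_spectra(setNames(rep(0.7, 6), channel_names()))
  chf <- build_channels(flat)
  lam_flat <- lam # any lambda* report works for a flat spectrum
  fvf <- extract_features(chf, lam_flat)
  expect_equal(fvf[["mean(BF1)"]], 0.7)
  expect_equal(fvf[["I_dw(BF1)"]], 0.7)
  expect_equal(fvf[["r576/610(BF1)"]], 1)

  # direct 576/610 read
  grid <- wavelength_grid()
  sp <- flat_spectra(setNames(rep(1, 6), channel_names()))
  for (chn in channel_names()) {
    sp[[chn]] <- 1 + (grid >= 570 & grid <= 580) * (-0.2) # dip at 576
  }
  fv2 <- extract_features(build_channels(sp), lam_flat)
  expect_equal(fv2[["r576/610(BF2)"]], 0.8)
})

test_that("band frequency respects 20-nm band boundaries and rounding", {
  mk_report <- function(lams) {
    tibble::tibble(
      combo = paste0("c", seq_along(lams)), variant = "unnorm",
      lambda_star_nm = lams, t_max = 1
    )
  }
  # all 27 in one band: 100%
  bf <- band_frequency(mk_report(rep(455, 27)), min_pct = 0)
  expect_equal(nrow(bf), 1)
  expect_equal(bf$pct, 100L)
  expect_equal(bf$band, "450 to 469")

  # 10 of 27 in 450-469: 37%
  bf2 <- band_frequency(mk_report(c(rep(460, 10), rep(700, 17))), min_pct = 0)
  expect_equal(bf2$pct[bf2$band == "450 to 469"], 37L)

  # boundary convention: 469 belongs to 450-469, 470 to 470-489
  bf3 <- band_frequency(mk_report(c(469, 470, rep(600, 25))), min_pct = 0)
  expect_equal(bf3$count[bf3$band == "450 to 469"], 1L)
  expect_equal(bf3$count[bf3$band == "470 to 489"], 1L)
  # the final band spans 730-750 inclusive
  bf4 <- band_frequency(mk_report(c(rep(750, 3), rep(730, 2), rep(500, 22))),
    min_pct = 0
  )
  expect_equal(bf4$count[bf4$band == "730 to 750"], 5L)

  expect_error(band_frequency(mk_report(c(400, rep(500, 26)))), "450-750")
})
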