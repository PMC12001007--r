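test_that("scenario configuration validates its invariants", {
  expect_s3_class(small_config(), "scenario_config")
  expect_error(scenario_config(years = 2003), ">= 2 years")
  expect_error(scenario_config(n_pixels = 0), "n_pixels")
  expect_error(scenario_config(hatch_sd = -1), "SDs")
  expect_error(scenario_config(diet_p0 = 1.4), "diet_p0")
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_config(seed = 7)
  expect_identical(gen_ndsi_year(cfg, 2004), gen_ndsi_year(cfg, 2004))
  expect_identical(gen_pitfall_season(cfg, 2007), gen_pitfall_season(cfg, 2007))
  expect_identical(gen_chick_cohort(cfg, 2005), gen_chick_cohort(cfg, 2005))
  expect_identical(gen_feces(cfg), gen_feces(cfg))
  expect_identical(gen_juvenile_biometrics(cfg), gen_juvenile_biometrics(cfg))
})

test_that("a year outside the configured range is rejected", {
  cfg <- small_config()
  expect_error(gen_ndsi_year(cfg, 1990), "outside")
  expect_error(gen_chick_cohort(cfg, 2050), "outside")
  expect_error(gen_pitfall_season(cfg, 1999), "outside")
})

test_that("noise-free single-pixel NDSI binarizes to a clean step at the true melt day", {
  cfg <- small_config(seed = 3)
  cfg$n_pixels <- 1; cfg$pixel_melt_sd <- 0; cfg$ndsi_noise_sd <- 0
  cfg$snow_on_sd <- 0; cfg$melt_ramp_width <- 1e-3
  y <- cfg$years[2]
  melt <- mismatchr:::.melt_days(cfg)$melt_day[2]
  b <- binarize_ndsi(gen_ndsi_year(cfg, y))
  spring <- b[b$day < 250, ]
  expect_equal(spring$snow, as.integer(spring$day <= melt))
})

test_that("true snowmelt days carry the configured trend", {
  cfg <- scenario_config(years = 2003:2021, n_pixels = 2, n_broods_per_year = 1,
                         n_juveniles_per_year = 2, n_stations = 2, seed = 5)
  md <- mismatchr:::.melt_days(cfg)
  tr <- snowmelt_trend(data.frame(year = md$year, snowmelt_day = md$melt_day))
  expect_lt(abs(tr$slope - (-0.87)), 2 * cfg$snowmelt_sd / (sd(md$year) * sqrt(19)) + 2 * tr$se)
})

test_that("chick cohorts respect brood structure and age limits", {
  cfg <- small_config(seed = 11)
  out <- gen_chick_cohort(cfg, 2006, n_broods = 10)
  rec <- out$records
  expect_true(all(rec$age >= 0 & rec$age <= 21))
  expect_true(all(tapply(rec$hatch_day, rec$brood, function(h) length(unique(h))) == 1))
  expect_true(all(rec$capture_day == rec$hatch_day + rec$age))
  expect_true(any(rec$age_known) && any(!rec$age_known))
  expect_error(gen_chick_cohort(cfg, 2006, n_broods = 0), "n_broods")
})

test_that("a chick lying on the noiseless population curve has condition zero", {
  cfg <- small_config()
  g <- cfg$growth_params$tarsus
  fit <- structure(list(trait = "tarsus", form = g$form, A = g$A,
                        A_estimated = FALSE, k = g$k, T = g$T, sd_k = 0,
                        sd_resid = 0, deltas = numeric(0), n_obs = 0,
                        n_chicks = 0, converged = TRUE), class = "growth_fit")
  rec <- data.frame(chick = "c1", age = c(3, 9, 15),
                    tarsus = growth_curve(c(3, 9, 15), g$form, g$A, g$k, g$T))
  ci <- condition_index(fit, rec)
  expect_equal(ci$condition, rep(0, 3), tolerance = 1e-12)
})

test_that("pitfall counts are non-negative integers peaking near the configured lag", {
  cfg <- scenario_config(years = 2018:2019, n_pixels = 2, n_broods_per_year = 1,
                         n_juveniles_per_year = 2, n_stations = 40, seed = 13)
  out <- gen_pitfall_season(cfg, 2019)
  rec <- out$records
  expect_true(all(rec$count >= 0 & rec$count == round(rec$count)))
  expect_true(all(rec$day >= rec$snowfree))
  pt <- cranefly_peak_timing(rec)
  expect_lt(abs(pt$grand_mean - 29), 2.5)
})

test_that("feather values follow the mixing construction exactly in the noiseless limit", {
  cfg <- small_config()
  cfg$source_isotopes$d15n_sd <- 0
  cfg$discrimination$sd <- 0
  fam <- cfg$source_isotopes$family
  pure <- as.data.frame(as.list(setNames(c(1, rep(0, 6)), fam)))
  pure <- cbind(bird = "x", pure)
  iso <- gen_isotope_data(cfg, pure, "juvenile_covert")
  expect_equal(iso$feathers$d15n, cfg$source_isotopes$d15n_mean[1] + 3.53)

  # two-source equal mix sits at the discrimination-shifted midpoint
  cfg2 <- cfg; cfg2$source_isotopes <- cfg$source_isotopes[1:2, ]
  half <- data.frame(bird = "y", Tipulidae = 0.5, Chironomidae = 0.5)
  iso2 <- gen_isotope_data(cfg2, half, "chick_body")
  expect_equal(iso2$feathers$d15n,
               mean(cfg2$source_isotopes$d15n_mean) + 3.33)

  bad <- data.frame(bird = "z", Tipulidae = 0.6, Chironomidae = 0.6)
  expect_error(gen_isotope_data(cfg2, bad), "sum to 1")
})

test_that("juvenile biometrics encode the sex effect with positive PC1 loadings", {
  cfg <- scenario_config(years = 2003:2012, n_pixels = 2, n_broods_per_year = 1,
                         n_juveniles_per_year = 40, n_stations = 2, seed = 17)
  out <- gen_juvenile_biometrics(cfg)
  juv <- out$juveniles
  p <- body_size_pc1(juv)
  expect_true(all(p$loadings > 0))
  expect_gt(mean(p$scores[juv$sex == 1]), mean(p$scores[juv$sex == 0]))
  # diet proportions complete the simplex
  P <- as.matrix(out$truth$diet_props[, cfg$source_isotopes$family])
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_true(all(P >= 0 & P <= 1))
})

test_that("a full scenario is schema-valid, deterministic, and its truth round-trips", {
  cfg <- small_config(seed = 19)
  s1 <- simulate_scenario(cfg)
  expect_true(validate_inputs(s1$tables)$valid)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1, s2)
  tf <- tempfile(fileext = ".yaml")
  write_truth(s1$truth, tf)
  back <- read_truth(tf)
  expect_equal(back$melt_days$melt_day, s1$truth$melt_days$melt_day, tolerance = 1e-15)
  expect_equal(unname(unlist(back$sem_truth)), unname(unlist(s1$truth$sem_truth)))
  expect_equal(back$cranefly_peak_lag, 29)
  unlink(tf)
})

test_that("fecal fractions are sparse, bounded, and sum below one", {
  cfg <- small_config(seed = 23)
  fec <- gen_feces(cfg)
  expect_true(all(fec$fraction >= 0 & fec$fraction <= 1))
  sums <- tapply(fec$fraction, fec$sample, sum)
  expect_true(all(sums <= 1 + 1e-9))
  kp <- key_prey(fec)
  expect_equal(kp$family[1], "Tipulidae")
  expect_lt(abs(kp$mean_fraction[1] - 0.548), 0.15)
})
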