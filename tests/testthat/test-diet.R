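test_that("length-biomass allometry evaluates the power law per tier", {
  tab <- data.frame(family = c("Fam", "Fam", "Other"),
                    a = c(1, 99, 0.005), b = c(1, 9, 2.59),
                    tier = c("site", "order", "order"))
  expect_equal(as.numeric(length_to_biomass("Fam", 5, tab)), 5)  # site tier wins
  expect_equal(attr(length_to_biomass("Fam", 5, tab), "tier"), "site")
  m <- length_to_biomass("Other", 10, tab)
  expect_equal(as.numeric(m), 0.005 * 10^2.59, tolerance = 1e-12)
  expect_equal(round(as.numeric(m), 3), 1.945)
  expect_equal(as.numeric(length_to_biomass("Other", 0, tab)), 0)
  expect_error(length_to_biomass("Missing", 5, tab), "Missing")
})

test_that("daily biomass interpolation anchors, conserves and passes through", {
  # single 5-day interval of 10 mg: 2 mg/day at the anchor, 5 x 2 = 10
  one <- data.frame(station = "s1", family = "Tipulidae", day_end = 15,
                    interval_days = 5, biomass_mg = 10)
  db <- suppressWarnings(interpolate_daily_biomass(one))
  a <- attr(db, "anchors")
  expect_equal(a$daily_value, 2)
  expect_equal(a$day, 12.5)
  expect_equal(a$daily_value * a$interval_days, a$biomass_mg, tolerance = 1e-9)

  # two anchors 2 mg/day (10.5) and 4 mg/day (15.5): linear midpoint at day 13
  two <- data.frame(station = "s1", family = "Tipulidae", day_end = c(13, 18),
                    interval_days = 5, biomass_mg = c(10, 20))
  db2 <- interpolate_daily_biomass(two)
  expect_equal(db2$biomass[db2$day == 13], 3.0)

  # daily-collection records pass through unchanged
  daily <- data.frame(station = "s1", family = "Tipulidae", day_end = 10:14,
                      interval_days = 1, biomass_mg = c(1, 4, 2, 8, 5))
  db3 <- interpolate_daily_biomass(daily)
  expect_equal(db3$biomass[match(10:14, db3$day)], c(1, 4, 2, 8, 5))
})

test_that("interval totals are conserved for arbitrary records", {
  set.seed(5)
  rec <- data.frame(station = sample(c("s1", "s2"), 30, TRUE),
                    family = sample(c("A", "B"), 30, TRUE),
                    day_end = sample(seq(10, 60, 5), 30, TRUE),
                    interval_days = 5,
                    biomass_mg = runif(30, 0, 20))
  db <- suppressWarnings(interpolate_daily_biomass(rec))
  a <- attr(db, "anchors")
  expect_true(all(abs(a$daily_value * a$interval_days - a$biomass_mg) < 1e-9))
  # per-day availability proportions sum to 1 wherever biomass is present
  sums <- tapply(db$proportion, db$day, sum, na.rm = TRUE)
  tot <- tapply(db$biomass, db$day, sum)
  expect_true(all(abs(sums[tot > 0] - 1) < 1e-9))
})

test_that("Ivlev electivity matches hand values and is antisymmetric", {
  expect_equal(ivlev_index(0.5, 0.5), 0)
  expect_equal(ivlev_index(0.6, 0.2), 0.5)
  expect_equal(ivlev_index(0.5, 0), 1)
  expect_true(is.na(ivlev_index(0, 0)))
  expect_error(ivlev_index(1.2, 0.5), "fractions")
  set.seed(9)
  O <- runif(200); E <- runif(200)
  iv <- ivlev_index(O, E)
  expect_true(all(iv >= -1 & iv <= 1))
  expect_equal(iv, -ivlev_index(E, O), tolerance = 1e-12)
})

test_that("key prey are families above the 1% mean-diet threshold, order-invariant", {
  fec <- rbind(
    data.frame(sample = rep(sprintf("s%d", 1:10), each = 2),
               family = rep(c("Tipulidae", "Rare"), 10),
               fraction = rep(c(0.548, 0.005), 10)),
    data.frame(sample = sprintf("s%d", 1:10), family = "Chironomidae",
               fraction = 0.2)
  )
  kp <- key_prey(fec)
  expect_equal(kp$family, c("Tipulidae", "Chironomidae"))
  expect_equal(kp$mean_fraction[1], 0.548, tolerance = 1e-12)
  expect_false("Rare" %in% kp$family)
  shuffled <- fec[sample(nrow(fec)), ]
  expect_equal(key_prey(shuffled), kp)
  expect_error(key_prey(fec[0, ]), "no diet samples")
})

test_that("Ivlev table matches availability to the sampling day", {
  db <- data.frame(day = c(10, 10, 11, 11), family = c("A", "B", "A", "B"),
                   biomass = c(2, 2, 3, 1), proportion = c(0.5, 0.5, 0.75, 0.25))
  fec <- data.frame(sample = "f1", day = 11, family = c("A", "B"),
                    fraction = c(0.9, 0.1))
  iv <- ivlev_table(fec, db)
  expect_equal(iv$E, c(0.75, 0.25))
  expect_equal(iv$index, ivlev_index(c(0.9, 0.1), c(0.75, 0.25)))
})

test_that("crane-fly peak timing: null between years, day-0 bin, station exclusion", {
  # identical catch-day distributions in both years -> t approx 0
  base <- data.frame(station = rep(sprintf("s%d", 1:6), each = 3),
                     snowfree = 150,
                     day = 150 + rep(c(25, 29, 33), 6) + rep(c(-3, 0, 2, -1, 1, 1), each = 3),
                     family = "Tipulidae", count = 2)
  rec <- rbind(cbind(base, year = 2018), cbind(base, year = 2019))
  pt <- cranefly_peak_timing(rec)
  expect_lt(abs(pt$t_test$statistic), 1e-8)
  expect_gt(pt$t_test$p.value, 0.99)
  expect_equal(pt$grand_mean, 29)

  # degenerate case: every station mean identical -> reported as no difference
  const <- data.frame(station = rep(c("s1", "s2"), 2), snowfree = 150,
                      day = 179, family = "Tipulidae", count = 2,
                      year = rep(c(2018, 2019), each = 2))
  pc <- cranefly_peak_timing(const)
  expect_equal(unname(pc$t_test$statistic), 0)
  expect_equal(pc$t_test$p.value, 1)

  # all catches on the snow-free day: mean 0, counted in bin [0, 5)
  zero <- data.frame(station = c("s1", "s2"), year = 2018, snowfree = 150,
                     day = 150, family = "Tipulidae", count = 3)
  pz <- cranefly_peak_timing(zero)
  expect_equal(pz$grand_mean, 0)
  expect_equal(pz$bins$bin_start[pz$bins$count > 0], 0)

  # a station without catches is excluded; < 2 stations in a year skips the test
  mix <- rbind(data.frame(station = c("s1", "s2", "s3"), year = 2018,
                          snowfree = 150, day = 179, family = "Tipulidae",
                          count = c(4, 0, 4)),
               data.frame(station = "s4", year = 2019, snowfree = 150,
                          day = 175, family = "Tipulidae", count = 1))
  expect_warning(pm <- cranefly_peak_timing(mix), "skipped")
  expect_equal(sort(unique(pm$station_means$station)), c("s1", "s3", "s4"))
  expect_null(pm$t_test)
})

test_that("biomass equivalence reproduces the midges-per-crane-fly arithmetic", {
  expect_equal(biomass_equivalents(6.56, 0.10), 65.6, tolerance = 1e-12)
  expect_equal(round(biomass_equivalents(6.56, 0.10)), 66)
  expect_error(biomass_equivalents(6.56, 0), "positive")
})
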