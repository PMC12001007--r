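test_that("a single source forces the whole simplex onto one proportion", {
  src <- data.frame(family = "Tipulidae", d15n_mean = 3.0, d15n_sd = 0.4)
  f <- fit_mixing_model(data.frame(bird = "x", d15n = 6.5), src,
                        chains = 2, iter = 1500, burnin = 500, seed = 1,
                        keep_draws = TRUE)
  expect_true(all(f$draws[["x"]]$p == 1))
  expect_equal(f$summary$mean, 1)
})

test_that("posterior draws live on the simplex", {
  src <- data.frame(family = c("A", "B", "C"), d15n_mean = c(0, 4, 8),
                    d15n_sd = c(0.5, 0.5, 0.5))
  f <- fit_mixing_model(data.frame(bird = "x", d15n = 6), src,
                        chains = 2, iter = 3000, burnin = 500, seed = 2,
                        keep_draws = TRUE)
  P <- f$draws[["x"]]$p
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
})

test_that("a feather at the discrimination-shifted midpoint splits two symmetric sources", {
  src <- data.frame(family = c("A", "B"), d15n_mean = c(0, 8), d15n_sd = c(0.5, 0.5))
  f <- fit_mixing_model(data.frame(bird = "x", d15n = 4 + 3.53), src, seed = 3)
  expect_lt(abs(f$summary$mean[1] - 0.5), 0.02)
})

test_that("MCMC posterior means agree with the dense-grid oracle for 2 and 3 sources", {
  # 2 sources, feather exactly at source A + discrimination
  src2 <- data.frame(family = c("A", "B"), d15n_mean = c(0, 8), d15n_sd = c(0.3, 0.3))
  f2 <- fit_mixing_model(data.frame(bird = "x", d15n = 3.53), src2, seed = 4)
  or2 <- grid_posterior_mean(3.53, c(0, 8), c(0.3, 0.3), 3.53, 0.30)
  expect_lt(max(abs(f2$summary$mean - or2)), 0.02)
  expect_gte(f2$summary$mean[1], 0.9)  # dominated by the matching source

  src3 <- data.frame(family = c("A", "B", "C"), d15n_mean = c(1, 4.5, 8),
                     d15n_sd = c(0.5, 0.7, 0.9))
  f3 <- fit_mixing_model(data.frame(bird = "x", d15n = 3.2 + 3.53), src3, seed = 5)
  or3 <- grid_posterior_mean(3.2 + 3.53, c(1, 4.5, 8), c(0.5, 0.7, 0.9), 3.53, 0.30)
  expect_lt(max(abs(f3$summary$mean - or3)), 0.02)
})

test_that("with vanishing SDs the two-source posterior matches the closed form", {
  mu <- c(0, 8); D <- 3.53
  src <- data.frame(family = c("A", "B"), d15n_mean = mu, d15n_sd = c(0.01, 0.01))
  disc <- data.frame(tissue = "juvenile_covert", mean = D, sd = 0)
  for (delta in c(1, 2.5, 4, 5.5, 7)) {
    closed <- min(max((delta + D - D - mu[2]) / (mu[1] - mu[2]), 0), 1)
    # near-degenerate variances make the sampler sticky, so the Rhat flag
    # (a warning by design) is expected here; the posterior mean is still
    # accurate
    f <- suppressWarnings(
      fit_mixing_model(data.frame(bird = "x", d15n = delta + D), src,
                       discrimination = disc, prior_sigma_scale = 0.02,
                       seed = round(10 * delta)))
    expect_lt(abs(f$summary$mean[1] - closed), 0.02)
  }
})

test_that("the posterior is invariant to a common location shift", {
  src <- data.frame(family = c("A", "B", "C"), d15n_mean = c(1, 4, 7),
                    d15n_sd = c(0.5, 0.5, 0.5))
  f1 <- fit_mixing_model(data.frame(bird = "x", d15n = 6), src,
                         chains = 2, iter = 3000, burnin = 500, seed = 6)
  src_shift <- transform(src, d15n_mean = d15n_mean + 5)
  f2 <- fit_mixing_model(data.frame(bird = "x", d15n = 11), src_shift,
                         chains = 2, iter = 3000, burnin = 500, seed = 6)
  expect_equal(f1$summary$mean, f2$summary$mean, tolerance = 1e-12)
})

test_that("sampler settings and errors behave as documented", {
  src <- data.frame(family = c("A", "B"), d15n_mean = c(0, 8), d15n_sd = c(0.5, 0.5))
  expect_error(fit_mixing_model(data.frame(bird = "x", d15n = NA_real_), src),
               "non-finite")
  expect_error(fit_mixing_model(data.frame(bird = "x", d15n = 5, tissue = "tail"),
                                src), "unknown tissue")
  f <- fit_mixing_model(data.frame(bird = c("x", "y"), d15n = c(4, 5)), src,
                        chains = 2, iter = 1500, burnin = 500, seed = 7)
  expect_equal(nrow(f$diagnostics), 2)
  expect_true(all(c("accept_rate", "max_rhat", "converged") %in% names(f$diagnostics)))
})

test_that("juvenile diet trend models recover known year and snowmelt slopes", {
  set.seed(31)
  n <- 500
  yr <- sample(2003:2021, n, TRUE)
  melt <- 172 - 0.87 * (yr - 2003) + rnorm(n, 0, 3)
  sex <- rbinom(n, 1, 0.5)
  prop <- 0.62 - 0.0072 * (yr - 2003) + 0.0029 * (melt - mean(melt)) +
    rnorm(n, 0, 0.06)
  mc <- diet_trend_juveniles(data.frame(prop = prop, year = yr,
                                        snowmelt = melt, sex = sex))
  av <- mc$averaged
  yr_slope <- av[av$term == "year", ]
  expect_lt(abs(yr_slope$estimate - (-0.97)), 2 * yr_slope$se)
  expect_error(diet_trend_juveniles(data.frame(prop = runif(10), year = 2003,
                                               snowmelt = 170, sex = 0)),
               ">= 3 years")
})

test_that("collinear year and snowmelt drops the joint models with a warning", {
  yr <- rep(2003:2012, each = 10)
  melt <- 172 - 0.87 * (yr - 2003)  # perfectly collinear
  d <- data.frame(prop = runif(100, 0.3, 0.7), year = yr, snowmelt = melt,
                  sex = rbinom(100, 1, 0.5))
  expect_warning(mc <- diet_trend_juveniles(d), "collinear")
  joint <- grepl("year", mc$table$terms) & grepl("snowmelt", mc$table$terms)
  expect_false(any(joint))
})

test_that("chick diet versus hatch date uses brood grouping and guards degeneracy", {
  set.seed(33)
  n_brood <- 12
  d <- do.call(rbind, lapply(seq_len(n_brood), function(b) {
    rhd <- rnorm(1, 12, 5)
    re <- rnorm(1, 0, 0.03)
    data.frame(prop = 0.5 - 0.006 * rhd + re + rnorm(3, 0, 0.04),
               rhd = rhd, year = sample(c(2018, 2019), 1),
               brood = sprintf("b%02d", b))
  }))
  mc <- diet_vs_hatch_chicks(d)
  av <- mc$averaged[mc$averaged$term == "rhd", ]
  if (nrow(av) == 1) {
    expect_lt(abs(av$estimate - (-0.6)), 3 * av$se)
  }
  expect_equal(sum(mc$table$weight), 1, tolerance = 1e-12)
  expect_error(diet_vs_hatch_chicks(transform(d, brood = "b1")), ">= 2 broods")
  expect_error(diet_vs_hatch_chicks(transform(d, rhd = 5)), "inestimable")
})
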