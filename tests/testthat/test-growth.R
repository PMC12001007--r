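test_that("AICc matches hand arithmetic and tends to AIC for large n", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17, tolerance = 1e-12)
  expect_lt(abs(aicc(-50, 3, 1e6) - (2 * 50 + 2 * 3)), 1e-3)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("model comparison weights sum to 1 and applies the uninformative-parameter rule", {
  set.seed(7)
  d <- data.frame(y = rnorm(60), x1 = rnorm(60), x2 = rnorm(60))
  models <- list(lm(y ~ 1, d), lm(y ~ x1, d), lm(y ~ x2, d), lm(y ~ x1 + x2, d))
  terms <- list(character(0), "x1", "x2", c("x1", "x2"))
  mc <- model_comparison(models, terms, n = 60)
  expect_equal(sum(mc$table$weight), 1, tolerance = 1e-12)
  expect_equal(mc$table$delta[1], 0)
  # noise predictors: models that merely add parameters to the best model
  # must not be competitive even if within delta 2
  best_terms <- mc$table$terms[1]
  supersets <- mc$table$terms != best_terms &
    vapply(strsplit(mc$table$terms, "+", fixed = TRUE), function(tt)
      all(strsplit(best_terms, "+", fixed = TRUE)[[1]] %in% tt), TRUE)
  expect_false(any(mc$table$competitive[supersets & mc$table$delta < 2 &
                                          nchar(mc$table$terms) > nchar(best_terms)]))
})

test_that("body-size PC1 handles rank-1 input and fixes the sign convention", {
  x <- rnorm(30, 10)
  rank1 <- data.frame(bill = x, tarsus = 2 * x + 1, wing = 3 * x - 2)
  p <- body_size_pc1(rank1)
  expect_equal(p$variance_explained, 100, tolerance = 1e-8)
  expect_equal(unname(p$loadings), rep(1 / sqrt(3), 3), tolerance = 1e-8)
  neg <- -rank1
  pn <- body_size_pc1(neg)
  expect_equal(unname(pn$loadings), unname(p$loadings), tolerance = 1e-8)
  expect_equal(unname(pn$scores), -unname(p$scores), tolerance = 1e-8)
})

test_that("age estimation from the 10th primary is exact on linear calibration", {
  cal <- data.frame(p10 = c(2, 6, 10, 14, 18), age = 2 + 0.5 * c(2, 6, 10, 14, 18))
  q <- data.frame(chick = c("a", "b", "c"), brood = c("B1", "B1", "B1"),
                  p10 = c(6, 10, 14))
  est <- estimate_age_from_p10(cal, q)
  expect_equal(est$age_ind, c(5, 7, 9))
  expect_equal(est$age_est, rep(7, 3))          # brood-averaged
  expect_false(any(est$extrapolated))
  # query at the calibration mean predicts the mean calibration age
  qm <- estimate_age_from_p10(cal, data.frame(chick = "x", brood = "B", p10 = mean(cal$p10)))
  expect_equal(qm$age_ind, mean(cal$age))
  expect_true(estimate_age_from_p10(cal, data.frame(chick = "y", brood = "B", p10 = 30))$extrapolated)
  expect_error(estimate_age_from_p10(cal[1:3, ], q), ">= 5")
})

test_that("growth curves satisfy their defining identities", {
  expect_equal(growth_curve(8, "logistic", A = 25, k = 0.3, T_ = 8), 12.5)
  expect_equal(growth_curve(-9, "von_bertalanffy", A = 30, k = 0.05, T_ = -9), 0)
})

test_that("noiseless trajectories recover growth parameters to 1e-6", {
  set.seed(1)
  ages <- runif(40, 0, 21)
  for (spec in list(list(form = "logistic", A = 25, k = 0.25, T = 8),
                    list(form = "von_bertalanffy", A = 33, k = 0.05, T = -9))) {
    d <- data.frame(chick = rep(sprintf("c%02d", 1:20), each = 2), age = ages)
    d$y <- growth_curve(d$age, spec$form, spec$A, spec$k, spec$T)
    f <- fit_growth_model(d, "y", spec$form, random_k = FALSE)
    expect_lt(abs(f$k - spec$k), 1e-6)
    expect_lt(abs(f$T - spec$T), 1e-6)
    expect_lt(abs(f$A - spec$A) / spec$A, 1e-6)
  }
})

test_that("structural traits demand a fixed asymptote", {
  d <- data.frame(chick = sprintf("c%02d", 1:20), age = 1:20, tarsus = 1:20 + 10)
  expect_error(fit_growth_model(d, "tarsus", "logistic"), "A_fixed")
})

test_that("per-chick growth-rate deviations are recovered with shrinkage", {
  set.seed(101)
  dd <- do.call(rbind, lapply(1:200, function(i) {
    dl <- rnorm(1, 0, 0.02)
    ages <- sort(sample(0:21, sample(1:3, 1)))
    data.frame(chick = sprintf("c%03d", i), age = ages,
               tarsus = growth_curve(ages, "logistic", 31.2, 0.22 + dl, -3.5) +
                 rnorm(length(ages), 0, 0.5))
  }))
  f <- fit_growth_model(dd, "tarsus", "logistic", A_fixed = 31.2)
  expect_lt(abs(f$k - 0.22) / 0.22, 0.08)
  expect_lt(abs(f$sd_k - 0.02) / 0.02, 0.4)
  expect_gt(f$sd_k, 0)
  # mean residual near zero relative to residual SD
  pred <- predict(f, dd$age, chick = dd$chick)
  expect_lt(abs(mean(dd$tarsus - pred)) / f$sd_resid, 0.1)
})

test_that("condition index is a relative residual with the age-2 exclusion", {
  fit <- structure(list(trait = "tarsus", form = "logistic", A = 31.2,
                        A_estimated = FALSE, k = 0.22, T = -3.5, sd_k = 0,
                        sd_resid = 0.5, deltas = numeric(0), n_obs = 0,
                        n_chicks = 0, converged = TRUE), class = "growth_fit")
  pred10 <- growth_curve(10, "logistic", 31.2, 0.22, -3.5)
  rec <- data.frame(chick = c("a", "b", "c", "d"),
                    age = c(10, 10, 1, NA),
                    tarsus = c(pred10, 1.05 * pred10, 20, 21))
  ci <- suppressMessages(condition_index(fit, rec))
  expect_equal(nrow(ci), 2)
  expect_equal(ci$condition, c(0, 0.05), tolerance = 1e-12)
  audit <- attr(ci, "audit")
  expect_equal(audit$n_dropped_young, 1)
  expect_equal(audit$n_dropped_no_age, 1)
})

test_that("condition index is invariant to measurement-unit rescaling", {
  set.seed(3)
  d <- data.frame(chick = rep(sprintf("c%02d", 1:15), 2), age = runif(30, 2, 20))
  d$y <- growth_curve(d$age, "logistic", 31.2, 0.22, -3.5) + rnorm(30, 0, 0.4)
  d$y_cm <- d$y / 10
  f_mm <- fit_growth_model(d, "y", "logistic", random_k = FALSE)
  f_cm <- fit_growth_model(d, "y_cm", "logistic", random_k = FALSE)
  ci_mm <- condition_index(f_mm, d)
  ci_cm <- condition_index(f_cm, d)
  expect_equal(ci_mm$condition, ci_cm$condition, tolerance = 1e-4)
})

test_that("relative hatch date is hatch minus snowmelt, negative allowed", {
  expect_equal(relative_hatch_date(193, 180), 13)
  expect_equal(relative_hatch_date(180, 180), 0)
  expect_equal(relative_hatch_date(179, 180), -1)
  expect_error(relative_hatch_date(190, NA_real_), "missing")
})

test_that("condition regression recovers a known hatch-date slope by model averaging", {
  set.seed(11)
  n_chick <- 150
  d <- do.call(rbind, lapply(seq_len(n_chick), function(i) {
    yr <- sample(1:4, 1)
    rhd <- rnorm(1, 12, 5)
    n <- sample(1:2, 1)
    data.frame(chick = sprintf("c%03d", i), year = yr, rhd = rhd,
               temp3d = rnorm(n, 8, 2),
               condition = -0.0024 * rhd + rnorm(1, 0, 0.01) +
                 c(0.005, -0.005, 0.002, -0.002)[yr] + rnorm(n, 0, 0.02))
  }))
  mc <- condition_regression(d)
  av <- mc$averaged[mc$averaged$term == "rhd", ]
  expect_equal(nrow(av), 1)
  expect_lt(abs(av$estimate - (-0.0024)), 2 * av$se)
  expect_true("rhd" %in% strsplit(mc$table$terms[1], "+", fixed = TRUE)[[1]])
})

test_that("condition regression prefers the intercept-only model under a null effect", {
  set.seed(21)
  d <- data.frame(chick = rep(sprintf("c%03d", 1:100), each = 2),
                  year = rep(sample(1:4, 100, TRUE), each = 2),
                  rhd = rep(rnorm(100, 12, 5), each = 2),
                  temp3d = rnorm(200, 8, 2),
                  condition = rnorm(200, 0, 0.03))
  mc <- condition_regression(d)
  expect_equal(mc$table$terms[1], "")
})
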