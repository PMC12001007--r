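#' Evaluate a chick growth curve
#'
#' Logistic: `A / (1 + exp(-k (t - T)))`, with inflection at `t = T` where
#' the curve passes `A/2`. Von Bertalanffy: `A (1 - exp(-k (t - T)))`, with
#' `T` the horizontal placement (t-axis crossing).
#'
#' @param t age in days (vectorized).
#' @param form `"logistic"` or `"von_bertalanffy"`.
#' @param A asymptote (trait units).
#' @param k growth rate per day.
#' @param T_ horizontal placement parameter (days).
#' @return Predicted size at each `t`.
#' @export
growth_curve <- function(t, form = c("logistic", "von_bertalanffy"), A, k, T_) {
  form <- match.arg(form)
  switch(form,
         logistic = A / (1 + exp(-k * (t - T_))),
         von_bertalanffy = A * (1 - exp(-k * (t - T_))))
}

## derivative of the curve w.r.t. k, needed for the Laplace curvature term
.growth_dk <- function(t, form, A, k, T_) {
  u <- k * (t - T_)
  if (form == "logistic") {
    e <- exp(-u)
    A * (t - T_) * e / (1 + e)^2
  } else {
    A * (t - T_) * exp(-u)
  }
}

#' Body-size index as the first principal component of structural measures
#'
#' PCA on unit-variance-scaled bill, tarsus and wing length. The PC1 sign is
#' fixed so that loadings are positive (larger score = larger bird).
#' Incomplete rows are dropped and counted.
#'
#' @param biometrics data frame containing the columns named in `traits`.
#' @param traits character vector of trait columns; default
#'   `c("bill", "tarsus", "wing")`.
#' @return List with `scores` (PC1 per retained row), `loadings`,
#'   `variance_explained` (percent), `center`, `scale`, `rows` (indices of
#'   retained rows), `n_used`, `n_dropped`.
#' @export
body_size_pc1 <- function(biometrics, traits = c("bill", "tarsus", "wing")) {
  stopifnot(all(traits %in% names(biometrics)))
  x <- biometrics[, traits, drop = FALSE]
  ok <- complete.cases(x)
  if (sum(ok) < 3L) stop("need >= 3 complete rows for a PCA")
  if (any(!ok)) message(sum(!ok), " rows with missing trait values dropped from PCA")
  p <- prcomp(x[ok, ], center = TRUE, scale. = TRUE)
  flip <- if (mean(p$rotation[, 1]) < 0) -1 else 1
  list(scores = flip * p$x[, 1],
       loadings = flip * p$rotation[, 1],
       variance_explained = 100 * p$sdev[1]^2 / sum(p$sdev^2),
       center = p$center, scale = p$scale,
       rows = which(ok), n_used = sum(ok), n_dropped = sum(!ok))
}

#' Estimate chick age from 10th-primary length
#'
#' Linear calibration of age on 10th-primary feather length from known-age
#' chicks, applied to chicks of unknown age. Because all chicks of a brood
#' hatch on the same day, per-chick predictions are averaged within broods.
#' Queries outside the calibration feather-length range are flagged as
#' extrapolated.
#'
#' @param calibration data frame with columns `age` (days) and `p10` (mm)
#'   from known-age chicks (>= 5 rows).
#' @param query data frame with columns `chick`, `brood` and `p10`.
#' @return `query` with added columns `age_ind` (per-chick prediction),
#'   `age_est` (brood-averaged age) and `extrapolated`.
#' @export
estimate_age_from_p10 <- function(calibration, query) {
  stopifnot(all(c("age", "p10") %in% names(calibration)),
            all(c("chick", "brood", "p10") %in% names(query)))
  if (nrow(calibration) < 5L) stop("need >= 5 known-age calibration pairs")
  fit <- lm(age ~ p10, data = calibration)
  query$age_ind <- predict(fit, newdata = query)
  query$age_est <- stats::ave(query$age_ind, query$brood)
  rng <- range(calibration$p10)
  query$extrapolated <- query$p10 < rng[1] | query$p10 > rng[2]
  query
}

#' Fit a population growth curve with per-chick growth-rate deviations
#'
#' Fits a logistic or von Bertalanffy curve to cross-sectional and repeated
#' chick measurements. Individual variation enters as an additive per-chick
#' deviation on the growth rate, `k_i = k + delta_i` with
#' `delta_i ~ Normal(0, sd_k^2)`, estimated by penalized nonlinear least
#' squares with the deviation SD chosen by a profiled Laplace marginal
#' criterion. Structural traits require a fixed asymptote (taken from
#' full-grown winter juveniles) because chicks have not reached final
#' structural size at fledging; for body mass the asymptote is estimated.
#'
#' @param records data frame with columns `chick`, `age`, and the trait
#'   column named by `trait`.
#' @param trait name of the measurement column.
#' @param form growth-curve form, `"logistic"` or `"von_bertalanffy"`.
#' @param A_fixed fixed asymptote; required for structural traits
#'   (`bill`, `tarsus`, `wing`, `pc1`), ignored message-free otherwise.
#' @param random_k logical; estimate per-chick growth-rate deviations
#'   (default TRUE). With FALSE a plain population fit is returned
#'   (`sd_k = 0`).
#' @return An object of class `growth_fit` with elements `trait`, `form`,
#'   `A`, `A_estimated`, `k`, `T`, `sd_k`, `sd_resid`, `deltas` (named
#'   per-chick k deviations), `n_obs`, `n_chicks`, `converged`.
#' @export
fit_growth_model <- function(records, trait, form = c("logistic", "von_bertalanffy"),
                             A_fixed = NULL, random_k = TRUE) {
  form <- match.arg(form)
  stopifnot(all(c("chick", "age") %in% names(records)), trait %in% names(records))
  d <- records[is.finite(records$age) & is.finite(records[[trait]]), ]
  y <- d[[trait]]; t_ <- d$age; chick <- as.character(d$chick)
  if (length(unique(chick)) < 10L) stop("need >= 10 chicks to fit a growth model")
  structural <- trait %in% c("bill", "tarsus", "wing", "pc1")
  if (structural && is.null(A_fixed)) {
    stop("A_fixed (asymptote from winter juveniles) is required for structural trait '",
         trait, "'")
  }
  est_A <- is.null(A_fixed)

  rss_fun <- function(par, deltas = NULL) {
    k <- exp(par[1]); T_ <- par[2]
    A <- if (est_A) exp(par[3]) else A_fixed
    ki <- if (is.null(deltas)) k else k + deltas[chick]
    sum((y - growth_curve(t_, form, A, ki, T_))^2)
  }

  ## initials by linearization
  A0 <- if (est_A) max(y) * 1.1 else A_fixed
  yy <- pmin(pmax(y / A0, 1e-3), 1 - 1e-3)
  z <- if (form == "logistic") qlogis(yy) else -log(1 - yy)
  lf <- lm(z ~ t_)
  k0 <- max(abs(coef(lf)[2]), 1e-3)
  T0 <- if (form == "logistic") -coef(lf)[1] / coef(lf)[2] else -coef(lf)[1] / k0
  p0 <- c(log(k0), unname(T0), if (est_A) log(A0))

  o <- optim(p0, rss_fun, method = "Nelder-Mead",
             control = list(maxit = 3000, reltol = 1e-14))
  o <- suppressWarnings(optim(o$par, rss_fun, method = "BFGS",
                              control = list(maxit = 1000, reltol = 1e-14)))
  pop <- o$par
  k_hat <- exp(pop[1]); T_hat <- pop[2]
  A_hat <- if (est_A) exp(pop[3]) else A_fixed
  n <- length(y)
  chicks <- unique(chick)
  m <- length(chicks)
  deltas <- setNames(rep(0, m), chicks)
  sd_k <- 0
  sigma2 <- max(o$value / n, 1e-12)

  if (random_k && m >= 2L) {
    idx <- split(seq_len(n), chick)

    update_deltas <- function(par, sdk, sig2) {
      k <- exp(par[1]); T_ <- par[2]
      A <- if (est_A) exp(par[3]) else A_fixed
      vapply(chicks, function(cid) {
        ii <- idx[[cid]]
        obj <- function(dl) {
          sum((y[ii] - growth_curve(t_[ii], form, A, k + dl, T_))^2) / sig2 +
            dl^2 / sdk^2
        }
        optimize(obj, interval = c(-0.9 * k, 2 * k), tol = 1e-10)$minimum
      }, 0)
    }

    laplace_negll <- function(log_sdk) {
      sdk <- exp(log_sdk)
      par <- pop; sig2 <- sigma2; dl <- deltas
      for (it in 1:3) {
        dl <- update_deltas(par, sdk, sig2)
        oo <- optim(par, rss_fun, deltas = dl, method = "Nelder-Mead",
                    control = list(maxit = 1500, reltol = 1e-12))
        par <- oo$par
        sig2 <- max(oo$value / n, 1e-12)
      }
      k <- exp(par[1]); T_ <- par[2]
      A <- if (est_A) exp(par[3]) else A_fixed
      logdet <- vapply(chicks, function(cid) {
        ii <- idx[[cid]]
        J <- sum(.growth_dk(t_[ii], form, A, k + dl[[cid]], T_)^2)
        log1p(sdk^2 * J / sig2)
      }, 0)
      val <- 0.5 * (n * log(2 * pi * sig2) + n + sum(dl^2) / sdk^2 + sum(logdet))
      attr(val, "state") <- list(par = par, deltas = dl, sigma2 = sig2)
      val
    }

    prof <- optimize(function(ls) as.numeric(laplace_negll(ls)),
                     interval = log(c(1e-4 * k_hat, k_hat)), tol = 1e-3)
    final <- laplace_negll(prof$minimum)
    st <- attr(final, "state")
    sd_k <- exp(prof$minimum)
    pop <- st$par; deltas <- st$deltas; sigma2 <- st$sigma2
    k_hat <- exp(pop[1]); T_hat <- pop[2]
    A_hat <- if (est_A) exp(pop[3]) else A_fixed
    ## an estimated SD at the lower profiling bound means no detectable
    ## between-chick variation
    if (sd_k <= 1.05 * 1e-4 * k_hat) {
      sd_k <- 0; deltas[] <- 0
    }
  }

  structure(list(trait = trait, form = form, A = A_hat, A_estimated = est_A,
                 k = k_hat, T = T_hat, sd_k = sd_k,
                 sd_resid = sqrt(sigma2), deltas = deltas,
                 n_obs = n, n_chicks = m, converged = o$convergence == 0),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s growth fit for '%s' (%d obs, %d chicks)\n",
              x$form, x$trait, x$n_obs, x$n_chicks))
  cat(sprintf("  A = %.3f%s, k = %.4f /day, T = %.3f d\n",
              x$A, if (x$A_estimated) " (estimated)" else " (fixed)", x$k, x$T))
  cat(sprintf("  sd_k = %.5f, sd_resid = %.4f\n", x$sd_k, x$sd_resid))
  invisible(x)
}

#' Predict from a fitted growth curve
#'
#' @param object a `growth_fit`.
#' @param age ages in days.
#' @param chick optional chick ids; when given and present in the fit, the
#'   per-chick growth-rate deviation is applied, otherwise the population
#'   curve is used.
#' @param ... unused.
#' @return Predicted sizes.
#' @export
predict.growth_fit <- function(object, age, chick = NULL, ...) {
  k <- object$k
  if (!is.null(chick)) {
    dl <- object$deltas[as.character(chick)]
    dl[is.na(dl)] <- 0
    k <- k + dl
  }
  growth_curve(age, object$form, object$A, k, object$T)
}

#' Chick condition index from growth-curve residuals
#'
#' For each measurement, `(observed - predicted) / predicted`, where the
#' prediction is the population-level curve at the chick's age (per-chick
#' growth-rate deviations are deliberately excluded so that a consistently
#' slow chick stays consistently negative). Chicks younger than `min_age`
#' days are excluded because up to that age they largely live off their yolk
#' sack; rows with missing age are skipped. Both counts are recorded in the
#' `audit` attribute.
#'
#' @param fit a `growth_fit`.
#' @param records data frame with columns `chick`, `age` and the fitted
#'   trait; any additional columns are carried through.
#' @param min_age minimum age in days (default 2).
#' @return Data frame of retained rows with columns `predicted` and
#'   `condition` added; attribute `audit` lists `n_in`, `n_kept`,
#'   `n_dropped_young`, `n_dropped_no_age`.
#' @export
condition_index <- function(fit, records, min_age = 2) {
  stopifnot(inherits(fit, "growth_fit"),
            all(c("chick", "age", fit$trait) %in% names(records)))
  n_in <- nrow(records)
  no_age <- !is.finite(records$age)
  if (any(no_age)) message(sum(no_age), " rows without age skipped")
  young <- !no_age & records$age < min_age
  keep <- !no_age & !young
  out <- records[keep, , drop = FALSE]
  out$predicted <- growth_curve(out$age, fit$form, fit$A, fit$k, fit$T)
  out$condition <- (out[[fit$trait]] - out$predicted) / out$predicted
  attr(out, "audit") <- list(n_in = n_in, n_kept = sum(keep),
                             n_dropped_young = sum(young),
                             n_dropped_no_age = sum(no_age))
  out
}

#' Relative hatch date
#'
#' Hatch day-of-year minus the local snowmelt day-of-year of the same year;
#' negative values mean hatching before 50% snowmelt.
#'
#' @param hatch_day hatch day-of-year (vectorized).
#' @param snowmelt_day snowmelt day-of-year (recycled).
#' @return `hatch_day - snowmelt_day` in days.
#' @export
relative_hatch_date <- function(hatch_day, snowmelt_day) {
  if (any(!is.finite(snowmelt_day))) {
    stop("snowmelt day missing for at least one year: cannot compute relative hatch date")
  }
  hatch_day - snowmelt_day
}

#' Regress chick condition on relative hatch date and temperature
#'
#' Candidate GLMMs with all fixed-effect subsets of relative hatch date and
#' 3-day pre-capture temperature, with year and chick identity as random
#' intercepts, compared by AICc (competitive set at delta < 2 with the
#' uninformative-parameter exclusion, model averaging where more than one
#' model remains). When grouping is degenerate (a single year or chick) the
#' candidate set degrades to fixed-effects-only GLMs with a warning.
#'
#' @param data data frame with columns `condition`, `rhd`, `temp3d`,
#'   `year`, `chick`.
#' @param min_obs minimum observations required (default 30).
#' @param hinge optional day threshold; when non-NULL an experimental hinge
#'   term `pmax(rhd - hinge, 0)` is added to the candidate set (breakpoint
#'   growth-depression form).
#' @return A [model_comparison] object.
#' @export
condition_regression <- function(data, min_obs = 30, hinge = NULL) {
  need <- c("condition", "rhd", "temp3d", "year", "chick")
  stopifnot(all(need %in% names(data)))
  data <- data[complete.cases(data[, need]), ]
  if (nrow(data) < min_obs) stop("need >= ", min_obs, " observations")
  fixed_sets <- list(character(0), "rhd", "temp3d", c("rhd", "temp3d"))
  if (!is.null(hinge)) {
    data$rhd_hinge <- pmax(data$rhd - hinge, 0)
    fixed_sets <- c(fixed_sets, list(c("rhd", "rhd_hinge")))
  }
  mixed <- length(unique(data$year)) > 1L && length(unique(data$chick)) > 1L
  if (!mixed) warning("degenerate grouping: falling back to fixed-effects-only models")
  fits <- lapply(fixed_sets, function(tt) {
    rhs <- if (length(tt) == 0) "1" else paste(tt, collapse = " + ")
    if (mixed) {
      f <- stats::as.formula(paste("condition ~", rhs, "+ (1 | year) + (1 | chick)"))
      suppressMessages(lme4::lmer(f, data = data, REML = FALSE))
    } else {
      lm(stats::as.formula(paste("condition ~", rhs)), data = data)
    }
  })
  model_comparison(fits, fixed_sets, n = nrow(data))
}

#' Express predicted size as a percentage of a reference size
#'
#' Display helper used for figure-style percent scaling (e.g. size relative
#' to a chick hatched at the earliest relative hatch date, or to a female
#' juvenile in the first study year). Never feeds inference.
#'
#' @param x predicted sizes.
#' @param reference reference size.
#' @return `100 * x / reference`.
#' @export
percent_of_reference <- function(x, reference) 100 * x / reference
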