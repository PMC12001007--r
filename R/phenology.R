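#' Binarize NDSI observations into snow / no-snow
#'
#' Classifies each satellite snow-index observation as snow-covered using the
#' established MODIS NDSI threshold of 0.4. Values at exactly the threshold
#' count as snow.
#'
#' @param obs data frame with columns `pixel`, `day` (day-of-year) and `ndsi`
#'   (fraction in \[0, 1\]).
#' @param threshold NDSI value at and above which a pixel counts as
#'   snow-covered. Default 0.4.
#' @return The input data frame with an added integer column `snow`
#'   (1 = snow, 0 = bare). Row count is preserved.
#' @examples
#' obs <- data.frame(pixel = 1, day = 150:153, ndsi = c(0.8, 0.41, 0.39, 0.1))
#' binarize_ndsi(obs)$snow
#' @export
binarize_ndsi <- function(obs, threshold = 0.4) {
  stopifnot(is.data.frame(obs), all(c("pixel", "day", "ndsi") %in% names(obs)))
  bad <- which(!is.finite(obs$ndsi) | obs$ndsi < 0 | obs$ndsi > 1)
  if (length(bad) > 0) {
    stop("ndsi values outside [0, 1] at rows: ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "")
  }
  obs$snow <- as.integer(obs$ndsi >= threshold)
  obs
}

## Asymmetric Gaussian for the snow-FREE (bare ground) fraction of the area.
## The curve peaks in mid-summer; snow fraction is 1 - curve, so the spring
## (descending-snow) limb is the Gaussian's left limb, and with height 1 /
## baseline 0 the 50% snowmelt crossing is at mu - sigma_l * sqrt(2 log 2).
#' Evaluate the asymmetric-Gaussian snow-free curve
#'
#' @param t day-of-year (vectorized).
#' @param par named vector or list with `baseline`, `height`, `mu`,
#'   `sigma_l`, `sigma_r`. `baseline` is the winter snow-free floor in
#'   \[0, 0.5); `baseline + height` is the summer maximum (at most 1); `mu`
#'   the day of maximum bare ground; `sigma_l`/`sigma_r` the spring and
#'   autumn widths in days.
#' @return Snow-free fraction in \[0, 1\] at each `t`. The snow-cover
#'   fraction is `1 - snow_curve(t, par)`.
#' @export
snow_curve <- function(t, par) {
  par <- as.list(par)
  sig <- ifelse(t < par$mu, par$sigma_l, par$sigma_r)
  par$baseline + par$height * exp(-(t - par$mu)^2 / (2 * sig^2))
}

#' Fit an asymmetric-Gaussian seasonal snow curve by maximum likelihood
#'
#' Fits the seasonal course of area snow cover for one year from binarized
#' snow-index observations. Per day, the number of snow-classified pixels out
#' of the valid pixels is modelled as Binomial with success probability
#' `1 - snow_curve(day, par)`; the five curve parameters are estimated by
#' maximizing the binomial log-likelihood (Nelder-Mead start from
#' moment-based initials, then BFGS polish). The snowmelt day is the 0.5
#' down-crossing of the fitted snow-cover fraction on the spring limb,
#' solved by bisection to 0.01-day tolerance.
#'
#' @param bin data frame with columns `pixel`, `day`, `snow` as produced by
#'   [binarize_ndsi()].
#' @param year calendar year label carried into the result.
#' @return An object of class `snow_curve_fit`: list with `year`, `par`
#'   (baseline, height, mu, sigma_l, sigma_r), `loglik`, `snowmelt_day`
#'   (NA when the optimizer failed), and `converged`.
#' @export
fit_snow_curve <- function(bin, year = NA_integer_) {
  stopifnot(all(c("day", "snow") %in% names(bin)))
  day <- sort(unique(bin$day))
  if (length(day) < 20L) stop("need >= 20 distinct day-points to fit the snow curve")
  agg <- data.frame(
    day = day,
    n = as.numeric(tapply(bin$snow, bin$day, length)),
    k = as.numeric(tapply(bin$snow, bin$day, sum))
  )
  frac_snow <- agg$k / agg$n
  if (all(frac_snow > 0.5) || all(frac_snow < 0.5)) {
    stop("no crossing: observed snow fraction never crosses 0.5")
  }
  if (min(frac_snow) == 1 || max(frac_snow) == 0) {
    stop("no crossing: input is all-snow or all-bare")
  }

  ## moment-based initials on the snow-free fraction
  f_free <- 1 - frac_snow
  peak <- max(f_free)
  mu0 <- median(agg$day[f_free >= 0.75 * peak])
  d50 <- agg$day[which(f_free >= 0.5)[1]]
  sigma_l0 <- max((mu0 - d50) / sqrt(2 * log(2)), 2)
  after <- agg$day > mu0 & f_free < 0.5
  sigma_r0 <- if (any(after)) max((agg$day[which(after)[1]] - mu0) / sqrt(2 * log(2)), 2) else sigma_l0
  base0 <- min(max(min(f_free), 0.005), 0.45)
  h0 <- min(max(peak - base0, 0.1), 1 - base0 - 1e-3)

  ## unconstrained parameterization: baseline in [0, .5), height in (0, 1-baseline]
  pack <- function(p) c(qlogis(p[1] / 0.5), qlogis(p[2] / (1 - p[1])), p[3], log(p[4]), log(p[5]))
  unpack <- function(th) {
    baseline <- 0.5 * plogis(th[1])
    height <- (1 - baseline) * plogis(th[2])
    c(baseline = baseline, height = height, mu = th[3],
      sigma_l = exp(th[4]), sigma_r = exp(th[5]))
  }
  negll <- function(th) {
    p <- unpack(th)
    pr <- 1 - snow_curve(agg$day, p)
    pr <- pmin(pmax(pr, 1e-9), 1 - 1e-9)
    -sum(agg$k * log(pr) + (agg$n - agg$k) * log(1 - pr))
  }
  th0 <- pack(c(base0, h0, mu0, sigma_l0, sigma_r0))
  o1 <- optim(th0, negll, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10))
  o2 <- suppressWarnings(optim(o1$par, negll, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-12)))
  o <- if (o2$value <= o1$value) o2 else o1
  par <- unpack(o$par)
  converged <- o$convergence == 0 && is.finite(o$value)

  snowmelt_day <- NA_real_
  if (converged) {
    f_snow <- function(t) 1 - snow_curve(t, par)
    lo <- min(agg$day); hi <- par[["mu"]]
    if (f_snow(lo) > 0.5 && f_snow(hi) < 0.5) {
      while (hi - lo > 0.01) {
        mid <- (lo + hi) / 2
        if (f_snow(mid) > 0.5) lo <- mid else hi <- mid
      }
      snowmelt_day <- (lo + hi) / 2
    } else {
      stop("no crossing: fitted snow curve does not cross 0.5 on the spring limb")
    }
  }

  structure(
    list(year = year, par = par, loglik = -o$value,
         snowmelt_day = snowmelt_day, converged = converged,
         n_days = nrow(agg)),
    class = "snow_curve_fit"
  )
}

#' @export
print.snow_curve_fit <- function(x, ...) {
  cat("Asymmetric-Gaussian snow curve fit", if (!is.na(x$year)) paste0("(", x$year, ")"), "\n")
  cat(sprintf("  snowmelt day (50%% crossing): %.2f\n", x$snowmelt_day))
  cat(sprintf("  mu = %.1f, sigma_l = %.1f, sigma_r = %.1f, baseline = %.3f, height = %.3f\n",
              x$par[["mu"]], x$par[["sigma_l"]], x$par[["sigma_r"]],
              x$par[["baseline"]], x$par[["height"]]))
  cat(sprintf("  logLik = %.1f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Local snowmelt date from ground snow-cover surveys
#'
#' Returns the first date at which surveyed snow cover drops below 50%,
#' using linear interpolation between survey visits. Later re-crossings
#' (refreeze followed by a second melt-out) are ignored: the first crossing
#' is the melt date.
#'
#' @param survey data frame with columns `date` (day-of-year) and `cover`
#'   (percent, 0-100).
#' @return Interpolated day-of-year of the first 50% down-crossing.
#' @examples
#' local_snowmelt(data.frame(date = c(10, 12), cover = c(60, 40)))  # 11
#' @export
local_snowmelt <- function(survey) {
  stopifnot(all(c("date", "cover") %in% names(survey)))
  if (any(survey$cover < 0 | survey$cover > 100)) stop("cover must be in [0, 100]")
  survey <- survey[order(survey$date), ]
  cv <- survey$cover; d <- survey$date
  if (!any(cv >= 50) || !any(cv < 50)) {
    stop("snow cover never crosses 50%: cannot determine local snowmelt")
  }
  for (i in seq_len(nrow(survey) - 1L)) {
    if (cv[i] >= 50 && cv[i + 1L] < 50) {
      if (cv[i] == 50) return(d[i])
      return(d[i] + (cv[i] - 50) / (cv[i] - cv[i + 1L]) * (d[i + 1L] - d[i]))
    }
  }
  stop("snow cover never crosses 50%: cannot determine local snowmelt")
}

#' Across-year trend in snowmelt date
#'
#' Ordinary least-squares regression of snowmelt day-of-year on year.
#'
#' @param melt data frame with columns `year` and `snowmelt_day`.
#' @return List with `slope` (days/year), `se`, `intercept`, and the fitted
#'   `lm` object (`fit`).
#' @export
snowmelt_trend <- function(melt) {
  stopifnot(all(c("year", "snowmelt_day") %in% names(melt)))
  melt <- melt[is.finite(melt$snowmelt_day), ]
  if (length(unique(melt$year)) < 3L) stop("need >= 3 years for a snowmelt trend")
  fit <- lm(snowmelt_day ~ year, data = melt)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)["year"]),
       se = unname(sm["year", "Std. Error"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       fit = fit)
}

#' Compare camp-measured and satellite-derived snowmelt dates
#'
#' Reports the mean offset (camp minus satellite) and the Pearson
#' correlation between the two series. The offset is reported for
#' diagnostics only and is never applied to the satellite dates, which
#' remain the dates used in analysis.
#'
#' @param camp,satellite data frames with columns `year` and `snowmelt_day`.
#' @return List with `mean_offset_days`, `sd_offset_days`, `pearson_r`, `n`.
#' @export
snowmelt_offset <- function(camp, satellite) {
  m <- merge(camp, satellite, by = "year", suffixes = c("_camp", "_sat"))
  if (nrow(m) < 2L) stop("need >= 2 common years to compare snowmelt dates")
  off <- m$snowmelt_day_camp - m$snowmelt_day_sat
  list(mean_offset_days = mean(off), sd_offset_days = sd(off),
       pearson_r = stats::cor(m$snowmelt_day_camp, m$snowmelt_day_sat),
       n = nrow(m))
}
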