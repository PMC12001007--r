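#' Synthetic source delta-15N table
#'
#' Family-level feather-diet source values for the seven key prey families,
#' with crane flies (Tipulidae) distinctly lowest — the feature that makes
#' a single-tracer mixing model informative about the crane-fly fraction.
#' Values are synthetic defaults for simulation and testing, not
#' measurements.
#'
#' @return Data frame with columns `family`, `d15n_mean`, `d15n_sd`
#'   (permil vs air).
#' @export
default_source_isotopes <- function() {
  data.frame(
    family = c("Tipulidae", "Chironomidae", "Muscidae", "Anthomyiidae",
               "Carabidae", "Linyphiidae", "Ichneumonidae"),
    d15n_mean = c(1.0, 4.5, 5.5, 6.0, 7.5, 8.0, 6.5),
    d15n_sd = c(0.5, 0.7, 0.8, 0.8, 0.9, 0.9, 0.8),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-study scenario configuration
#'
#' Defines every parameter of the synthetic data generator: the study
#' design dimensions, the snowmelt trend, hatch phenology, growth-curve
#' parameters per trait, prey phenology, diet composition and its trends,
#' isotope sources and discrimination, and the path-model coefficients.
#' Defaults reproduce the structure of a two-decade Arctic shorebird
#' study: snowmelt advancing by 0.87 days/year over 19 years, hatch at
#' July 12 +/- 4 days, a crane-fly peak 29 days after station snowmelt
#' with 4.9-day between-station SD, a 0.24%-per-day growth depression per
#' day of relative hatch date, and a crane-fly diet fraction declining by
#' 0.97 percentage points per year.
#'
#' @param years calendar year range (>= 2 years).
#' @param n_pixels satellite pixels per year (>= 1).
#' @param n_broods_per_year,chicks_per_brood,n_stations,n_juveniles_per_year
#'   design dimensions.
#' @param snowmelt_intercept regional snowmelt day-of-year in the first
#'   year.
#' @param snowmelt_trend days/year change of snowmelt day.
#' @param snowmelt_sd interannual SD (days) around the trend line.
#' @param local_offset_sd SD (days) of the local-grid melt day around the
#'   regional one.
#' @param pixel_melt_sd spatial SD (days) of per-pixel melt dates.
#' @param ndsi_noise_sd observation noise on NDSI values.
#' @param melt_ramp_width per-pixel NDSI melt ramp width (days).
#' @param snow_on_day,snow_on_sd autumn snow-onset day and its spatial SD.
#' @param hatch_mean,hatch_sd hatch-date distribution (day-of-year).
#' @param known_age_frac fraction of broods with known hatch dates.
#' @param cranefly_peak_lag days between station snowmelt and the crane-fly
#'   abundance peak.
#' @param cranefly_peak_sd between-station SD (days) of that lag.
#' @param cranefly_within_sd within-station SD (days) of the emergence
#'   curve.
#' @param cranefly_peak_height expected crane flies/trap/day at the peak.
#' @param growth_params named list per trait: `form`, `A`, `k`, `T`,
#'   `sd_k`, `sd_resid`.
#' @param p10_intercept,p10_slope,p10_sd linear 10th-primary growth used
#'   for age estimation (mm, mm/day).
#' @param condition_slope_per_rhd proportional size change per day of
#'   relative hatch date (fraction/day; -0.0024 is a 0.24%/day
#'   depression).
#' @param temp_mean,temp_sd daily summer temperature distribution (deg C).
#' @param temp_effect proportional size change per degree of 3-day
#'   pre-capture temperature (default 0).
#' @param diet_p0 crane-fly diet fraction in the first year.
#' @param diet_trend marginal change of that fraction per year
#'   (fraction/yr).
#' @param diet_snowmelt_effect structural change per day of snowmelt
#'   anomaly (fraction/day; positive = later melt, more crane flies).
#' @param diet_sd between-bird SD of the diet fraction.
#' @param chick_diet_rhd_slope change of chick diet fraction per day of
#'   relative hatch date (fraction/day).
#' @param n_chick_feathers number of tundra chicks with feather isotopes.
#' @param feces_concentration Dirichlet concentration of fecal diet
#'   fractions (low = sparse, metabarcoding-like samples).
#' @param source_isotopes source table, see [default_source_isotopes()].
#' @param discrimination discrimination table, see
#'   [discrimination_factors()].
#' @param sem_truth named list of path coefficients (standardized scale)
#'   and error SDs; the body-size equation entries generate juvenile body
#'   size, the full set serves SEM recovery simulations.
#' @param trait_map per-trait winter biometric mean, shared structural
#'   scale per body-size SD, and residual SD (mm).
#' @param seed master seed; per-table sub-seeds are derived from it.
#' @return Object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(
    years = 2003:2021,
    n_pixels = 200,
    n_broods_per_year = 25,
    chicks_per_brood = 4,
    n_stations = 45,
    n_juveniles_per_year = 30,
    snowmelt_intercept = 172,
    snowmelt_trend = -0.87,
    snowmelt_sd = 3,
    local_offset_sd = 1,
    pixel_melt_sd = 6,
    ndsi_noise_sd = 0.08,
    melt_ramp_width = 1.5,
    snow_on_day = 268,
    snow_on_sd = 4,
    hatch_mean = 193,
    hatch_sd = 4,
    known_age_frac = 0.6,
    cranefly_peak_lag = 29,
    cranefly_peak_sd = 4.9,
    cranefly_within_sd = 6,
    cranefly_peak_height = 1.5,
    growth_params = list(
      bill = list(form = "von_bertalanffy", A = 32.6, k = 0.045, T = -9, sd_k = 0.004, sd_resid = 0.45),
      tarsus = list(form = "logistic", A = 31.2, k = 0.22, T = -3.5, sd_k = 0.02, sd_resid = 0.5),
      mass = list(form = "logistic", A = 110, k = 0.25, T = 8, sd_k = 0.025, sd_resid = 3)
    ),
    p10_intercept = 1.5,
    p10_slope = 2.4,
    p10_sd = 0.5,
    condition_slope_per_rhd = -0.0024,
    temp_mean = 8,
    temp_sd = 3,
    temp_effect = 0,
    diet_p0 = 0.62,
    diet_trend = -0.0097,
    diet_snowmelt_effect = 0.0029,
    diet_sd = 0.25,
    chick_diet_rhd_slope = -0.006,
    n_chick_feathers = 37,
    feces_concentration = 1.2,
    source_isotopes = default_source_isotopes(),
    discrimination = discrimination_factors(),
    sem_truth = list(
      b2.2 = 0, b1.2 = -0.85,
      b3.3 = 0, b1.3 = -0.16, b2.3 = 0.065,
      b4.4 = -0.35, b1.4 = -0.15, b2.4 = 0.15, b3.4 = 0.25, b4.1 = 0.7,
      sigma_snowmelt = 0.52, sigma_prop = 0.98, sigma_body = 0.9
    ),
    trait_map = list(
      bill = list(mean = 32.6, scale = 0.95, resid = 1.29),
      tarsus = list(mean = 31.2, scale = 0.85, resid = 1.16),
      wing = list(mean = 165, scale = 3.0, resid = 4.1)
    ),
    seed = 1L) {
  cfg <- as.list(environment())
  sds <- c(cfg$snowmelt_sd, cfg$local_offset_sd, cfg$pixel_melt_sd,
           cfg$ndsi_noise_sd, cfg$snow_on_sd, cfg$hatch_sd,
           cfg$cranefly_peak_sd, cfg$cranefly_within_sd, cfg$p10_sd,
           cfg$temp_sd, cfg$diet_sd,
           vapply(cfg$growth_params, function(g) g$sd_k, 0),
           vapply(cfg$growth_params, function(g) g$sd_resid, 0),
           cfg$source_isotopes$d15n_sd, cfg$discrimination$sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (cfg$n_pixels < 1) stop("n_pixels must be >= 1")
  if (length(cfg$years) < 2) stop("years must span >= 2 years")
  if (cfg$diet_p0 < 0 || cfg$diet_p0 > 1) stop("diet_p0 must be in [0, 1]")
  if (cfg$known_age_frac < 0 || cfg$known_age_frac > 1) stop("known_age_frac must be in [0, 1]")
  class(cfg) <- "scenario_config"
  cfg
}

.year_index <- function(config, year) {
  i <- match(year, config$years)
  if (is.na(i)) {
    stop("year ", year, " outside the configured range ",
         min(config$years), "-", max(config$years))
  }
  i
}

## realized regional and local-grid snowmelt days, deterministic in the seed
.melt_days <- function(config) {
  set.seed(.sub_seed(config$seed, 101))
  n <- length(config$years)
  off <- config$years - config$years[1]
  melt <- config$snowmelt_intercept + config$snowmelt_trend * off +
    rnorm(n, 0, config$snowmelt_sd)
  local <- melt + rnorm(n, 0, config$local_offset_sd)
  data.frame(year = config$years, melt_day = melt, local_melt_day = local)
}

## daily summer air temperatures for one year, deterministic in the seed
.year_temps <- function(config, year) {
  i <- .year_index(config, year)
  set.seed(.sub_seed(config$seed, 500 + i))
  days <- 150:250
  data.frame(day = days, temp = rnorm(length(days), config$temp_mean, config$temp_sd))
}
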