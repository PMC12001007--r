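#' Generate one year of synthetic NDSI observations
#'
#' Each pixel melts on its own day (the regional melt day plus spatial
#' jitter) and carries an NDSI time series that ramps down through the 0.4
#' binarization threshold exactly at that day, with an autumn snow-onset
#' ramp late in the season and Gaussian observation noise, clamped to
#' \[0, 1\]. With noise SDs at zero a single pixel binarizes to a clean
#' step at its melt day. The regional 50% snow-cover crossing equals the
#' year's realized melt day recorded in the scenario truth.
#'
#' @param config a [scenario_config()].
#' @param year a year within the configured range.
#' @return Data frame with columns `pixel`, `day` (60-273), `ndsi`.
#' @export
gen_ndsi_year <- function(config, year) {
  i <- .year_index(config, year)
  melt <- .melt_days(config)$melt_day[i]
  set.seed(.sub_seed(config$seed, 200 + i))
  np <- config$n_pixels
  d_p <- melt + rnorm(np, 0, config$pixel_melt_sd)
  on_p <- config$snow_on_day + rnorm(np, 0, config$snow_on_sd)
  days <- 60:273
  pixel <- rep(seq_len(np), each = length(days))
  day <- rep(days, np)
  w <- config$melt_ramp_width
  base <- 0.8 / (1 + exp((day - d_p[pixel]) / w)) +
    0.8 / (1 + exp(-(day - on_p[pixel]) / w))
  ndsi <- .clamp(base + rnorm(length(day), 0, config$ndsi_noise_sd), 0, 1)
  data.frame(pixel = pixel, day = day, ndsi = ndsi)
}

#' Generate a local-grid snow-cover survey for one year
#'
#' Visual snow-cover estimates every 2 days around the local melt date,
#' following a logistic melt-out with small observation noise, so that the
#' interpolated 50% down-crossing falls at the year's local melt day.
#'
#' @param config a [scenario_config()].
#' @param year a year within the configured range.
#' @return Data frame with columns `year`, `date` (day-of-year), `cover`
#'   (percent).
#' @export
gen_snow_survey <- function(config, year) {
  i <- .year_index(config, year)
  local <- .melt_days(config)$local_melt_day[i]
  set.seed(.sub_seed(config$seed, 300 + i))
  dates <- seq(floor(local) - 20, floor(local) + 20, by = 2)
  cover <- 100 * plogis(-(dates - local) / 2.5) + rnorm(length(dates), 0, 2)
  data.frame(year = year, date = dates, cover = .clamp(cover, 0, 100))
}

#' Generate a longitudinal chick cohort for one year
#'
#' Broods hatch around the population hatch date (all chicks of a brood on
#' the same day); each chick carries per-trait growth-rate deviations and
#' is captured 1-3 times between ages 0 and 21 days. The whole trajectory
#' is scaled by `1 + condition_slope_per_rhd * RHD` (and by the optional
#' temperature effect), so chicks hatching later after snowmelt run below
#' the population curve by that fraction. The 10th primary grows linearly
#' with age, unaffected by the condition effect, which is what makes it a
#' usable age proxy.
#'
#' @param config a [scenario_config()].
#' @param year a year within the configured range.
#' @param n_broods number of broods (default from config).
#' @return List with `records` (one row per capture: `chick`, `brood`,
#'   `year`, `capture_day`, `age`, `age_known`, `bill`, `tarsus`, `p10`,
#'   `mass`, `sex`, `temp3d`, `hatch_day`, `rhd`) and `truth` (per-chick
#'   growth-rate deviations per trait, brood hatch days, the local melt
#'   day used).
#' @export
gen_chick_cohort <- function(config, year, n_broods = config$n_broods_per_year) {
  i <- .year_index(config, year)
  if (n_broods < 1) stop("n_broods must be >= 1")
  local_melt <- .melt_days(config)$local_melt_day[i]
  temps <- .year_temps(config, year)
  set.seed(.sub_seed(config$seed, 400 + i))
  gp <- config$growth_params
  rows <- list(); deltas <- lapply(gp, function(g) numeric(0))
  hatch_days <- numeric(0)
  for (b in seq_len(n_broods)) {
    hatch <- round(rnorm(1, config$hatch_mean, config$hatch_sd))
    known <- runif(1) < config$known_age_frac
    brood_id <- sprintf("%d_b%02d", year, b)
    hatch_days[brood_id] <- hatch
    rhd <- hatch - local_melt
    cond <- 1 + config$condition_slope_per_rhd * rhd
    ## broods are encountered and measured as a unit, so all chicks of a
    ## brood share the capture schedule (and hence age at capture)
    n_caps <- sample(1:3, 1)
    brood_ages <- cumsum(c(sample(0:12, 1), sample(2:6, n_caps, replace = TRUE)[seq_len(n_caps - 1)]))
    brood_ages <- brood_ages[brood_ages <= 21]
    for (cc in seq_len(config$chicks_per_brood)) {
      chick_id <- sprintf("%s_c%d", brood_id, cc)
      sex <- rbinom(1, 1, 0.5)
      dl <- vapply(gp, function(g) rnorm(1, 0, g$sd_k), 0)
      for (tr in names(gp)) {
        deltas[[tr]][chick_id] <- dl[[tr]]
      }
      for (age in brood_ages) {
        cday <- hatch + age
        t3 <- mean(temps$temp[match(cday - (1:3), temps$day)], na.rm = TRUE)
        tfac <- 1 + config$temp_effect * (t3 - config$temp_mean)
        meas <- vapply(names(gp), function(tr) {
          g <- gp[[tr]]
          mu <- growth_curve(age, g$form, g$A, g$k + dl[[tr]], g$T) * cond * tfac
          max(mu + rnorm(1, 0, g$sd_resid), 0.1)  # measurements are positive
        }, 0)
        p10 <- max(config$p10_intercept + config$p10_slope * age + rnorm(1, 0, config$p10_sd), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          chick = chick_id, brood = brood_id, year = year, capture_day = cday,
          age = age, age_known = known, bill = meas[["bill"]],
          tarsus = meas[["tarsus"]], p10 = p10, mass = meas[["mass"]],
          sex = sex, temp3d = t3, hatch_day = hatch, rhd = rhd)
      }
    }
  }
  list(records = do.call(rbind, rows),
       truth = list(deltas = deltas, hatch_days = hatch_days,
                    local_melt_day = local_melt))
}

.family_lengths <- c(Tipulidae = 18, Chironomidae = 4.6, Muscidae = 6.5,
                     Anthomyiidae = 6, Carabidae = 8, Linyphiidae = 2.5,
                     Ichneumonidae = 7)

#' Generate a pitfall-trapping season for one year
#'
#' Stations become snow-free around the local melt date (with strong
#' between-station spread); crane-fly daily counts follow a Gaussian
#' emergence curve peaking `cranefly_peak_lag` days after the
#' station-specific snow-free date (the lag itself varies between stations
#' with SD `cranefly_peak_sd`); six other arthropod families have their
#' own seasonal profiles. Counts are Poisson; biomass accumulates
#' individual body lengths through the family allometry.
#'
#' @param config a [scenario_config()].
#' @param year a year within the configured range.
#' @param n_stations number of stations (default from config).
#' @return List with `records` (daily rows: `station`, `year`, `snowfree`,
#'   `day`, `family`, `count`, `biomass_mg`) and `truth` (station
#'   snow-free days and realized peak lags).
#' @export
gen_pitfall_season <- function(config, year, n_stations = config$n_stations) {
  i <- .year_index(config, year)
  if (n_stations < 1) stop("n_stations must be >= 1")
  local_melt <- .melt_days(config)$local_melt_day[i]
  set.seed(.sub_seed(config$seed, 600 + i))
  allo <- default_allometry()
  sf <- round(local_melt + rnorm(n_stations, 0, 5))
  lag <- rnorm(n_stations, config$cranefly_peak_lag, config$cranefly_peak_sd)
  fams <- names(.family_lengths)
  rows <- vector("list", n_stations)
  for (s in seq_len(n_stations)) {
    days <- sf[s]:(sf[s] + 55)
    rel <- days - sf[s]
    lam <- rbind(
      Tipulidae = config$cranefly_peak_height *
        exp(-(rel - lag[s])^2 / (2 * config$cranefly_within_sd^2)),
      Chironomidae = 35 * exp(-(rel - 12)^2 / (2 * 12^2)),
      Muscidae = 2.0 * exp(-(rel - 20)^2 / (2 * 10^2)),
      Anthomyiidae = 1.0 * exp(-(rel - 18)^2 / (2 * 10^2)),
      Carabidae = rep(1.0, length(rel)),
      Linyphiidae = rep(1.5, length(rel)),
      Ichneumonidae = rep(0.4, length(rel))
    )
    cnt <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
    biom <- matrix(0, nrow(lam), ncol(lam))
    for (f in seq_along(fams)) {
      nz <- which(cnt[f, ] > 0)
      if (length(nz) > 0) {
        lens <- lapply(cnt[f, nz], function(n)
          pmax(rnorm(n, .family_lengths[[fams[f]]], 0.12 * .family_lengths[[fams[f]]]), 0.5))
        biom[f, nz] <- vapply(lens, function(L)
          sum(length_to_biomass(fams[f], L, allo)), 0)
      }
    }
    rows[[s]] <- data.frame(
      station = sprintf("st%02d", s), year = year, snowfree = sf[s],
      day = rep(days, each = length(fams)), family = rep(fams, length(days)),
      count = as.vector(cnt), biomass_mg = as.vector(biom))
  }
  list(records = do.call(rbind, rows),
       truth = list(snowfree = sf, peak_lag = lag, local_melt_day = local_melt))
}

#' Aggregate daily pitfall records into sampling intervals
#'
#' Emulates the field protocol in which a few stations are emptied daily
#' and the rest every 5 days: biomass is summed per interval with the
#' emptying day as `day_end`.
#'
#' @param records daily records from [gen_pitfall_season()].
#' @param daily_stations number of stations (taken in id order) emptied
#'   daily; the rest get 5-day intervals. Default 5.
#' @return Data frame with columns `station`, `family`, `day_end`,
#'   `interval_days`, `biomass_mg`.
#' @export
aggregate_pitfall <- function(records, daily_stations = 5) {
  st <- sort(unique(records$station))
  daily_ids <- head(st, daily_stations)
  out <- lapply(split(records, list(records$station, records$family), drop = TRUE),
                function(d) {
    d <- d[order(d$day), ]
    if (d$station[1] %in% daily_ids) {
      data.frame(station = d$station[1], family = d$family[1], day_end = d$day,
                 interval_days = 1, biomass_mg = d$biomass_mg)
    } else {
      rel <- d$day - d$snowfree[1]
      grp <- rel %/% 5
      agg <- tapply(d$biomass_mg, grp, sum)
      data.frame(station = d$station[1], family = d$family[1],
                 day_end = d$snowfree[1] + 5 * (as.integer(names(agg)) + 1),
                 interval_days = 5, biomass_mg = as.numeric(agg))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate feather delta-15N values from known diet proportions
#'
#' Feather value for a bird with source proportions `p`:
#' `sum p_k (mu_k + D)` plus Gaussian noise with variance
#' `sum p_k^2 (sigma_k^2 + sigma_D^2)` — the generative counterpart of the
#' mixing-model likelihood. With all SDs zero and a single source the
#' feather value is exactly `mu + D`.
#'
#' @param config a [scenario_config()].
#' @param diet_truth data frame with a `bird` column and one proportion
#'   column per source family (rows must sum to 1).
#' @param tissue `"juvenile_covert"` or `"chick_body"` (selects the
#'   discrimination factor).
#' @return List with `feathers` (`bird`, `tissue`, `d15n`) and `sources`
#'   (the config's source table with columns renamed for the mixing
#'   model).
#' @export
gen_isotope_data <- function(config, diet_truth, tissue = "juvenile_covert") {
  src <- config$source_isotopes
  fam <- src$family
  stopifnot("bird" %in% names(diet_truth))
  if (!all(fam %in% names(diet_truth))) {
    stop("diet_truth must have one proportion column per source family")
  }
  P <- as.matrix(diet_truth[, fam])
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop("per-bird proportions must sum to 1")
  disc <- config$discrimination
  j <- match(tissue, disc$tissue)
  if (is.na(j)) stop("unknown tissue: ", tissue)
  set.seed(.sub_seed(config$seed, 700 + j))
  mu <- P %*% (src$d15n_mean + disc$mean[j])
  vv <- (P^2) %*% (src$d15n_sd^2 + disc$sd[j]^2)
  d15n <- as.numeric(mu + rnorm(nrow(P), 0, sqrt(vv)))
  list(feathers = data.frame(bird = diet_truth$bird, tissue = tissue, d15n = d15n),
       sources = data.frame(family = fam, d15n_mean = src$d15n_mean,
                            d15n_sd = src$d15n_sd))
}

## crane-fly diet fraction per juvenile: marginal year trend `diet_trend`,
## structural snowmelt-anomaly effect `diet_snowmelt_effect`
.juvenile_diet <- function(config, year, melt_day) {
  off <- year - config$years[1]
  pred_melt <- config$snowmelt_intercept + config$snowmelt_trend * off
  mu <- config$diet_p0 + config$diet_trend * off +
    config$diet_snowmelt_effect * (melt_day - pred_melt)
  .clamp(mu + rnorm(length(year), 0, config$diet_sd), 0.01, 0.99)
}

## split (1 - p_cranefly) over the remaining sources with mild Dirichlet noise
.fill_other_sources <- function(config, p_cf) {
  fam <- config$source_isotopes$family
  others <- setdiff(fam, "Tipulidae")
  base <- c(Chironomidae = 0.45, Muscidae = 0.14, Anthomyiidae = 0.12,
            Carabidae = 0.1, Linyphiidae = 0.1, Ichneumonidae = 0.09)[others]
  g <- matrix(rgamma(length(p_cf) * length(others), shape = 8 * base), ncol = length(others),
              byrow = TRUE)
  g <- g / rowSums(g) * (1 - p_cf)
  out <- data.frame(Tipulidae = p_cf)
  out[others] <- as.data.frame(g)
  out[fam]
}

#' Generate winter juvenile biometrics consistent with the path model
#'
#' For each juvenile: year (Time), sex, the year's snowmelt day, a true
#' crane-fly diet fraction from the diet trend model, and a body-size
#' score generated from the body-size path equation
#' (`b1.4 Time + b2.4 Snowmelt + b3.4 PropCranefly + b4.1 Sex + error`, all
#' on standardized scales). The score is then mapped to bill, tarsus and
#' wing lengths with positive loadings, so PC1 of the winter biometrics
#' recovers it.
#'
#' @param config a [scenario_config()].
#' @param melt_days optional data frame `year`, `melt_day`; defaults to
#'   the scenario's realized melt days.
#' @return List with `juveniles` (`bird`, `year`, `sex`, `bill`, `tarsus`,
#'   `wing`, `snowmelt_day`) and `truth` (`body_z`, true `p_cranefly` per
#'   bird, the full diet-proportion table).
#' @export
gen_juvenile_biometrics <- function(config, melt_days = NULL) {
  if (is.null(melt_days)) melt_days <- .melt_days(config)[, c("year", "melt_day")]
  set.seed(.sub_seed(config$seed, 800))
  yrs <- rep(config$years, each = config$n_juveniles_per_year)
  n <- length(yrs)
  bird <- sprintf("juv%04d", seq_len(n))
  sex <- rbinom(n, 1, 0.5)
  melt <- melt_days$melt_day[match(yrs, melt_days$year)]
  p_cf <- .juvenile_diet(config, yrs, melt)
  st <- config$sem_truth
  tz <- as.numeric(scale(yrs))
  mz <- as.numeric(scale(melt))
  pz <- as.numeric(scale(p_cf))
  body_z <- st$b4.4 + st$b1.4 * tz + st$b2.4 * mz + st$b3.4 * pz +
    st$b4.1 * sex + rnorm(n, 0, st$sigma_body)
  bz <- body_z - mean(body_z)
  tm <- config$trait_map
  juv <- data.frame(
    bird = bird, year = yrs, sex = sex,
    bill = tm$bill$mean + tm$bill$scale * bz + rnorm(n, 0, tm$bill$resid),
    tarsus = tm$tarsus$mean + tm$tarsus$scale * bz + rnorm(n, 0, tm$tarsus$resid),
    wing = tm$wing$mean + tm$wing$scale * bz + rnorm(n, 0, tm$wing$resid),
    snowmelt_day = melt)
  props <- .fill_other_sources(config, p_cf)
  props <- cbind(bird = bird, props)
  list(juveniles = juv,
       truth = list(body_z = setNames(body_z, bird),
                    p_cranefly = setNames(p_cf, bird),
                    diet_props = props))
}

.feces_mean_diet <- c(Tipulidae = 0.548, Chironomidae = 0.201, Muscidae = 0.060,
                      Anthomyiidae = 0.045, Carabidae = 0.035, Linyphiidae = 0.030,
                      Ichneumonidae = 0.022, Sciaridae = 0.008, Mycetophilidae = 0.005)

#' Generate fecal diet-fraction samples
#'
#' Brood- and date-averaged metabarcoding read fractions per arthropod
#' family, Dirichlet-distributed around a mean diet dominated by crane
#' flies (54.8%) and non-biting midges (20.1%), with two minor families
#' below the 1% key-prey threshold and a small excluded-taxa remainder
#' (fractions sum to just under 1). The low Dirichlet concentration makes
#' individual samples sparse, as read-count data are.
#'
#' @param config a [scenario_config()].
#' @param n_samples number of samples (default 52).
#' @return Data frame with columns `sample`, `brood`, `day`, `family`,
#'   `fraction`.
#' @export
gen_feces <- function(config, n_samples = 52) {
  set.seed(.sub_seed(config$seed, 900))
  mean_diet <- c(.feces_mean_diet, other = 1 - sum(.feces_mean_diet))
  alpha <- config$feces_concentration * mean_diet / sum(mean_diet)
  local_melt <- .melt_days(config)$local_melt_day
  yr_pick <- sample(rev(seq_along(config$years))[1:2], n_samples, replace = TRUE)
  rows <- lapply(seq_len(n_samples), function(s) {
    g <- rgamma(length(alpha), shape = alpha)
    frac <- g / sum(g)
    day <- round(local_melt[yr_pick[s]] + runif(1, 15, 45))
    data.frame(sample = sprintf("fec%03d", s),
               brood = sprintf("%d_b%02d", config$years[yr_pick[s]], sample(1:20, 1)),
               day = day,
               family = names(mean_diet), fraction = as.numeric(frac))
  })
  out <- do.call(rbind, rows)
  out <- out[out$family != "other", ]  # excluded taxa leave the fractions summing < 1
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Generates all input tables of the analysis with one master seed:
#' NDSI series and local snow surveys per year, chick cohorts, pitfall
#' seasons for the last two years (daily and interval-aggregated), fecal
#' diet fractions, the isotope source table, winter juveniles with feather
#' values, and feather values for a subset of tundra chicks. Every
#' generating parameter actually realized is recorded in `truth`.
#'
#' @param config a [scenario_config()].
#' @param chick_years years with chick fieldwork (default: all).
#' @param pitfall_years years with pitfall trapping (default: last two).
#' @return List with `tables` (named list of data frames) and `truth`.
#' @export
simulate_scenario <- function(config,
                              chick_years = config$years,
                              pitfall_years = utils::tail(config$years, 2)) {
  stopifnot(inherits(config, "scenario_config"))
  md <- .melt_days(config)

  ndsi <- do.call(rbind, lapply(config$years, function(y) {
    cbind(year = y, gen_ndsi_year(config, y))
  }))
  survey <- do.call(rbind, lapply(config$years, function(y) gen_snow_survey(config, y)))

  chick_out <- lapply(chick_years, function(y) gen_chick_cohort(config, y))
  chicks <- do.call(rbind, lapply(chick_out, `[[`, "records"))
  chick_truth <- setNames(lapply(chick_out, `[[`, "truth"), chick_years)

  pit_out <- lapply(pitfall_years, function(y) gen_pitfall_season(config, y))
  pitfall_daily <- do.call(rbind, lapply(pit_out, `[[`, "records"))
  pitfall_samples <- do.call(rbind, lapply(pit_out, function(p)
    aggregate_pitfall(p$records)))
  pitfall_truth <- setNames(lapply(pit_out, `[[`, "truth"), pitfall_years)

  feces <- gen_feces(config)

  juv_out <- gen_juvenile_biometrics(config, md[, c("year", "melt_day")])
  iso_juv <- gen_isotope_data(config, juv_out$truth$diet_props, "juvenile_covert")
  juveniles <- juv_out$juveniles
  juveniles$d15n <- iso_juv$feathers$d15n[match(juveniles$bird, iso_juv$feathers$bird)]

  ## tundra chicks with feather isotopes: diet driven by relative hatch date
  set.seed(.sub_seed(config$seed, 950))
  first_caps <- chicks[!duplicated(chicks$chick), ]
  late <- first_caps[first_caps$year %in% utils::tail(chick_years, 2), ]
  pick <- late[sample(nrow(late), min(config$n_chick_feathers, nrow(late))), ]
  yr_mean_p <- .juvenile_diet(config, pick$year,
                              md$melt_day[match(pick$year, md$year)])  # draws noise too
  p_chick <- .clamp(yr_mean_p + config$chick_diet_rhd_slope * (pick$rhd - mean(pick$rhd)),
                    0.02, 0.95)
  chick_props <- .fill_other_sources(config, p_chick)
  chick_props <- cbind(bird = pick$chick, chick_props)
  iso_chick <- gen_isotope_data(config, chick_props, "chick_body")
  chick_feathers <- data.frame(bird = pick$chick, year = pick$year,
                               brood = pick$brood, rhd = pick$rhd,
                               tissue = "chick_body", d15n = iso_chick$feathers$d15n)

  truth <- list(
    config_seed = config$seed,
    melt_days = md,
    chick = chick_truth,
    pitfall = pitfall_truth,
    juvenile_body_z = juv_out$truth$body_z,
    juvenile_p_cranefly = juv_out$truth$p_cranefly,
    chick_p_cranefly = setNames(p_chick, pick$chick),
    sem_truth = config$sem_truth,
    growth_params = config$growth_params,
    snowmelt_trend = config$snowmelt_trend,
    diet_trend = config$diet_trend,
    cranefly_peak_lag = config$cranefly_peak_lag,
    condition_slope_per_rhd = config$condition_slope_per_rhd
  )

  list(tables = list(ndsi = ndsi, snow_survey = survey, chicks = chicks,
                     pitfall_daily = pitfall_daily,
                     pitfall_samples = pitfall_samples, feces = feces,
                     sources = iso_juv$sources, juveniles = juveniles,
                     chick_feathers = chick_feathers),
       truth = truth)
}

#' Write a simulated scenario to CSV files plus a truth record
#'
#' @param scenario output of [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(scenario$tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(scenario$tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  tf <- file.path(dir, "truth.yaml")
  write_truth(scenario$truth, tf)
  invisible(c(files, tf))
}

#' Save / load a scenario ground-truth record
#'
#' Structured text (YAML) with 17-digit numeric precision so that values
#' round-trip exactly.
#'
#' @param truth truth list from [simulate_scenario()].
#' @param path file path.
#' @return `write_truth` returns the path invisibly; `read_truth` the
#'   truth list.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(truth, path, precision = 17)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  yaml::read_yaml(path)
}
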