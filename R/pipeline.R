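#' Pipeline thresholds and sampler settings
#'
#' @param ndsi_threshold NDSI binarization threshold (default 0.4).
#' @param crossing snow-fraction crossing defining snowmelt (default 0.5).
#' @param key_prey_threshold mean diet fraction defining key prey
#'   (default 0.01).
#' @param delta_aicc AICc difference defining competitive models
#'   (default 2).
#' @param min_age youngest chick age (days) entering condition analyses
#'   (default 2).
#' @param chains,iter,burnin MCMC schedule for the mixing and path models.
#' @return Named list of validated settings.
#' @export
pipeline_settings <- function(ndsi_threshold = 0.4, crossing = 0.5,
                              key_prey_threshold = 0.01, delta_aicc = 2,
                              min_age = 2, chains = 4, iter = 10000,
                              burnin = 1000) {
  stopifnot(ndsi_threshold > 0, ndsi_threshold < 1,
            crossing > 0, crossing < 1,
            key_prey_threshold >= 0, key_prey_threshold < 1,
            delta_aicc > 0, min_age >= 0, chains >= 1, iter > burnin)
  as.list(environment())
}

.schemas <- list(
  ndsi = list(cols = c("pixel", "day", "ndsi"),
              checks = list(ndsi = function(d) d$ndsi < 0 | d$ndsi > 1,
                            day = function(d) d$day < 1 | d$day > 366)),
  snow_survey = list(cols = c("year", "date", "cover"),
                     checks = list(cover = function(d) d$cover < 0 | d$cover > 100)),
  chicks = list(cols = c("chick", "brood", "year", "capture_day", "age",
                         "age_known", "bill", "tarsus", "p10", "mass", "sex"),
                checks = list(age = function(d) !is.na(d$age) & d$age < 0,
                              mass = function(d) !is.na(d$mass) & d$mass <= 0,
                              tarsus = function(d) !is.na(d$tarsus) & d$tarsus <= 0)),
  pitfall_daily = list(cols = c("station", "year", "snowfree", "day", "family", "count"),
                       checks = list(count = function(d) d$count < 0)),
  pitfall_samples = list(cols = c("station", "family", "day_end", "interval_days",
                                  "biomass_mg"),
                         checks = list(interval_days = function(d) !d$interval_days %in% c(1, 5),
                                       biomass_mg = function(d) d$biomass_mg < 0)),
  feces = list(cols = c("sample", "day", "family", "fraction"),
               checks = list(fraction = function(d) d$fraction < 0 | d$fraction > 1)),
  sources = list(cols = c("family", "d15n_mean", "d15n_sd"),
                 checks = list(d15n_sd = function(d) d$d15n_sd < 0)),
  juveniles = list(cols = c("bird", "year", "sex", "bill", "tarsus", "wing"),
                   checks = list(sex = function(d) !d$sex %in% c(0, 1))),
  chick_feathers = list(cols = c("bird", "year", "brood", "rhd", "tissue", "d15n"),
                        checks = list(d15n = function(d) !is.finite(d$d15n)))
)

#' Validate pipeline input tables against their schemas
#'
#' Checks every supplied table for required columns (a missing column is a
#' hard error) and for value violations, reporting row counts and the
#' first offending rows per check.
#'
#' @param tables named list of data frames; recognized names are
#'   `ndsi`, `snow_survey`, `chicks`, `pitfall_daily`, `pitfall_samples`,
#'   `feces`, `sources`, `juveniles`, `chick_feathers`.
#' @return Object of class `validation_report`: data frame `report`
#'   (table, check, n_rows, n_bad, first_bad_row) and logical `valid`.
#' @export
validate_inputs <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  unknown <- setdiff(names(tables), names(.schemas))
  if (length(unknown) > 0) {
    warning("unrecognized table(s) skipped: ", paste(unknown, collapse = ", "))
  }
  rows <- list()
  for (nm in intersect(names(tables), names(.schemas))) {
    d <- tables[[nm]]
    sch <- .schemas[[nm]]
    miss <- setdiff(sch$cols, names(d))
    if (length(miss) > 0) {
      stop("table '", nm, "' is missing required column(s): ",
           paste(miss, collapse = ", "))
    }
    for (ck in names(sch$checks)) {
      bad <- which(sch$checks[[ck]](d))
      rows[[length(rows) + 1L]] <- data.frame(
        table = nm, check = ck, n_rows = nrow(d), n_bad = length(bad),
        first_bad_row = if (length(bad) > 0) bad[1] else NA_integer_)
    }
  }
  report <- do.call(rbind, rows)
  structure(list(report = report, valid = all(report$n_bad == 0)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Input validation:", if (x$valid) "all checks passed" else "VIOLATIONS FOUND", "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

.hash_obj <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(x, tf, compress = FALSE)
  unname(tools::md5sum(tf))
}

## growth stage helper: asymptote from winter juveniles as the mean of the
## male- and female-specific averages (corrects for unequal sex sampling)
.juvenile_asymptote <- function(juveniles, trait) {
  mean(tapply(juveniles[[trait]], juveniles$sex, mean, na.rm = TRUE))
}

#' Run the full demand-resource mismatch analysis pipeline
#'
#' Orchestrates the stages in causal order: snowmelt phenology (satellite
#' and local), chick growth and condition, prey availability and
#' electivity, isotope diet mixing and diet trends, and the path model
#' with its simulate-refit check. Inputs are validated first; every source
#' of randomness flows from `seed`; when `out_dir` is given all stage
#' outputs are written as CSV and a manifest with per-file checksums is
#' returned, so a rerun with identical inputs and seed is byte-identical.
#'
#' @param tables named list of input tables as in [validate_inputs()]
#'   (e.g. `simulate_scenario(...)$tables`).
#' @param seed integer seed governing all stochastic stages.
#' @param settings a [pipeline_settings()] list.
#' @param stages character vector of stages to run, a subset of
#'   `c("phenology", "growth", "diet", "mixing", "sem")`. A stage whose
#'   upstream requirement is disabled stops with a clear message.
#' @param out_dir optional output directory for stage CSVs and the
#'   manifest.
#' @return List with one element per executed stage plus `manifest`.
#' @export
run_pipeline <- function(tables, seed = 1, settings = pipeline_settings(),
                         stages = c("phenology", "growth", "diet", "mixing", "sem"),
                         out_dir = NULL) {
  all_stages <- c("phenology", "growth", "diet", "mixing", "sem")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- list(growth = "phenology", mixing = "phenology", sem = c("phenology", "mixing"))
  for (s in stages) {
    up <- setdiff(need[[s]], stages)
    if (length(up) > 0) {
      stop("stage '", s, "' requires output of disabled stage(s): ",
           paste(up, collapse = ", "))
    }
  }
  val <- validate_inputs(tables)
  if (!val$valid) {
    bad <- val$report[val$report$n_bad > 0, ][1, ]
    stop("validation failed: table '", bad$table, "', column '", bad$check,
         "', first offending row ", bad$first_bad_row)
  }
  res <- list(validation = val)
  outputs <- list()

  if ("phenology" %in% stages) {
    yrs <- sort(unique(tables$ndsi$year))
    fits <- lapply(yrs, function(y) {
      b <- binarize_ndsi(tables$ndsi[tables$ndsi$year == y, ],
                         threshold = settings$ndsi_threshold)
      fit_snow_curve(b, year = y)
    })
    melt <- data.frame(year = yrs,
                       snowmelt_day = vapply(fits, `[[`, 0, "snowmelt_day"),
                       converged = vapply(fits, `[[`, TRUE, "converged"))
    local <- do.call(rbind, lapply(split(tables$snow_survey, tables$snow_survey$year),
                                   function(d) data.frame(year = d$year[1],
                                                          local_melt_day = local_snowmelt(d))))
    trend <- snowmelt_trend(melt)
    res$phenology <- list(fits = fits, melt = merge(melt, local, all.x = TRUE),
                          trend = trend)
    outputs$melt_days <- res$phenology$melt
    outputs$snowmelt_trend <- data.frame(slope = trend$slope, se = trend$se,
                                         intercept = trend$intercept)
  }

  if ("growth" %in% stages) {
    ch <- tables$chicks
    melt <- res$phenology$melt
    ## ages: known broods keep field ages; unknown broods get p10-calibrated ages
    first <- ch[!duplicated(ch$chick), ]
    cal <- first[first$age_known & is.finite(first$age), c("age", "p10")]
    unk <- first[!first$age_known, c("chick", "brood", "p10")]
    if (nrow(unk) > 0 && nrow(cal) >= 5) {
      est <- estimate_age_from_p10(cal, unk)
      first_day <- setNames(first$capture_day, first$chick)
      age0 <- setNames(est$age_est, est$chick)
      unknown_rows <- !ch$age_known
      ch$age[unknown_rows] <- age0[ch$chick[unknown_rows]] +
        (ch$capture_day[unknown_rows] - first_day[ch$chick[unknown_rows]])
    }
    ch$hatch_est <- ch$capture_day - ch$age
    lm_by_year <- setNames(melt$local_melt_day, melt$year)
    ch$rhd_est <- relative_hatch_date(ch$hatch_est, lm_by_year[as.character(ch$year)])

    A_bill <- .juvenile_asymptote(tables$juveniles, "bill")
    A_tarsus <- .juvenile_asymptote(tables$juveniles, "tarsus")
    fits <- list(
      bill = fit_growth_model(ch, "bill", "von_bertalanffy", A_fixed = A_bill),
      tarsus = fit_growth_model(ch, "tarsus", "logistic", A_fixed = A_tarsus),
      mass = fit_growth_model(ch, "mass", "logistic")
    )
    cond <- lapply(fits, function(f) {
      ci <- condition_index(f, ch, min_age = settings$min_age)
      ci$condition_trait <- f$trait
      ci
    })
    reg <- lapply(cond, function(ci) {
      d <- data.frame(condition = ci$condition, rhd = ci$rhd_est,
                      temp3d = ci$temp3d, year = ci$year, chick = ci$chick)
      condition_regression(d)
    })
    res$growth <- list(asymptotes = c(bill = A_bill, tarsus = A_tarsus),
                       fits = fits, condition = cond, regressions = reg)
    outputs$growth_params <- do.call(rbind, lapply(fits, function(f)
      data.frame(trait = f$trait, form = f$form, A = f$A, k = f$k, T = f$T,
                 sd_k = f$sd_k, sd_resid = f$sd_resid)))
    outputs$condition_tarsus <- cond$tarsus[, c("chick", "year", "age",
                                                "predicted", "condition")]
    outputs$condition_models <- do.call(rbind, lapply(names(reg), function(nm)
      cbind(trait = nm, reg[[nm]]$table)))
  }

  if ("diet" %in% stages) {
    db <- interpolate_daily_biomass(tables$pitfall_samples)
    kp <- key_prey(tables$feces, threshold = settings$key_prey_threshold)
    iv <- ivlev_table(tables$feces[tables$feces$family %in% kp$family, ], db)
    cf <- cranefly_peak_timing(tables$pitfall_daily[
      tables$pitfall_daily$family == "Tipulidae", ])
    res$diet <- list(daily_biomass = db, key_prey = kp, ivlev = iv,
                     peak_timing = cf)
    outputs$daily_biomass <- db
    outputs$key_prey <- kp
    outputs$ivlev <- iv
    outputs$peak_timing <- cf$station_means
  }

  if ("mixing" %in% stages) {
    juv <- tables$juveniles
    feathers <- data.frame(bird = juv$bird, year = juv$year, sex = juv$sex,
                           d15n = juv$d15n)
    mix <- fit_mixing_model(feathers, tables$sources, tissue = "juvenile_covert",
                            chains = settings$chains, iter = settings$iter,
                            burnin = settings$burnin, seed = seed)
    props <- source_proportions(mix)
    melt <- res$phenology$melt
    props$snowmelt <- melt$snowmelt_day[match(props$year, melt$year)]
    trend <- diet_trend_juveniles(data.frame(prop = props$prop_mean,
                                             year = props$year,
                                             snowmelt = props$snowmelt,
                                             sex = props$sex))
    res$mixing <- list(fit = mix, proportions = props, trend = trend)
    if (!is.null(tables$chick_feathers)) {
      cfe <- tables$chick_feathers
      cmix <- fit_mixing_model(data.frame(bird = cfe$bird, d15n = cfe$d15n),
                               tables$sources, tissue = "chick_body",
                               chains = settings$chains, iter = settings$iter,
                               burnin = settings$burnin, seed = seed + 1)
      cprops <- source_proportions(cmix)
      cd <- data.frame(prop = cprops$prop_mean,
                       rhd = cfe$rhd[match(cprops$bird, cfe$bird)],
                       year = cfe$year[match(cprops$bird, cfe$bird)],
                       brood = cfe$brood[match(cprops$bird, cfe$bird)])
      res$mixing$chicks <- list(fit = cmix,
                                vs_hatch = diet_vs_hatch_chicks(cd))
    }
    outputs$mixing_summary <- mix$summary
    outputs$diet_trend_models <- trend$table
  }

  if ("sem" %in% stages) {
    juv <- tables$juveniles
    pca <- body_size_pc1(juv)
    props <- res$mixing$proportions
    melt <- res$phenology$melt
    dat <- data.frame(bird = juv$bird[pca$rows],
                      time = juv$year[pca$rows],
                      snowmelt = melt$snowmelt_day[match(juv$year[pca$rows], melt$year)],
                      prop_cranefly = props$prop_mean[match(juv$bird[pca$rows], props$bird)],
                      bodysize = pca$scores,
                      sex = juv$sex[pca$rows])
    std <- sem_standardize(dat)
    fit <- fit_path_model(std$data, chains = settings$chains,
                          iter = settings$iter, burnin = settings$burnin,
                          seed = seed + 2)
    check <- simulate_refit_check(fit, seed = seed + 3)
    res$sem <- list(pca = pca, data = std, fit = fit, refit_check = check)
    outputs$sem_summary <- fit$summary
    outputs$sem_refit_check <- check$report
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mismatchr")),
    seed = seed,
    settings = settings,
    stages = stages,
    input_hash = .hash_obj(tables),
    n_rows_in = vapply(tables, nrow, 0L)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (nm in names(outputs)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(outputs[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    manifest$checksums <- as.list(tools::md5sum(files))
    yaml::write_yaml(manifest[c("package_version", "seed", "stages",
                                "input_hash", "checksums")],
                     file.path(out_dir, "manifest.yaml"))
  }
  res$manifest <- manifest
  res
}
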