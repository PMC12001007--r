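#' Illustrative length-biomass allometry table
#'
#' Power-law coefficients `mass_mg = a * length_mm^b` per arthropod family,
#' organized in three tiers mirroring how such coefficients are sourced in
#' practice: measured at the study site (`site`), measured at another Arctic
#' site (`fallback_site`), or order-level literature values (`order`). The
#' values shipped here are illustrative defaults for synthetic work, not
#' field measurements; supply your own table for real data.
#'
#' @return Data frame with columns `family`, `a`, `b`, `tier`.
#' @export
default_allometry <- function() {
  data.frame(
    family = c("Tipulidae", "Chironomidae", "Muscidae", "Carabidae",
               "Linyphiidae", "Lycosidae", "Ichneumonidae",
               "Anthomyiidae", "Scathophagidae", "Syrphidae",
               "Diptera", "Coleoptera", "Araneae", "Hymenoptera"),
    a = c(0.0029, 0.0018, 0.0086, 0.0077,
          0.0050, 0.0460, 0.0031,
          0.0054, 0.0054, 0.0040,
          0.0054, 0.0077, 0.0500, 0.0056),
    b = c(2.68, 2.62, 2.61, 2.79,
          2.59, 2.34, 2.59,
          2.59, 2.59, 2.59,
          2.55, 2.79, 2.40, 2.46),
    tier = c(rep("site", 7), rep("fallback_site", 3), rep("order", 4)),
    stringsAsFactors = FALSE
  )
}

#' Convert arthropod body length to dry biomass
#'
#' Applies family-specific power-law allometry `m = a * L^b` (mg dry mass,
#' length in mm), preferring site-measured coefficients, then
#' fallback-site coefficients, then order-level ones.
#'
#' @param family arthropod family (scalar or vector recycled with
#'   `length_mm`).
#' @param length_mm body length in mm.
#' @param coefficients allometry table as from [default_allometry()];
#'   optionally an `order` column mapping each family to its order for
#'   order-tier lookup (otherwise order-tier rows are matched by name).
#' @return Numeric vector of dry masses in mg, with attribute `tier`
#'   recording the tier matched per element.
#' @export
length_to_biomass <- function(family, length_mm, coefficients = default_allometry()) {
  n <- max(length(family), length(length_mm))
  family <- rep_len(as.character(family), n)
  length_mm <- rep_len(length_mm, n)
  if (any(length_mm < 0)) stop("lengths must be >= 0")
  tier_order <- c("site", "fallback_site", "order")
  out <- numeric(n); tier <- character(n)
  for (i in seq_len(n)) {
    hit <- NULL
    for (tr in tier_order) {
      j <- which(coefficients$family == family[i] & coefficients$tier == tr)
      if (length(j) > 0) { hit <- j[1]; break }
    }
    if (is.null(hit)) stop("no allometry coefficients in any tier for family: ", family[i])
    out[i] <- coefficients$a[hit] * length_mm[i]^coefficients$b[hit]
    tier[i] <- coefficients$tier[hit]
  }
  attr(out, "tier") <- tier
  out
}

#' Daily prey biomass availability by linear interpolation
#'
#' Converts interval pitfall totals to daily availability. Five-day totals
#' are anchored at the average sampling date (emptying day minus 2.5) and
#' divided by 5; daily-collection records pass through unchanged. Anchors
#' are linearly interpolated to integer days per station and family
#' (constant extension outside the anchor range), then averaged over
#' stations to a per-trap daily series, with per-day availability
#' proportions over families.
#'
#' @param records data frame with columns `station`, `family`, `day_end`
#'   (emptying day-of-year), `interval_days` (1 or 5) and `biomass_mg`
#'   (total dry mass trapped over the interval).
#' @return Data frame with columns `day`, `family`, `biomass`
#'   (mg/trap/day) and `proportion` (share of all-family biomass that day).
#'   Attribute `anchors` holds the per-record anchor table (with
#'   `daily_value * interval_days` conserving each interval's total).
#' @export
interpolate_daily_biomass <- function(records) {
  need <- c("station", "family", "day_end", "interval_days", "biomass_mg")
  stopifnot(all(need %in% names(records)))
  if (any(!records$interval_days %in% c(1, 5))) {
    stop("interval_days must be 1 or 5")
  }
  anchors <- data.frame(
    station = records$station, family = records$family,
    day = ifelse(records$interval_days == 5, records$day_end - 2.5, records$day_end),
    daily_value = records$biomass_mg / records$interval_days,
    interval_days = records$interval_days,
    biomass_mg = records$biomass_mg
  )
  days <- seq(floor(min(anchors$day)), ceiling(max(anchors$day)))
  key <- interaction(anchors$station, anchors$family, drop = TRUE)
  pieces <- lapply(split(anchors, key), function(a) {
    if (nrow(a) == 1L) {
      warning("single sampling interval for station ", a$station[1], ", family ",
              a$family[1], ": constant daily value carried", call. = FALSE)
      val <- rep(a$daily_value, length(days))
    } else {
      val <- approx(a$day, a$daily_value, xout = days, rule = 2)$y
    }
    data.frame(station = a$station[1], family = a$family[1], day = days, value = val)
  })
  long <- do.call(rbind, pieces)
  agg <- stats::aggregate(value ~ day + family, data = long, FUN = mean)
  names(agg)[names(agg) == "value"] <- "biomass"
  tot <- stats::aggregate(biomass ~ day, data = agg, FUN = sum)
  names(tot)[2] <- "total"
  agg <- merge(agg, tot, by = "day")
  agg$proportion <- ifelse(agg$total > 0, agg$biomass / agg$total, NA_real_)
  agg$total <- NULL
  agg <- agg[order(agg$day, agg$family), ]
  rownames(agg) <- NULL
  attr(agg, "anchors") <- anchors
  agg
}

#' Ivlev electivity index
#'
#' `(O - E) / (O + E)` comparing the observed diet fraction `O` of a prey
#' family with its expected availability fraction `E`. Ranges over
#' \[-1, 1\]; positive values indicate preference, negative avoidance. When
#' both fractions are zero the index is undefined and returned as `NA`.
#'
#' @param O observed diet fraction(s) in \[0, 1\].
#' @param E expected availability fraction(s) in \[0, 1\].
#' @return Numeric vector of electivity values.
#' @examples
#' ivlev_index(0.6, 0.2)  # 0.5
#' @export
ivlev_index <- function(O, E) {
  if (any(O < 0 | O > 1 | E < 0 | E > 1, na.rm = TRUE)) {
    stop("O and E must be fractions in [0, 1]")
  }
  ifelse(O == 0 & E == 0, NA_real_, (O - E) / (O + E))
}

#' Electivity of diet samples against daily availability
#'
#' Matches each fecal diet fraction to the availability proportion of the
#' same family interpolated to the sample's collection day and computes the
#' Ivlev index.
#'
#' @param feces data frame with columns `sample`, `day`, `family`,
#'   `fraction`.
#' @param daily_biomass output of [interpolate_daily_biomass()].
#' @return Data frame with columns `sample`, `day`, `family`, `O`, `E`,
#'   `index`.
#' @export
ivlev_table <- function(feces, daily_biomass) {
  stopifnot(all(c("sample", "day", "family", "fraction") %in% names(feces)))
  E <- mapply(function(fam, dy) {
    j <- daily_biomass$family == fam & daily_biomass$day == dy
    if (any(j)) daily_biomass$proportion[which(j)[1]] else 0
  }, feces$family, feces$day)
  data.frame(sample = feces$sample, day = feces$day, family = feces$family,
             O = feces$fraction, E = E,
             index = ivlev_index(feces$fraction, E), row.names = NULL)
}

#' Identify key prey families
#'
#' Families whose mean fraction across diet samples exceeds the threshold
#' (1% by default). Samples in which a family does not occur count as zero.
#'
#' @param feces data frame with columns `sample`, `family`, `fraction`.
#' @param threshold mean-diet-fraction cutoff (default 0.01).
#' @return Data frame with `family` and `mean_fraction`, sorted by
#'   decreasing mean fraction.
#' @export
key_prey <- function(feces, threshold = 0.01) {
  stopifnot(all(c("sample", "family", "fraction") %in% names(feces)))
  if (nrow(feces) == 0L) stop("no diet samples supplied")
  n_samples <- length(unique(feces$sample))
  s <- stats::aggregate(fraction ~ family, data = feces, FUN = sum)
  s$mean_fraction <- s$fraction / n_samples
  s <- s[s$mean_fraction > threshold, c("family", "mean_fraction")]
  s <- s[order(-s$mean_fraction), ]
  rownames(s) <- NULL
  s
}

#' Timing of the crane-fly abundance peak relative to snowmelt
#'
#' Links daily crane-fly catches at each pitfall station to the number of
#' days after that station's snow-free date, bins abundance into 5-day
#' intervals starting at 0, computes per-station mean catch day after
#' snowmelt (stations without any catch are excluded), and tests for a
#' between-year difference in that metric with a Welch t-test. Catches
#' recorded before a station's snow-free day are dropped and counted.
#'
#' @param records data frame with columns `station`, `year`, `snowfree`
#'   (station-specific snow-free day-of-year), `day` (catch day-of-year)
#'   and `count`.
#' @param family unused label carried into the output (default
#'   `"Tipulidae"`).
#' @return List with `station_means` (station, year, mean_day, n_caught),
#'   `bins` (bin_start, count), `grand_mean`, `sd_between_stations`,
#'   `t_test` (a `htest`, or NULL with a warning when a year has fewer than
#'   2 qualifying stations), and `n_dropped_presnow`.
#' @export
cranefly_peak_timing <- function(records, family = "Tipulidae") {
  need <- c("station", "year", "snowfree", "day", "count")
  stopifnot(all(need %in% names(records)))
  if ("family" %in% names(records)) records <- records[records$family == family, ]
  records$after <- records$day - records$snowfree
  pre <- records$after < 0 & records$count > 0
  n_dropped <- sum(records$count[pre])
  if (n_dropped > 0) message(n_dropped, " catches before station snow-free day dropped")
  records <- records[records$after >= 0, ]

  bin_start <- 5 * (records$after %/% 5)
  bins <- stats::aggregate(records$count, by = list(bin_start = bin_start), FUN = sum)
  names(bins)[2] <- "count"

  per_station <- lapply(split(records, interaction(records$station, records$year, drop = TRUE)),
                        function(d) {
    n <- sum(d$count)
    if (n == 0) return(NULL)
    data.frame(station = d$station[1], year = d$year[1],
               mean_day = sum(d$after * d$count) / n, n_caught = n)
  })
  station_means <- do.call(rbind, per_station)
  if (is.null(station_means)) stop("no crane flies caught at any station")
  rownames(station_means) <- NULL

  yrs <- unique(station_means$year)
  t_test <- NULL
  if (length(yrs) == 2L) {
    n_by_year <- table(station_means$year)
    if (all(n_by_year >= 2L)) {
      t_test <- tryCatch(
        t.test(mean_day ~ year, data = station_means),
        error = function(e) {
          # zero within-group variance: identical groups, no difference
          list(statistic = c(t = 0), p.value = 1,
               method = "Welch Two Sample t-test (degenerate: zero variance)")
        })
    } else {
      warning("a year has < 2 stations with catches: t-test skipped")
    }
  } else if (length(yrs) > 2L) {
    warning("t-test requires exactly 2 years; skipped")
  }

  list(family = family, station_means = station_means, bins = bins,
       grand_mean = mean(station_means$mean_day),
       sd_between_stations = sd(station_means$mean_day),
       t_test = t_test, n_dropped_presnow = n_dropped)
}

#' Biomass equivalence between two prey types
#'
#' How many items of an alternative prey match the dry mass of one item of
#' a focal prey, e.g. the number of non-biting midges equivalent to a
#' single crane fly.
#'
#' @param focal_mass_mg dry mass of the focal prey item (mg).
#' @param alternative_mass_mg dry mass of the alternative prey item (mg).
#' @return `focal_mass_mg / alternative_mass_mg`.
#' @examples
#' round(biomass_equivalents(6.56, 0.10))  # about 66 midges per crane fly
#' @export
biomass_equivalents <- function(focal_mass_mg, alternative_mass_mg) {
  if (any(alternative_mass_mg <= 0)) stop("alternative prey mass must be positive")
  focal_mass_mg / alternative_mass_mg
}
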