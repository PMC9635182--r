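# Rule-based behaviour classification of 10-s temperature-depth-immersion
# streams. The rules are simple threshold rules applied to maximal runs of
# samples: depth >= 5 m defines diving; dry runs are flight (>= 60 s, cold)
# or leg-tucked rest (warm); bird-detected SST comes from thermally stable
# wet at-surface samples. A "day" is the UTC calendar day throughout.

.utc_date <- function(instant) as.Date(instant, tz = "UTC")

.infer_cadence <- function(timestamp) {
  d <- diff(as.numeric(timestamp))
  if (!length(d)) return(10)
  stats::median(d)
}

#' Detect dives from depth records
#'
#' A dive is a maximal run of consecutive samples with depth at or beyond
#' the threshold (default 5 m). Duration is the sample count times the
#' sampling interval; a dive spanning midnight is assigned to the UTC date
#' of its start.
#'
#' @param records Logger records (see [read_logger_records()]); may contain
#'   several birds.
#' @param threshold_m Depth threshold in metres (default 5).
#' @param cadence_s Sampling interval in seconds; inferred from the
#'   timestamps when `NULL`.
#' @return A `data.frame` with one row per dive: `bird_id`, `date`, `start`,
#'   `end`, `duration_min`, `max_depth_m`, `n_samples`, and a list column
#'   `temps` of in-dive temperature samples.
#' @export
detect_dives <- function(records, threshold_m = 5, cadence_s = NULL) {
  if (!nrow(records)) {
    return(data.frame(bird_id = character(), date = as.Date(character()),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_min = numeric(), max_depth_m = numeric(),
                      n_samples = integer()))
  }
  per_bird <- lapply(split(records, records$bird_id), function(r) {
    cad <- if (is.null(cadence_s)) .infer_cadence(r$timestamp) else cadence_s
    runs <- rle(r$depth >= threshold_m)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    if (!length(keep)) return(NULL)
    s <- starts[keep]; e <- ends[keep]
    data.frame(
      bird_id = r$bird_id[1],
      date = .utc_date(r$timestamp[s]),
      start = r$timestamp[s],
      end = r$timestamp[e] + cad,
      duration_min = (e - s + 1L) * cad / 60,
      max_depth_m = vapply(seq_along(s), function(i) max(r$depth[s[i]:e[i]]), 0),
      n_samples = e - s + 1L,
      temps = I(lapply(seq_along(s), function(i) r$temp[s[i]:e[i]]))
    )
  })
  out <- do.call(rbind, per_bird)
  if (is.null(out)) out <- detect_dives(records[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Daily in-dive water temperature range
#'
#' The 5th and 95th percentiles (linear-interpolation quantiles) of all
#' temperatures recorded during dives on one bird-day; used to bound which
#' samples can be at-surface when estimating SST.
#'
#' @param dive_temps Numeric vector of pooled in-dive temperatures for one
#'   bird-day.
#' @return Named numeric `c(lo, hi)`, or `c(NA, NA)` when there are no
#'   in-dive temperatures (SST is then undefined for the day).
#' @export
water_temp_range <- function(dive_temps) {
  dive_temps <- dive_temps[is.finite(dive_temps)]
  if (!length(dive_temps)) return(c(lo = NA_real_, hi = NA_real_))
  q <- stats::quantile(dive_temps, c(0.05, 0.95), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

.daily_water_ranges <- function(dives) {
  if (!nrow(dives)) {
    return(data.frame(bird_id = character(), date = as.Date(character()),
                      lo = numeric(), hi = numeric()))
  }
  sp <- split(dives, list(dives$bird_id, dives$date), drop = TRUE)
  out <- lapply(sp, function(d) {
    r <- water_temp_range(unlist(d$temps))
    data.frame(bird_id = d$bird_id[1], date = d$date[1], lo = r[["lo"]], hi = r[["hi"]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Identify at-surface samples
#'
#' A sample is at-surface when, jointly: the temperature range within the
#' centred 180-s window around it is below 0.5 deg C; it is not part of a
#' dive; the tag is wet; and its temperature lies within that day's in-dive
#' water temperature range widened by 1 deg C. Window membership is decided
#' by timestamp, so windows never span recording gaps artificially.
#'
#' @param records Logger records (single or multiple birds).
#' @param dives Dives from [detect_dives()].
#' @param window_s Full window width in seconds (default 180).
#' @param stability_c Maximum in-window temperature range (default 0.5).
#' @param margin_c Widening applied to the daily water range (default 1).
#' @param threshold_m Dive depth threshold used to flag in-dive samples.
#' @return Logical vector aligned with `records` rows.
#' @export
detect_surface_points <- function(records, dives, window_s = 180,
                                  stability_c = 0.5, margin_c = 1,
                                  threshold_m = 5) {
  n <- nrow(records)
  if (!n) return(logical(0))
  wr <- .daily_water_ranges(dives)
  key <- paste(records$bird_id, .utc_date(records$timestamp))
  idx <- match(key, paste(wr$bird_id, wr$date))
  lo <- wr$lo[idx]; hi <- wr$hi[idx]
  rng <- numeric(n)
  for (ii in split(seq_len(n), records$bird_id)) {
    rng[ii] <- sliding_time_range(as.numeric(records$timestamp[ii]),
                                  records$temp[ii], window_s / 2)
  }
  stable <- rng < stability_c
  not_diving <- records$depth < threshold_m
  in_range <- !is.na(lo) & records$temp >= lo - margin_c & records$temp <= hi + margin_c
  stable & not_diving & records$wet & in_range
}

#' Daily bird-detected SST
#'
#' Mean temperature over all at-surface samples of each bird-day; missing
#' when no sample qualifies that day.
#'
#' @param records Logger records.
#' @param surface_mask Logical mask from [detect_surface_points()].
#' @return Data frame `bird_id, date, sst_c, n_surface`.
#' @export
estimate_daily_sst <- function(records, surface_mask) {
  stopifnot(length(surface_mask) == nrow(records))
  key <- data.frame(bird_id = records$bird_id, date = .utc_date(records$timestamp))
  agg <- stats::aggregate(list(n_surface = surface_mask), key, sum)
  temps <- ifelse(surface_mask, records$temp, NA_real_)
  m <- stats::aggregate(list(sst_c = temps), key, function(x) mean(x, na.rm = TRUE))
  out <- merge(agg, m, by = c("bird_id", "date"))
  out$sst_c[out$n_surface == 0] <- NA_real_
  out[order(out$bird_id, out$date), c("bird_id", "date", "sst_c", "n_surface")]
}

#' Detect flight and leg-tucked resting
#'
#' Maximal dry runs are classified: a run lasting at least 60 s whose
#' maximum temperature stays below 7 deg C is flight; a dry run whose
#' maximum temperature exceeds 7 deg C is resting with the tagged leg
#' tucked into the plumage (which warms the tag above water temperature).
#' Short cold dry runs, and runs whose maximum is exactly 7 deg C, stay
#' unclassified and fall into the swimming residual.
#'
#' @param records Logger records.
#' @param min_dry_s Minimum dry duration for flight, seconds (default 60).
#' @param temp_thresh_c Flight/rest temperature threshold (default 7).
#' @param cadence_s Sampling interval; inferred when `NULL`.
#' @return Data frame of intervals: `bird_id, class, start, end, duration_s`
#'   with `class` in `{"flight", "rest"}`.
#' @export
detect_flight_and_rest <- function(records, min_dry_s = 60, temp_thresh_c = 7,
                                   cadence_s = NULL) {
  empty <- data.frame(bird_id = character(), class = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_s = numeric())
  if (!nrow(records)) return(empty)
  per_bird <- lapply(split(records, records$bird_id), function(r) {
    cad <- if (is.null(cadence_s)) .infer_cadence(r$timestamp) else cadence_s
    runs <- rle(!r$wet)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    if (!length(keep)) return(NULL)
    s <- starts[keep]; e <- ends[keep]
    dur <- (e - s + 1L) * cad
    mx <- vapply(seq_along(s), function(i) max(r$temp[s[i]:e[i]]), 0)
    cls <- ifelse(mx > temp_thresh_c, "rest",
           ifelse(dur >= min_dry_s & mx < temp_thresh_c, "flight", NA_character_))
    ok <- !is.na(cls)
    if (!any(ok)) return(NULL)
    data.frame(bird_id = r$bird_id[1], class = cls[ok],
               start = r$timestamp[s[ok]], end = r$timestamp[e[ok]] + cad,
               duration_s = dur[ok])
  })
  out <- do.call(rbind, per_bird)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Per-sample behaviour classes
#'
#' Assigns each sample to dive, flight, rest or swim. Diving takes
#' precedence (depth rule); dry samples get their dry-run class; everything
#' else is the swimming residual.
#'
#' @inheritParams detect_flight_and_rest
#' @param threshold_m Dive depth threshold in metres.
#' @return Factor vector with levels `dive, flight, rest, swim`, aligned
#'   with `records` rows.
#' @export
classify_samples <- function(records, threshold_m = 5, min_dry_s = 60,
                             temp_thresh_c = 7, cadence_s = NULL) {
  n <- nrow(records)
  cls <- rep("swim", n)
  cls[records$depth >= threshold_m] <- "dive"
  iv <- detect_flight_and_rest(records, min_dry_s, temp_thresh_c, cadence_s)
  if (nrow(iv)) {
    for (b in unique(iv$bird_id)) {
      ri <- which(records$bird_id == b)
      ivb <- iv[iv$bird_id == b, ]
      t <- as.numeric(records$timestamp[ri])
      for (k in seq_len(nrow(ivb))) {
        inside <- t >= as.numeric(ivb$start[k]) & t < as.numeric(ivb$end[k])
        cls[ri[inside]] <- ivb$class[k]
      }
    }
  }
  factor(cls, levels = c("dive", "flight", "rest", "swim"))
}

#' Daily activity budget
#'
#' Hours per UTC day spent flying, diving, resting (leg-tuck) and swimming
#' (the residual). Budgets are computed over the samples actually recorded,
#' so the four components always sum exactly to the day's coverage (24 h on
#' a gap-free day).
#'
#' @param records Logger records.
#' @param sample_class Optional precomputed factor from [classify_samples()].
#' @param cadence_s Sampling interval; inferred when `NULL`.
#' @param ... Passed to [classify_samples()] when `sample_class` is `NULL`.
#' @return Data frame `bird_id, date, t_fly_h, t_dive_h, t_rest_h, t_swim_h,
#'   coverage_h`.
#' @export
daily_activity_budget <- function(records, sample_class = NULL,
                                  cadence_s = NULL, ...) {
  if (is.null(sample_class)) sample_class <- classify_samples(records, cadence_s = cadence_s, ...)
  stopifnot(length(sample_class) == nrow(records))
  per_bird <- lapply(split(seq_len(nrow(records)), records$bird_id), function(ii) {
    cad <- if (is.null(cadence_s)) .infer_cadence(records$timestamp[ii]) else cadence_s
    date <- .utc_date(records$timestamp[ii])
    tab <- table(date, sample_class[ii])
    h <- as.data.frame.matrix(tab) * cad / 3600
    data.frame(bird_id = records$bird_id[ii[1]], date = as.Date(rownames(h)),
               t_fly_h = h$flight, t_dive_h = h$dive, t_rest_h = h$rest,
               t_swim_h = h$swim, coverage_h = rowSums(h))
  })
  out <- do.call(rbind, per_bird)
  rownames(out) <- NULL
  out
}

#' Assign a light category to each dive
#'
#' The category is that of the dive's start instant, evaluated at the
#' bird's mean daily position for the UTC date of the start.
#'
#' @param dives Dives from [detect_dives()].
#' @param positions Daily positions (`bird_id, date, lat, lon`).
#' @return `dives` with a `light_class` factor column (`NA` when the day's
#'   position is missing).
#' @export
assign_dive_light <- function(dives, positions) {
  if (!nrow(dives)) {
    dives$light_class <- factor(character(), levels = light_levels())
    return(dives)
  }
  idx <- match(paste(dives$bird_id, dives$date),
               paste(positions$bird_id, as.Date(positions$date)))
  lat <- positions$lat[idx]; lon <- positions$lon[idx]
  lc <- rep(NA_character_, nrow(dives))
  ok <- !is.na(lat) & !is.na(lon)
  if (any(ok)) {
    elev <- solar_elevation(lat[ok], lon[ok], dives$start[ok])
    lc[ok] <- as.character(classify_light(elev))
  }
  dives$light_class <- factor(lc, levels = light_levels())
  dives
}

#' Dive time per light category
#'
#' Splits each bird-day's total dive time across day, civil twilight,
#' nautical twilight and night by the light category of each dive's start,
#' and reports the corresponding proportions of total dive time.
#'
#' @param dives Dives carrying a `light_class` column (see
#'   [assign_dive_light()]).
#' @return Data frame `bird_id, date, dive_day_h, dive_civil_h, dive_naut_h,
#'   dive_night_h, n_dives` plus proportion columns `prop_*` (NA on days
#'   without dives or without a position).
#' @export
dive_time_by_light <- function(dives) {
  stopifnot("light_class" %in% names(dives))
  if (!nrow(dives)) {
    out <- data.frame(bird_id = character(), date = as.Date(character()),
                      dive_day_h = numeric(), dive_civil_h = numeric(),
                      dive_naut_h = numeric(), dive_night_h = numeric(),
                      n_dives = integer())
    return(out)
  }
  sp <- split(dives, list(dives$bird_id, dives$date), drop = TRUE)
  out <- lapply(sp, function(d) {
    h <- vapply(light_levels(), function(l) {
      sum(d$duration_min[!is.na(d$light_class) & d$light_class == l]) / 60
    }, 0)
    data.frame(bird_id = d$bird_id[1], date = d$date[1],
               dive_day_h = h[[1]], dive_civil_h = h[[2]],
               dive_naut_h = h[[3]], dive_night_h = h[[4]],
               n_dives = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  tot <- out$dive_day_h + out$dive_civil_h + out$dive_naut_h + out$dive_night_h
  for (l in c("day", "civil", "naut", "night")) {
    out[[paste0("prop_", l)]] <- ifelse(tot > 0, out[[paste0("dive_", l, "_h")]] / tot, NA_real_)
  }
  out[order(out$bird_id, out$date), , drop = FALSE]
}

#' Dive-depth histogram by light category
#'
#' Percentage of dives falling in 10-m maximum-depth bins for each light
#' category, optionally within groups (e.g. habitat state). Within each
#' group the percentages over all (bin, light category) cells sum to 100.
#'
#' @param dives Dives with `light_class` (and optionally a grouping column).
#' @param group Optional name of a grouping column in `dives`.
#' @param bin_m Bin width in metres (default 10).
#' @return Data frame `group, light_class, depth_bin_lo, pct`.
#' @export
dive_depth_histogram <- function(dives, group = NULL, bin_m = 10) {
  if (!nrow(dives)) {
    return(data.frame(group = character(), light_class = character(),
                      depth_bin_lo = numeric(), pct = numeric()))
  }
  g <- if (is.null(group)) rep("all", nrow(dives)) else as.character(dives[[group]])
  bin <- floor(dives$max_depth_m / bin_m) * bin_m
  sp <- split(seq_len(nrow(dives)), g)
  out <- lapply(names(sp), function(gn) {
    ii <- sp[[gn]]
    tab <- table(light_class = dives$light_class[ii], depth_bin_lo = bin[ii])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    data.frame(group = gn, light_class = df$light_class,
               depth_bin_lo = as.numeric(df$depth_bin_lo),
               pct = 100 * df$Freq / length(ii))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the per-bird-day summary table
#'
#' Runs the full rule-based classification: dive detection, SST estimation,
#' flight/rest detection, daily budgets and dive-time-by-light, and merges
#' the results into one row per bird-day.
#'
#' @param records Logger records.
#' @param positions Daily positions.
#' @param threshold_m,min_dry_s,temp_thresh_c,window_s,stability_c,margin_c
#'   Rule constants (defaults as documented in the individual functions).
#' @param cadence_s Sampling interval; inferred when `NULL`.
#' @return Data frame with one row per bird-day: budgets, SST, dive time by
#'   light category and dive counts. Energetics and habitat-state columns
#'   are added downstream.
#' @export
summarize_bird_days <- function(records, positions, threshold_m = 5,
                                min_dry_s = 60, temp_thresh_c = 7,
                                window_s = 180, stability_c = 0.5,
                                margin_c = 1, cadence_s = NULL) {
  dives <- detect_dives(records, threshold_m, cadence_s)
  mask <- detect_surface_points(records, dives, window_s, stability_c,
                                margin_c, threshold_m)
  sst <- estimate_daily_sst(records, mask)
  cls <- classify_samples(records, threshold_m, min_dry_s, temp_thresh_c, cadence_s)
  budget <- daily_activity_budget(records, cls, cadence_s)
  dives <- assign_dive_light(dives, positions)
  light <- dive_time_by_light(dives)
  out <- merge(budget, sst[, c("bird_id", "date", "sst_c")],
               by = c("bird_id", "date"), all.x = TRUE)
  out <- merge(out, light[, c("bird_id", "date", "dive_day_h", "dive_civil_h",
                              "dive_naut_h", "dive_night_h", "n_dives")],
               by = c("bird_id", "date"), all.x = TRUE)
  zero <- c("dive_day_h", "dive_civil_h", "dive_naut_h", "dive_night_h", "n_dives")
  for (cc in zero) out[[cc]][is.na(out[[cc]])] <- 0
  attr(out, "dives") <- dives
  out[order(out$bird_id, out$date), , drop = FALSE]
}
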