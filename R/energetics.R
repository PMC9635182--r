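# Activity-budget energetics. DEE combines a fixed flight cost, a per-dive
# cost that declines with dive duration, and SST-dependent costs of surface
# swimming and of resting on the water. AEI assumes energy balance over a
# 5-day window with 73% assimilation efficiency.

#' Energetics constants
#'
#' Coefficients of the activity-budget daily energy expenditure equation and
#' the apparent-energy-intake correction:
#' `DEE = 508 * T_f + 3.64 * sum(1 - d / exp(1.23)) +
#'  (113 - 2.75 * SST) * T_s + (72.2 - 2.75 * SST) * T_r`
#' with `T_f`, `T_s`, `T_r` in hours per day, each dive duration `d` in
#' minutes and SST in deg C, and `AEI = (DEE_5 / E) / Td_5` with
#' assimilation efficiency `E = 0.73` over a 5-day window.
#'
#' @param flight_kj_h Flight cost, kJ per hour flying.
#' @param dive_kj Per-dive cost scale, kJ.
#' @param dive_scale_min Dive-duration scale, minutes (`exp(1.23)`).
#' @param swim_base_kj_h Surface-swimming base cost, kJ/h at 0 deg C.
#' @param temp_slope_kj_h_c Thermal slope, kJ/h per deg C of SST.
#' @param rest_base_kj_h On-water resting base cost, kJ/h at 0 deg C.
#' @param assimilation Assimilation efficiency, in (0, 1].
#' @param window_days Moving-average window for DEE and dive time.
#' @return A named list of constants.
#' @export
energetics_constants <- function(flight_kj_h = 508, dive_kj = 3.64,
                                 dive_scale_min = exp(1.23),
                                 swim_base_kj_h = 113,
                                 temp_slope_kj_h_c = 2.75,
                                 rest_base_kj_h = 72.2,
                                 assimilation = 0.73, window_days = 5L) {
  stopifnot(flight_kj_h > 0, dive_kj > 0, dive_scale_min > 0,
            swim_base_kj_h > 0, temp_slope_kj_h_c > 0, rest_base_kj_h > 0,
            assimilation > 0, assimilation <= 1, window_days >= 1)
  list(flight_kj_h = flight_kj_h, dive_kj = dive_kj,
       dive_scale_min = dive_scale_min, swim_base_kj_h = swim_base_kj_h,
       temp_slope_kj_h_c = temp_slope_kj_h_c, rest_base_kj_h = rest_base_kj_h,
       assimilation = assimilation, window_days = as.integer(window_days))
}

#' Daily energy expenditure
#'
#' Evaluates the activity-budget DEE equation for one bird-day. The per-dive
#' term `3.64 * (1 - d / exp(1.23))` is applied exactly as specified, which
#' makes dives longer than about 3.42 min contribute negative energy; such
#' days are counted in the `n_negative_dive_terms` attribute rather than
#' silently clipped.
#'
#' @param t_fly_h Hours spent flying.
#' @param dive_durations_min Numeric vector of dive durations, minutes.
#' @param sst_c Sea surface temperature, deg C (`NA` gives `NA` DEE).
#' @param t_swim_h Hours actively swimming at the surface.
#' @param t_rest_h Hours resting on the water.
#' @param constants See [energetics_constants()].
#' @return DEE in kJ/day (`NA` when SST is missing).
#' @export
daily_dee <- function(t_fly_h, dive_durations_min, sst_c, t_swim_h, t_rest_h,
                      constants = energetics_constants()) {
  if (any(c(t_fly_h, t_swim_h, t_rest_h) < 0, na.rm = TRUE) ||
      any(dive_durations_min < 0)) {
    stop("negative time input to daily_dee", call. = FALSE)
  }
  if (is.na(sst_c)) return(NA_real_)
  dive_term <- constants$dive_kj *
    sum(1 - dive_durations_min / constants$dive_scale_min)
  out <- constants$flight_kj_h * t_fly_h + dive_term +
    (constants$swim_base_kj_h - constants$temp_slope_kj_h_c * sst_c) * t_swim_h +
    (constants$rest_base_kj_h - constants$temp_slope_kj_h_c * sst_c) * t_rest_h
  attr(out, "n_negative_dive_terms") <-
    sum(dive_durations_min > constants$dive_scale_min)
  out
}

#' Centred rolling mean over daily series
#'
#' Centred moving average with a minimum count of non-missing values per
#' window (windows with fewer yield `NA`). Intended for per-bird,
#' date-ordered daily series; never call it on concatenated birds.
#'
#' @param x Numeric series (may contain `NA`).
#' @param window Window width in days (default 5).
#' @param min_obs Minimum non-missing values required (default 3).
#' @return Numeric series of the same length.
#' @export
rolling_mean <- function(x, window = 5L, min_obs = 3L) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half):min(n, i + half)]
    if (sum(!is.na(w)) >= min_obs) out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Apparent energy intake rate
#'
#' `AEI = (DEE_5 / E) / Td_5`, kJ ingested per hour of diving, assuming
#' energy balance over the rolling window. Missing whenever either rolling
#' input is missing or the rolling dive time is zero.
#'
#' @param dee5_kj 5-day rolling mean DEE, kJ/day.
#' @param td5_h 5-day rolling mean daily dive time, hours.
#' @param constants See [energetics_constants()].
#' @return AEI in kJ per hour diving (vectorised).
#' @export
apparent_energy_intake <- function(dee5_kj, td5_h,
                                   constants = energetics_constants()) {
  out <- (dee5_kj / constants$assimilation) / td5_h
  out[is.na(dee5_kj) | is.na(td5_h) | td5_h == 0] <- NA_real_
  out
}

#' Add energetics columns to a daily summary table
#'
#' Computes per-day DEE from the budgets and dive durations, then the
#' centred 5-day rolling DEE and dive-time means and AEI, per bird.
#'
#' @param summaries Bird-day table from [summarize_bird_days()] (its
#'   `dives` attribute supplies per-dive durations; a `dives` argument can
#'   override it).
#' @param dives Optional dive table (`bird_id, date, duration_min`).
#' @param constants See [energetics_constants()].
#' @return `summaries` with `dee_kj`, `dee5_kj`, `td5_h`, `aei_kj_per_h`.
#' @export
add_energetics <- function(summaries, dives = NULL,
                           constants = energetics_constants()) {
  if (is.null(dives)) dives <- attr(summaries, "dives")
  if (is.null(dives)) stop("no dive table supplied", call. = FALSE)
  dive_key <- paste(dives$bird_id, dives$date)
  summaries$dee_kj <- vapply(seq_len(nrow(summaries)), function(i) {
    dd <- dives$duration_min[dive_key == paste(summaries$bird_id[i], summaries$date[i])]
    daily_dee(summaries$t_fly_h[i], dd, summaries$sst_c[i],
              summaries$t_swim_h[i], summaries$t_rest_h[i], constants)
  }, 0)
  out <- lapply(split(summaries, summaries$bird_id), function(s) {
    s <- s[order(s$date), , drop = FALSE]
    s$dee5_kj <- rolling_mean(s$dee_kj, constants$window_days)
    s$td5_h <- rolling_mean(s$t_dive_h, constants$window_days)
    s$aei_kj_per_h <- apparent_energy_intake(s$dee5_kj, s$td5_h, constants)
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "dives") <- dives
  out
}
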