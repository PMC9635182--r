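# Ground-truth simulator for winter logger datasets. Generates multi-bird
# 10-s temperature-depth-immersion streams from a known habitat-state
# sequence, with dive/flight/rest schedules structured by solar light
# category, so every downstream stage can be validated against a truth
# ledger without any external data.

#' Default per-state activity profiles
#'
#' Mean daily flight, dive and rest hours and the light-category dive
#' allocation for each habitat state (Cold, Warm, Warmer). Flight hours and
#' the light-category dive shares follow reported winter values for
#' thick-billed murres (Cold: more flight, 81% daylight dives; Warm: less
#' flight, 62% daylight with substantial nautical-twilight and night
#' diving); dive hours sit in the reported 3-6 h/day band. The Warmer
#' profile mirrors Warm (too few birds used that habitat for its budget to
#' be reported).
#'
#' @return A list of three profiles, each with `flight_h`, `dive_h`,
#'   `rest_h` and `light_alloc` (probabilities over
#'   day/civil/nautical/night, summing to 1).
#' @export
default_activity_profiles <- function() {
  list(
    cold = list(flight_h = 0.52, dive_h = 4.3, rest_h = 1.0,
                light_alloc = c(day = 0.81, civil_twilight = 0.10,
                                nautical_twilight = 0.05, night = 0.04)),
    warm = list(flight_h = 0.32, dive_h = 4.6, rest_h = 1.0,
                light_alloc = c(day = 0.62, civil_twilight = 0.12,
                                nautical_twilight = 0.12, night = 0.14)),
    warmer = list(flight_h = 0.32, dive_h = 4.6, rest_h = 1.0,
                  light_alloc = c(day = 0.62, civil_twilight = 0.12,
                                  nautical_twilight = 0.12, night = 0.14))
  )
}

#' Convert daily transition probabilities to logit intercepts
#'
#' Inverse of [transition_matrix()] for intercept-only models: given a 3x3
#' row-stochastic daily transition matrix, returns the 6 multinomial-logit
#' intercepts (`eta_ij = log(p_ij / p_ii)`).
#'
#' @param P 3x3 row-stochastic matrix.
#' @return 6 x 1 coefficient matrix in the standard transition row order.
#' @export
transition_intercepts_from_probs <- function(P) {
  stopifnot(all(dim(P) == c(3, 3)), all(abs(rowSums(P) - 1) < 1e-8),
            all(diag(P) > 0))
  eta <- numeric(6)
  k <- 1L
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    eta[k] <- log(P[i, j] / P[i, i])
    k <- k + 1L
  }
  matrix(eta, nrow = 6, dimnames = list(.transition_names(), "(Intercept)"))
}

#' Stationary distribution of a transition matrix
#' @param P Row-stochastic square matrix.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Reported daily transition probabilities between Cold and Warm water plus
# a slow-exit Warmer row consistent with the long but rare Warmer-water
# bouts (mean about 30 days among the birds that used it).
.default_transition_probs <- function() {
  P <- diag(3)
  P[1, 2] <- 0.033; P[1, 3] <- 0.001
  P[2, 1] <- 0.024; P[2, 3] <- 0.003
  P[3, 1] <- 0.008; P[3, 2] <- 0.025
  diag(P) <- 0
  diag(P) <- 1 - rowSums(P)
  P
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic winter logger dataset. Defaults
#' reproduce the study conditions: three thermal states with means/SDs of
#' -0.1/1.2, 3.1/0.3 and 6.5/2.4 deg C, the reported daily Cold-Warm
#' transition probabilities, winter activity profiles per state, birds
#' placed on the Labrador Shelf/Basin (55-60 N, 48-55 W) and a January
#' start.
#'
#' @param n_birds Number of birds.
#' @param start_date First day (UTC calendar date).
#' @param n_days Days per bird.
#' @param sample_interval_s Sampling interval, seconds; must divide 86400.
#' @param state_means,state_sds Emission means and SDs per state, deg C.
#' @param transition_coeffs Logit-scale coefficient block (6 x (1 + p)); by
#'   default the intercepts implied by the reported daily transition
#'   probabilities.
#' @param delta Initial state distribution; defaults to the stationary
#'   distribution of the intercept transition matrix.
#' @param activity_profiles See [default_activity_profiles()].
#' @param dive_duration Truncated log-normal dive-duration parameters
#'   (minutes): `meanlog`, `sdlog`, `min`, `max`.
#' @param depth_by_light Per light category, `c(mean, sd, min, max)` for
#'   truncated normal maximum dive depth (m); night and nautical twilight
#'   use shallow uniform-like draws by default.
#' @param nao_ar1 NAO daily AR(1): `c(mean, phi, sd)` (innovation SD).
#' @param sensor_noise_sd Temperature sensor noise SD, deg C.
#' @param flight_temp_c,rest_temp_c Dry-tag temperatures during flight
#'   (cold airstream) and leg-tucked rest (plumage), deg C; they sit on
#'   either side of the 7 deg C classification threshold.
#' @param descent_rate_m_s Vertical transit speed for the trapezoidal dive
#'   shape, m/s.
#' @param lat_range,lon_range Per-bird home position ranges, degrees.
#' @param rng_seed Integer seed; identical configs give identical output.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_birds = 5, start_date = as.Date("2019-01-01"),
                              n_days = 30, sample_interval_s = 10,
                              state_means = c(-0.1, 3.1, 6.5),
                              state_sds = c(1.2, 0.3, 2.4),
                              transition_coeffs =
                                transition_intercepts_from_probs(.default_transition_probs()),
                              delta = NULL,
                              activity_profiles = default_activity_profiles(),
                              dive_duration = c(meanlog = log(1.5), sdlog = 0.35,
                                                min = 0.5, max = 4),
                              depth_by_light = list(
                                day = c(mean = 70, sd = 20, min = 5, max = 140),
                                civil_twilight = c(mean = 35, sd = 15, min = 5, max = 80),
                                nautical_twilight = c(mean = 12, sd = 5, min = 5, max = 20),
                                night = c(mean = 12, sd = 5, min = 5, max = 20)),
                              nao_ar1 = c(mean = 0, phi = 0.8, sd = 0.6),
                              sensor_noise_sd = 0.05,
                              flight_temp_c = 2, rest_temp_c = 15,
                              descent_rate_m_s = 2,
                              lat_range = c(55, 60), lon_range = c(-55, -48),
                              rng_seed = 1L) {
  stopifnot(n_days >= 1, 86400 %% sample_interval_s == 0,
            all(state_sds > 0), length(state_means) == 3,
            abs(nao_ar1[["phi"]]) < 1)
  for (pr in activity_profiles) {
    stopifnot(abs(sum(pr$light_alloc) - 1) < 1e-8, all(pr$light_alloc >= 0))
  }
  if (is.null(dim(transition_coeffs))) {
    transition_coeffs <- matrix(transition_coeffs, nrow = 6,
                                dimnames = list(.transition_names(), "(Intercept)"))
  }
  if (is.null(delta)) {
    delta <- stationary_distribution(transition_matrix(
      transition_coeffs[, 1, drop = FALSE]))
  }
  structure(list(
    n_birds = as.integer(n_birds), start_date = as.Date(start_date),
    n_days = as.integer(n_days), sample_interval_s = sample_interval_s,
    state_means = state_means, state_sds = state_sds,
    transition_coeffs = transition_coeffs, delta = delta,
    activity_profiles = activity_profiles, dive_duration = dive_duration,
    depth_by_light = depth_by_light, nao_ar1 = nao_ar1,
    sensor_noise_sd = sensor_noise_sd, flight_temp_c = flight_temp_c,
    rest_temp_c = rest_temp_c, descent_rate_m_s = descent_rate_m_s,
    lat_range = lat_range, lon_range = lon_range,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

.sim_seed <- function(config, offset) {
  as.integer((abs(config$rng_seed) + offset) %% 2147483646L + 1L)
}

#' Simulate the daily covariate series
#'
#' Day-of-year from the calendar; moon illumination from
#' [moon_fraction()]; NAO as a stationary AR(1) draw with the configured
#' mean, autocorrelation and innovation SD (initialised from the stationary
#' distribution); year coded 0/1 against the first calendar year.
#'
#' @param config A [simulation_config()].
#' @return Data frame `date, year, doy, moon, nao`, one row per day.
#' @export
simulate_covariates <- function(config) {
  stopifnot(abs(config$nao_ar1[["phi"]]) < 1)
  set.seed(.sim_seed(config, 101))
  dates <- config$start_date + seq_len(config$n_days) - 1L
  phi <- config$nao_ar1[["phi"]]
  m <- config$nao_ar1[["mean"]]
  s <- config$nao_ar1[["sd"]]
  n <- config$n_days
  nao <- numeric(n)
  nao[1] <- m + if (s > 0) stats::rnorm(1, 0, s / sqrt(1 - phi^2)) else 0
  if (n > 1) for (t in 2:n) {
    nao[t] <- m + phi * (nao[t - 1] - m) + stats::rnorm(1, 0, s)
  }
  yr <- as.integer(format(dates, "%Y"))
  data.frame(
    date = dates,
    year = as.numeric(yr - min(yr) > 0),
    doy = as.integer(format(dates, "%j")),
    moon = moon_fraction(dates),
    nao = nao
  )
}

#' Simulate a bird's daily habitat-state sequence
#'
#' First state from the initial distribution, then each day's state drawn
#' from the row of the multinomial-logit transition matrix evaluated at
#' that day's covariates (the same construction as
#' [transition_matrix()]).
#'
#' @param config A [simulation_config()].
#' @param covariates Output of [simulate_covariates()].
#' @param bird Bird index (drives the per-bird seed).
#' @return Integer vector of states (1 = Cold, 2 = Warm, 3 = Warmer).
#' @export
simulate_state_sequence <- function(config, covariates, bird = 1L) {
  stopifnot(nrow(covariates) >= config$n_days)
  set.seed(.sim_seed(config, 1000 + 7919 * bird))
  covariate_set <- colnames(config$transition_coeffs)[-1]
  X <- .design_matrix(covariates, covariates$date[seq_len(config$n_days)],
                      covariate_set)
  G <- .gamma_array(config$transition_coeffs, X)
  st <- integer(config$n_days)
  st[1] <- sample.int(3, 1, prob = config$delta)
  if (config$n_days > 1) for (t in 2:config$n_days) {
    st[t] <- sample.int(3, 1, prob = G[st[t - 1L], , t])
  }
  st
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

.rdive_durations <- function(n, dd) {
  x <- exp(stats::rnorm(n, dd[["meanlog"]], dd[["sdlog"]]))
  pmin(pmax(x, dd[["min"]]), dd[["max"]])
}

# remaining free-run length at each index (0 where occupied)
.free_run_len <- function(free) {
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(length(free))
  for (k in which(r$values)) {
    out[starts[k]:ends[k]] <- ends[k] - (starts[k]:ends[k]) + 1L
  }
  out
}

#' Simulate logger records for one bird
#'
#' Tiles each day with dive, flight, rest and swimming intervals drawn from
#' the state's activity profile. Dives are trapezoidal depth excursions
#' whose start samples fall in light categories drawn from the state's
#' allocation probabilities (evaluated from solar elevation at the bird's
#' daily position); the tag is wet except during flight and leg-tucked
#' rest; wet temperature is true SST plus sensor noise, dry temperature
#' sits below the 7 deg C rule in flight and above it at rest. A day whose
#' allocation requests a light category that never occurs at the simulated
#' latitude (e.g. daylight during polar night) raises a schedule-infeasible
#' error naming the bird and date.
#'
#' @param config A [simulation_config()].
#' @param states Daily state sequence from [simulate_state_sequence()].
#' @param covariates Covariate table (dates).
#' @param bird Bird index.
#' @return A list: `records` (logger stream), `positions` (daily mean
#'   positions), `truth_days` (per-day ledger: state, true SST, realized
#'   behaviour hours and dive counts), `truth_dives` (per-dive ledger) and
#'   `truth_intervals` (scheduled behaviour intervals tiling each day).
#' @export
simulate_logger_records <- function(config, states, covariates, bird = 1L) {
  stopifnot(length(states) == config$n_days)
  set.seed(.sim_seed(config, 2000 + 104729 * bird))
  iv <- config$sample_interval_s
  ns <- 86400 %/% iv
  bird_id <- sprintf("bird%02d", bird)
  base_lat <- stats::runif(1, config$lat_range[1], config$lat_range[2])
  base_lon <- stats::runif(1, config$lon_range[1], config$lon_range[2])
  lv <- light_levels()
  prof_all <- config$activity_profiles
  dates <- config$start_date + seq_len(config$n_days) - 1L

  rec_list <- vector("list", config$n_days)
  pos_list <- vector("list", config$n_days)
  day_list <- vector("list", config$n_days)
  dive_list <- vector("list", config$n_days)
  int_list <- vector("list", config$n_days)

  for (d in seq_len(config$n_days)) {
    state <- states[d]
    prof <- prof_all[[state]]
    date <- dates[d]
    day_start <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
    times <- day_start + (seq_len(ns) - 1L) * iv

    jit <- stats::rnorm(2, 0, 0.05)
    dawn <- c(base_lat + jit[1] + 0.02, base_lon + jit[2] - 0.02)
    dusk <- c(base_lat + jit[1] - 0.02, base_lon + jit[2] + 0.02)
    pos <- mean_daily_position(dawn, dusk)

    light <- classify_light(solar_elevation(pos$lat, pos$lon, times))
    alloc <- prof$light_alloc
    present <- table(factor(as.character(light), levels = lv)) > 0
    if (any(alloc > 0 & !present)) {
      stop(sprintf("schedule infeasible for %s on %s: no %s at lat %.1f",
                   bird_id, format(date),
                   paste(lv[alloc > 0 & !present], collapse = "/"), pos$lat),
           call. = FALSE)
    }

    free <- rep(TRUE, ns)
    beh <- rep("swim", ns)

    place_run <- function(len, mask) {
      # place a run of `len` samples starting where `mask` holds, with a
      # 1-sample buffer on each side so dry runs and dives never merge;
      # returns the start index or NA
      r <- .free_run_len(free)
      ok_prev <- c(FALSE, free[-ns] & r[-ns] >= len + 2L)
      cand <- which(mask & ok_prev)
      if (!length(cand)) return(NA_integer_)
      s <- if (length(cand) == 1L) cand else sample(cand, 1L)
      free[(s - 1L):(s + len)] <<- FALSE
      s
    }

    # dry bouts: flight (short cold runs >= 60 s) and leg-tucked rest
    schedule_dry <- function(total_h, bout_range_min, class) {
      remaining <- total_h * 60
      while (remaining >= bout_range_min[1]) {
        bout <- min(stats::runif(1, bout_range_min[1], bout_range_min[2]),
                    remaining)
        len <- max(as.integer(round(bout * 60 / iv)),
                   as.integer(ceiling(60 / iv)))
        s <- place_run(len, rep(TRUE, ns))
        if (is.na(s)) break
        beh[s:(s + len - 1L)] <<- class
        remaining <- remaining - len * iv / 60
      }
    }
    if (prof$flight_h > 0) {
      schedule_dry(.rtrunc_norm(1, prof$flight_h, 0.25 * prof$flight_h,
                                0, 3 * prof$flight_h + 0.1),
                   c(5, 20), "flight")
    }
    if (prof$rest_h > 0) {
      schedule_dry(.rtrunc_norm(1, prof$rest_h, 0.25 * prof$rest_h,
                                0, 3 * prof$rest_h + 0.1),
                   c(10, 60), "rest")
    }

    # dives: durations until the day's target dive time is reached
    target_min <- .rtrunc_norm(1, prof$dive_h, 0.3, 0.5, 12) * 60
    durations <- .rdive_durations(ceiling(target_min / config$dive_duration[["min"]]),
                                  config$dive_duration)
    durations <- durations[cumsum(durations) <= target_min + durations[1]]
    dive_rows <- list()
    for (dur in durations) {
      len <- max(as.integer(round(dur * 60 / iv)), 3L)
      cls_i <- sample.int(4, 1, prob = alloc)
      s <- NA_integer_
      for (try in 1:25) {
        s <- place_run(len, as.integer(light) == cls_i)
        if (!is.na(s)) break
        cls_i <- sample.int(4, 1, prob = alloc)
      }
      if (is.na(s)) next # congestion; dive dropped (ledger sees only placed dives)
      e <- s + len - 1L
      beh[s:e] <- "dive"
      depth_par <- config$depth_by_light[[lv[cls_i]]]
      D <- .rtrunc_norm(1, depth_par[["mean"]], depth_par[["sd"]],
                        depth_par[["min"]], depth_par[["max"]])
      prof_depth <- pmin(config$descent_rate_m_s * iv * seq_len(len),
                         config$descent_rate_m_s * iv * (len - seq_len(len) + 1L),
                         D)
      dive_rows[[length(dive_rows) + 1L]] <- list(
        s = s, len = len, depth = prof_depth,
        row = data.frame(bird_id = bird_id, date = date,
                         start = times[s], end = times[e] + iv,
                         duration_min = len * iv / 60,
                         max_depth_m = max(prof_depth),
                         light_class = lv[cls_i])
      )
    }

    true_sst <- stats::rnorm(1, config$state_means[state],
                             config$state_sds[state])
    noise <- if (config$sensor_noise_sd > 0) {
      stats::rnorm(ns, 0, config$sensor_noise_sd)
    } else rep(0, ns)
    temp <- true_sst + noise
    temp[beh == "flight"] <- config$flight_temp_c + noise[beh == "flight"]
    temp[beh == "rest"] <- config$rest_temp_c + noise[beh == "rest"]
    depth <- numeric(ns)
    for (dv in dive_rows) depth[dv$s:(dv$s + dv$len - 1L)] <- dv$depth
    wet <- !(beh %in% c("flight", "rest"))

    rec_list[[d]] <- data.frame(
      bird_id = bird_id, timestamp = times, depth = depth, temp = temp,
      wet = wet, light_raw = NA_real_
    )
    pos_list[[d]] <- data.frame(bird_id = bird_id, date = date,
                                lat = pos$lat, lon = pos$lon,
                                source = pos$source)
    dives_df <- if (length(dive_rows)) {
      do.call(rbind, lapply(dive_rows, `[[`, "row"))
    } else NULL
    dive_list[[d]] <- dives_df
    cnt <- function(cl) if (is.null(dives_df)) 0 else sum(dives_df$light_class == cl)
    day_list[[d]] <- data.frame(
      bird_id = bird_id, date = date, state = state, true_sst = true_sst,
      flight_h = sum(beh == "flight") * iv / 3600,
      dive_h = sum(beh == "dive") * iv / 3600,
      rest_h = sum(beh == "rest") * iv / 3600,
      swim_h = sum(beh == "swim") * iv / 3600,
      n_dives = if (is.null(dives_df)) 0L else nrow(dives_df),
      dives_day = cnt("day"), dives_civil = cnt("civil_twilight"),
      dives_naut = cnt("nautical_twilight"), dives_night = cnt("night")
    )
    rr <- rle(beh)
    re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1L
    int_list[[d]] <- data.frame(
      bird_id = bird_id, date = date, class = rr$values,
      start = times[rs], end = times[re] + iv
    )
  }

  list(
    records = do.call(rbind, rec_list),
    positions = do.call(rbind, pos_list),
    truth_days = do.call(rbind, day_list),
    truth_dives = do.call(rbind, dive_list),
    truth_intervals = do.call(rbind, int_list)
  )
}

#' Simulate a full multi-bird dataset
#'
#' Runs [simulate_covariates()], [simulate_state_sequence()] and
#' [simulate_logger_records()] for every bird and binds the results.
#' Identical configurations (including the seed) give identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with `records`, `positions`, `covariates`, `truth_days`,
#'   `truth_dives`, `truth_intervals` and the `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  covariates <- simulate_covariates(config)
  parts <- lapply(seq_len(config$n_birds), function(b) {
    states <- simulate_state_sequence(config, covariates, b)
    simulate_logger_records(config, states, covariates, b)
  })
  bind <- function(name) do.call(rbind, lapply(parts, `[[`, name))
  out <- list(records = bind("records"), positions = bind("positions"),
              covariates = covariates, truth_days = bind("truth_days"),
              truth_dives = bind("truth_dives"),
              truth_intervals = bind("truth_intervals"), config = config)
  rownames(out$records) <- NULL
  out
}

#' Simulate daily SST series only
#'
#' Fast path for HMM experiments: draws per-bird state sequences and daily
#' SST from the emission model, without rendering logger streams.
#'
#' @param config A [simulation_config()].
#' @return A list: `sst` (data frame `bird_id, date, sst`), `states`
#'   (`bird_id, date, state`), `covariates`.
#' @export
simulate_daily_sst <- function(config = simulation_config()) {
  covariates <- simulate_covariates(config)
  out <- lapply(seq_len(config$n_birds), function(b) {
    st <- simulate_state_sequence(config, covariates, b)
    set.seed(.sim_seed(config, 3000 + 15485863 * b))
    y <- stats::rnorm(config$n_days, config$state_means[st],
                      config$state_sds[st])
    data.frame(bird_id = sprintf("bird%02d", b),
               date = covariates$date[seq_len(config$n_days)],
               state = st, sst = y)
  })
  out <- do.call(rbind, out)
  list(sst = out[, c("bird_id", "date", "sst")],
       states = out[, c("bird_id", "date", "state")],
       covariates = covariates)
}
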