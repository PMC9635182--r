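test_that("covariate simulation: degenerate, periodic and AR(1) behaviour", {
  cfg <- simulation_config(n_days = 40, nao_ar1 = c(mean = 0, phi = 0.5, sd = 0))
  cov <- simulate_covariates(cfg)
  expect_equal(cov$nao, rep(0, 40)) # zero-innovation AR(1) sits at its mean
  expect_equal(cov$doy, 1:40)
  expect_true(all(cov$moon >= 0 & cov$moon <= 1))
  expect_lt(max(abs(diff(cov$moon))), 0.25) # lunar phase is continuous

  # sample lag-1 autocorrelation of a long AR(1) draw matches phi
  cfg2 <- simulation_config(n_days = 10000,
                            nao_ar1 = c(mean = 0, phi = 0.8, sd = 0.5),
                            rng_seed = 21)
  nao <- simulate_covariates(cfg2)$nao
  r1 <- cor(nao[-1], nao[-length(nao)])
  expect_lt(abs(r1 - 0.8), 0.05)

  # explosive AR(1) rejected
  expect_error(simulation_config(nao_ar1 = c(mean = 0, phi = 1.01, sd = 0.5)))
})

test_that("state sequences follow the covariate transition model", {
  # near-identity transitions freeze the chain at its initial state
  cfg <- simulation_config(n_days = 50, transition_coeffs = rep(-20, 6),
                           rng_seed = 2)
  cov <- simulate_covariates(cfg)
  st <- simulate_state_sequence(cfg, cov, bird = 1)
  expect_equal(st, rep(st[1], 50))

  # long-run transition frequencies match the intercept-only matrix
  P <- .default_transition_probs_test()
  cfg2 <- simulation_config(n_days = 50000, rng_seed = 3)
  cov2 <- simulate_covariates(cfg2)
  st2 <- simulate_state_sequence(cfg2, cov2, bird = 1)
  emp <- prop.table(table(factor(head(st2, -1), 1:3),
                          factor(tail(st2, -1), 1:3)), 1)
  expect_lt(max(abs(emp - P)), 0.01)

  # a positive NAO slope on Warm->Cold raises that frequency on high-NAO days
  beta <- transition_intercepts_from_probs(P)
  beta <- cbind(beta, nao = c(0, 0, 1.5, 0, 0, 0))
  cfg3 <- simulation_config(n_days = 20000, transition_coeffs = beta,
                            rng_seed = 4)
  cov3 <- simulate_covariates(cfg3)
  st3 <- simulate_state_sequence(cfg3, cov3, bird = 1)
  from_warm <- which(head(st3, -1) == 2)
  hi <- from_warm[cov3$nao[from_warm + 1] > 0.5]
  lo <- from_warm[cov3$nao[from_warm + 1] < -0.5]
  expect_gt(mean(st3[hi + 1] == 1), mean(st3[lo + 1] == 1))

  # reproducible under the seed
  expect_identical(st, simulate_state_sequence(cfg, cov, bird = 1))
})

test_that("logger streams honour the construction rules and the truth ledger", {
  cfg <- simulation_config(n_birds = 2, n_days = 3, rng_seed = 5)
  sim <- simulate_dataset(cfg)

  # determinism: identical config gives identical output
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$records, sim2$records)
  expect_identical(sim$truth_days, sim2$truth_days)

  # each day is tiled: scheduled hours sum to exactly 24
  tot <- with(sim$truth_days, flight_h + dive_h + rest_h + swim_h)
  expect_equal(tot, rep(24, nrow(sim$truth_days)))

  # scheduled intervals are non-overlapping and tile each bird-day
  for (key in split(sim$truth_intervals,
                    paste(sim$truth_intervals$bird_id, sim$truth_intervals$date))) {
    key <- key[order(key$start), ]
    expect_equal(as.numeric(key$start[-1]), as.numeric(key$end[-nrow(key)]))
    expect_equal(sum(as.numeric(key$end) - as.numeric(key$start)), 86400)
  }

  # dive detection recovers the ledger exactly (count, duration, depth)
  dv <- detect_dives(sim$records)
  td <- sim$truth_dives[order(sim$truth_dives$bird_id, sim$truth_dives$start), ]
  expect_equal(nrow(dv), nrow(td))
  expect_equal(as.numeric(dv$start), as.numeric(td$start))
  expect_equal(dv$duration_min, td$duration_min)
  expect_equal(dv$max_depth_m, td$max_depth_m)

  # no flight or rest scheduled -> wet at every sample
  prof <- default_activity_profiles()
  for (i in seq_along(prof)) { prof[[i]]$flight_h <- 0; prof[[i]]$rest_h <- 0 }
  cfg_wet <- simulation_config(n_birds = 1, n_days = 2,
                               activity_profiles = prof, rng_seed = 6)
  sim_wet <- simulate_dataset(cfg_wet)
  expect_true(all(sim_wet$records$wet))

  # noiseless sensor: wet non-dive temperature equals true SST exactly
  cfg0 <- simulation_config(n_birds = 1, n_days = 2, sensor_noise_sd = 0,
                            rng_seed = 7)
  sim0 <- simulate_dataset(cfg0)
  r <- sim0$records
  r$date <- as.Date(r$timestamp, tz = "UTC")
  for (d in unique(r$date)) {
    sel <- r$date == d & r$wet & r$depth < 5
    expect_equal(unique(r$temp[sel]),
                 sim0$truth_days$true_sst[sim0$truth_days$date == d])
  }
})

test_that("an infeasible light schedule names the bird and date", {
  # polar night in January: daylight dives cannot be scheduled at 80N
  cfg <- simulation_config(n_birds = 1, n_days = 1, lat_range = c(80, 80),
                           rng_seed = 1)
  cov <- simulate_covariates(cfg)
  st <- simulate_state_sequence(cfg, cov, 1)
  expect_error(simulate_logger_records(cfg, st, cov, 1),
               "schedule infeasible.*bird01.*2019-01-01")
})

test_that("full classification recovers the ledger budgets and SST", {
  cfg <- simulation_config(n_birds = 2, n_days = 4, rng_seed = 8)
  sim <- simulate_dataset(cfg)
  s <- summarize_bird_days(sim$records, sim$positions)
  m <- merge(s, sim$truth_days, by = c("bird_id", "date"))
  expect_equal(nrow(m), 8L)
  expect_lt(max(abs(m$t_fly_h - m$flight_h)), 0.1)
  expect_lt(max(abs(m$t_dive_h - m$dive_h)), 0.1)
  expect_lt(max(abs(m$t_rest_h - m$rest_h)), 0.1)
  expect_equal(m$n_dives.x, m$n_dives.y)
  # daily SST within sensor-noise tolerance of the ledger truth
  expect_lt(max(abs(m$sst_c - m$true_sst)), 3 * cfg$sensor_noise_sd / sqrt(1000))
  # dive light classes match the schedule
  dv <- attr(s, "dives")
  dv <- dv[order(dv$bird_id, dv$start), ]
  td <- sim$truth_dives[order(sim$truth_dives$bird_id, sim$truth_dives$start), ]
  expect_equal(as.character(dv$light_class), td$light_class)
})
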