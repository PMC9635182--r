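test_that("transition matrix follows the multinomial logit construction", {
  # strongly negative intercepts: near-identity
  G <- transition_matrix(rep(-20, 6))
  expect_equal(diag(G), rep(1, 3), tolerance = 1e-7)

  # all-zero coefficients: uniform rows
  G0 <- transition_matrix(rep(0, 6))
  expect_equal(as.numeric(G0), rep(1 / 3, 9))

  # hand case for one row: eta = (log 2, log 1) -> (0.5, 0.25), diag 0.25
  b <- matrix(-20, 6, 1)
  b[1:2, 1] <- c(log(2), log(1))
  G1 <- transition_matrix(b)
  expect_equal(G1[1, ], c(0.25, 0.5, 0.25))

  # rows always stochastic, also with covariates
  beta <- matrix(rnorm(12, sd = 0.5), 6, 2,
                 dimnames = list(NULL, c("(Intercept)", "nao")))
  for (nao in c(-2, 0, 3)) {
    G2 <- transition_matrix(beta, c(nao = nao))
    expect_equal(rowSums(G2), rep(1, 3), tolerance = 1e-12)
    expect_true(all(G2 >= 0))
  }

  # missing covariate named in the error
  expect_error(transition_matrix(beta, c(moon = 0.5)), "nao")
})

test_that("forward likelihood matches exhaustive path enumeration", {
  set.seed(42)
  dates <- as.Date("2019-01-01") + 0:5
  cov <- make_covariates(dates, nao = round(rnorm(6), 2))
  mu <- c(-1, 3, 8); sigma <- c(1, 0.5, 2); delta <- c(0.5, 0.3, 0.2)
  beta <- matrix(c(rep(-1.5, 6), rep(0.8, 6)), 6, 2,
                 dimnames = list(NULL, c("(Intercept)", "nao")))
  params <- hmm_params(mu, sigma, beta, delta)

  for (rep_i in 1:3) {
    y <- rnorm(6, sample(mu, 6, replace = TRUE), 1)
    if (rep_i == 2) y[3] <- NA # missing emission decoded through transitions
    sst <- data.frame(bird_id = "b1", date = dates, sst = y)
    gammas <- lapply(seq_len(6), function(t) {
      transition_matrix(beta, c(nao = cov$nao[t]))
    })
    expect_equal(forward_loglik(sst, cov, params),
                 brute_loglik(y, gammas, mu, sigma, delta), tolerance = 1e-8)
  }

  # fully missing series carries no emission information
  sst_na <- data.frame(bird_id = "b1", date = dates, sst = NA_real_)
  expect_equal(forward_loglik(sst_na, cov, params), 0, tolerance = 1e-10)

  # several birds sum their contributions
  sst2 <- rbind(data.frame(bird_id = "b1", date = dates, sst = rnorm(6, 3, 1)),
                data.frame(bird_id = "b2", date = dates, sst = rnorm(6, -1, 1)))
  ll_joint <- forward_loglik(sst2, cov, params)
  ll_split <- forward_loglik(sst2[sst2$bird_id == "b1", ], cov, params) +
    forward_loglik(sst2[sst2$bird_id == "b2", ], cov, params)
  expect_equal(ll_joint, ll_split, tolerance = 1e-10)
})

test_that("viterbi equals the exhaustive maximum-probability path", {
  set.seed(7)
  dates <- as.Date("2019-01-01") + 0:7
  cov <- make_covariates(dates, nao = round(rnorm(8), 2))
  mu <- c(-1, 3, 8); sigma <- c(1.5, 1, 2); delta <- c(0.4, 0.4, 0.2)
  beta <- matrix(c(rep(-1, 6), rep(0.5, 6)), 6, 2,
                 dimnames = list(NULL, c("(Intercept)", "nao")))
  params <- hmm_params(mu, sigma, beta, delta)
  gammas <- lapply(seq_len(8), function(t) {
    transition_matrix(beta, c(nao = cov$nao[t]))
  })
  for (rep_i in 1:3) {
    y <- rnorm(8, sample(mu, 8, replace = TRUE), 1.5)
    if (rep_i == 3) y[c(2, 6)] <- NA
    sst <- data.frame(bird_id = "b1", date = dates, sst = y)
    dec <- viterbi_decode(sst, cov, params)
    expect_equal(dec$state, brute_viterbi(y, gammas, mu, sigma, delta))
  }
})

test_that("well-separated states decode essentially perfectly", {
  cfg <- simulation_config(n_birds = 4, n_days = 60,
                           state_means = c(-10, 0, 10),
                           state_sds = c(1, 1, 1), rng_seed = 3)
  sim <- simulate_daily_sst(cfg)
  params <- hmm_params(cfg$state_means, cfg$state_sds,
                       cfg$transition_coeffs, cfg$delta)
  dec <- viterbi_decode(sim$sst, sim$covariates, params)
  truth <- sim$states[order(sim$states$bird_id, sim$states$date), ]
  expect_gte(mean(dec$state == truth$state), 0.99)
})

test_that("grid SST cells classify to the densest state, ties to colder", {
  params <- hmm_params(c(-0.1, 3.1, 6.5), c(1.2, 0.3, 2.4), rep(-3, 6))
  expect_equal(classify_sst_to_state(c(-0.1, 3.1, 20), params), c(1L, 2L, 3L))
  # analytic equal-density crossover between two equal-sd states is the
  # midpoint of their means; it must classify to the lower index
  p2 <- hmm_params(c(0, 4, 20), c(1, 1, 1), rep(-3, 6))
  expect_equal(classify_sst_to_state(2, p2), 1L)
  expect_true(is.na(classify_sst_to_state(NA, p2)))
  grid <- data.frame(lat = c(55, 56), lon = c(-50, -51), month = 1,
                     sst_c = c(-0.5, 3.2))
  expect_equal(classify_sst_grid(grid, params)$state, c(1L, 2L))
})

test_that("occupancy summaries conserve birds and days", {
  dec <- data.frame(
    bird_id = rep(c("b1", "b2"), each = 5),
    date = rep(as.Date("2019-01-01") + 0:4, 2),
    state = c(1, 1, 2, 2, 2, 1, 1, 1, 1, 1)
  )
  occ <- occupancy_summary(dec)
  expect_equal(rowSums(occ$by_date[, paste0("p_state", 1:3)]), rep(1, 5))
  expect_equal(rowSums(occ$by_bird[, paste0("days_state", 1:3)]), c(5, 5))
  all_cold <- transform(dec, state = 1)
  expect_equal(occupancy_summary(all_cold)$by_date$p_state1, rep(1, 5))
})

test_that("fitting improves on the start and canonicalises state order", {
  cfg <- simulation_config(n_birds = 8, n_days = 60, rng_seed = 2)
  sim <- simulate_daily_sst(cfg)
  fit <- fit_hmm(sim$sst, sim$covariates)
  expect_gte(fit$loglik, fit$loglik_init)
  expect_true(all(diff(fit$params$mu) > 0))
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_equal(fit$convergence, 0)

  # label invariance: a permuted start recovers the same states
  fit2 <- fit_hmm(sim$sst, sim$covariates,
                  init = hmm_init(mu = c(8, 3, -1)))
  expect_equal(fit2$params$mu, fit$params$mu, tolerance = 0.05)
  expect_equal(fit2$params$sigma, fit$params$sigma, tolerance = 0.05)
})

test_that("standardising transition covariates leaves the likelihood invariant", {
  cfg <- simulation_config(n_birds = 6, n_days = 40, rng_seed = 9)
  sim <- simulate_daily_sst(cfg)
  fit <- fit_hmm(sim$sst, sim$covariates, covariate_set = "nao")
  # same model refit on a covariate shifted and scaled by arbitrary amounts
  cov2 <- sim$covariates
  cov2$nao <- 3 * cov2$nao + 10
  fit2 <- fit_hmm(sim$sst, cov2, covariate_set = "nao")
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-3)
  # raw-scale slopes absorb the affine change
  expect_equal(fit2$params$beta[, "nao"], fit$params$beta[, "nao"] / 3,
               tolerance = 0.05)
})

test_that("AIC selection prefers the generating structure", {
  # intercept-only truth: the intercept model should win or tie-to-simplest
  cfg <- simulation_config(n_birds = 10, n_days = 60, rng_seed = 4)
  sim <- simulate_daily_sst(cfg)
  sel <- select_model(sim$sst, sim$covariates, candidates = c("moon", "nao"))
  expect_equal(sel$covariate_set, character(0))
  tab <- attr(sel, "selection_table")
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$aic, 2 * tab$n_params - 2 * tab$loglik)

  # a strong nao effect on transitions should be detected
  beta <- transition_intercepts_from_probs(.default_transition_probs_test())
  beta <- cbind(beta, nao = c(0, 0, 2.5, 0, 0, 0))
  cfg2 <- simulation_config(n_birds = 12, n_days = 60,
                            transition_coeffs = beta, rng_seed = 8)
  sim2 <- simulate_daily_sst(cfg2)
  sel2 <- select_model(sim2$sst, sim2$covariates, candidates = c("moon", "nao"))
  expect_true("nao" %in% sel2$covariate_set)
})

test_that("fitted parameters survive JSON serialisation", {
  params <- hmm_params(c(-0.1, 3.1, 6.5), c(1.2, 0.3, 2.4),
                       cbind("(Intercept)" = rep(-3, 6), nao = rnorm(6)),
                       c(0.5, 0.45, 0.05))
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_params(params, path)
  back <- read_hmm_params(path)
  expect_equal(back$mu, params$mu)
  expect_equal(back$sigma, params$sigma)
  expect_equal(unname(back$beta), unname(params$beta))
  expect_equal(back$delta, params$delta)
})

test_that("model check calibrates on data from the fitted model itself", {
  cfg <- simulation_config(n_birds = 8, n_days = 60, rng_seed = 6)
  sim <- simulate_daily_sst(cfg)
  fit <- fit_hmm(sim$sst, sim$covariates)
  chk <- model_check(fit, sim$sst, sim$covariates, n_sims = 60, seed = 2)
  expect_gte(mean(chk$inside), 0.9)
  # reproducible under the same seed
  chk2 <- model_check(fit, sim$sst, sim$covariates, n_sims = 60, seed = 2)
  expect_identical(chk$observed, chk2$observed)
  expect_identical(chk$lo, chk2$lo)
  # destroying temporal order pushes lag-1 autocorrelation outside
  set.seed(1)
  shuf <- do.call(rbind, lapply(split(sim$sst, sim$sst$bird_id), function(s) {
    s$sst <- sample(s$sst); s
  }))
  chk3 <- model_check(fit, shuf, sim$covariates, n_sims = 60, seed = 2)
  expect_false(chk3$inside[chk3$statistic == "acf_lag1"])
})
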