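# Three-state Gaussian hidden Markov model on daily bird-detected SST with
# multinomial-logit covariate-dependent transition probabilities. Fitting is
# by direct maximisation of the scaled forward log-likelihood over
# unconstrained reparameterisations (log sigma, logit-scale beta, softmax
# initial distribution); covariate effects on transitions make an EM M-step
# non-closed-form, so quasi-Newton on the joint likelihood is used instead.

.transition_names <- function(K = 3L) {
  out <- character(0)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j) {
    out <- c(out, sprintf("%d->%d", i, j))
  }
  out # row order: 1->2, 1->3, 2->1, 2->3, 3->1, 3->2
}

#' Construct HMM parameters
#'
#' @param mu Emission means, deg C, length 3 (Cold, Warm, Warmer).
#' @param sigma Emission SDs, deg C, length 3, all positive.
#' @param beta Transition coefficient block: a 6 x (1 + p) matrix, one row
#'   per off-diagonal transition in the order `1->2, 1->3, 2->1, 2->3,
#'   3->1, 3->2`, first column the intercept, remaining columns named for
#'   covariates. A numeric length-6 vector is taken as intercepts only.
#' @param delta Initial state distribution (normalised to sum to 1).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(mu, sigma, beta, delta = rep(1 / 3, 3)) {
  stopifnot(length(mu) == 3, length(sigma) == 3, all(sigma > 0),
            length(delta) == 3, all(delta >= 0), sum(delta) > 0)
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 6, ncol = 1)
  stopifnot(nrow(beta) == 6)
  if (is.null(colnames(beta))) {
    colnames(beta) <- c("(Intercept)", paste0("x", seq_len(ncol(beta) - 1)))[seq_len(ncol(beta))]
  }
  rownames(beta) <- .transition_names()
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 beta = beta, delta = as.numeric(delta) / sum(delta)),
            class = "hmm_params")
}

#' Multinomial-logit transition matrix
#'
#' For each origin state i, the probability of moving to j != i is
#' `exp(eta_ij) / (1 + sum_j' exp(eta_ij'))` with `eta_ij` the linear
#' predictor from the beta row for i->j evaluated at the covariate values;
#' the diagonal takes the remainder, so every row sums to one.
#'
#' @param beta 6 x (1 + p) coefficient matrix (see [hmm_params()]).
#' @param covariate_row Named numeric vector supplying every non-intercept
#'   column of `beta` (may be empty for intercept-only models).
#' @return A 3 x 3 row-stochastic matrix.
#' @export
transition_matrix <- function(beta, covariate_row = numeric(0)) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 6, ncol = 1)
  covs <- colnames(beta)[-1]
  if (length(covs)) {
    if (!all(covs %in% names(covariate_row))) {
      stop(sprintf("covariate row lacks: %s",
                   paste(setdiff(covs, names(covariate_row)), collapse = ", ")),
           call. = FALSE)
    }
    x <- c(1, as.numeric(covariate_row[covs]))
  } else {
    x <- 1
  }
  eta <- as.numeric(beta %*% x)
  if (any(!is.finite(eta))) {
    bad <- which(!is.finite(eta))[1]
    stop(sprintf("non-finite linear predictor for transition %s",
                 .transition_names()[bad]), call. = FALSE)
  }
  G <- diag(3)
  k <- 1L
  for (i in 1:3) {
    e <- exp(eta[k:(k + 1L)])
    p <- e / (1 + sum(e))
    js <- setdiff(1:3, i)
    G[i, js] <- p
    G[i, i] <- 1 - sum(p)
    k <- k + 2L
  }
  G
}

# T x 6 linear predictors -> array of T transition matrices (3 x 3 x T)
.gamma_array <- function(beta, X) {
  eta <- X %*% t(beta) # T x 6
  Tt <- nrow(eta)
  G <- array(0, c(3, 3, Tt))
  k <- 1L
  for (i in 1:3) {
    e1 <- exp(eta[, k]); e2 <- exp(eta[, k + 1L])
    den <- 1 + e1 + e2
    js <- setdiff(1:3, i)
    G[i, js[1], ] <- e1 / den
    G[i, js[2], ] <- e2 / den
    G[i, i, ] <- 1 / den
    k <- k + 2L
  }
  G
}

# Design matrix for the selected covariates at given dates; standardisation
# constants (center/scale) are applied when supplied.
.design_matrix <- function(covariates, dates, covariate_set, std = NULL) {
  idx <- match(as.Date(dates), as.Date(covariates$date))
  if (anyNA(idx)) stop("covariates missing for some dates", call. = FALSE)
  X <- matrix(1, nrow = length(dates), ncol = 1 + length(covariate_set),
              dimnames = list(NULL, c("(Intercept)", covariate_set)))
  for (v in covariate_set) {
    x <- as.numeric(covariates[[v]][idx])
    if (!is.null(std)) x <- (x - std$center[[v]]) / std$scale[[v]]
    X[, v] <- x
  }
  X
}

# Split a long (bird_id, date, sst) table into groups of birds that share an
# identical date sequence, for vectorised forward recursions.
.bird_groups <- function(sst_long) {
  sp <- split(sst_long, sst_long$bird_id)
  sp <- lapply(sp, function(s) s[order(s$date), , drop = FALSE])
  keys <- vapply(sp, function(s) paste(s$date, collapse = "|"), "")
  lapply(split(seq_along(sp), keys), function(ii) {
    list(birds = names(sp)[ii],
         dates = sp[[ii[1]]]$date,
         Y = do.call(rbind, lapply(sp[ii], function(s) s$sst)))
  })
}

.emission_probs <- function(Y, mu, sigma) {
  # Y: nb x T; returns list of T matrices nb x 3; NA observation -> 1
  Tt <- ncol(Y)
  lapply(seq_len(Tt), function(t) {
    y <- Y[, t]
    E <- matrix(1, nrow = length(y), ncol = 3)
    ok <- !is.na(y)
    if (any(ok)) {
      for (k in 1:3) E[ok, k] <- stats::dnorm(y[ok], mu[k], sigma[k])
    }
    E
  })
}

#' Forward log-likelihood
#'
#' Scaled forward-algorithm log-likelihood summed over birds sharing one
#' parameter set. Missing SST days contribute only the transition step (the
#' emission density is replaced by 1), so tracks are never split at gaps.
#' Covariates are matched by date; the transition into day t is evaluated
#' at day t's covariate values.
#'
#' @param sst_long Data frame `bird_id, date, sst` (deg C, `NA` allowed).
#' @param covariates Data frame `date, year, doy, moon, nao` (see
#'   [read_covariates()]); only the columns named in `beta` are used.
#' @param params An [hmm_params()] object (its beta columns define the
#'   covariate set and scale).
#' @return Log-likelihood (scalar).
#' @export
forward_loglik <- function(sst_long, covariates, params) {
  stopifnot(inherits(params, "hmm_params"), all(params$sigma > 0))
  covariate_set <- colnames(params$beta)[-1]
  ll <- 0
  for (g in .bird_groups(sst_long)) {
    X <- .design_matrix(covariates, g$dates, covariate_set,
                        std = attr(params, "std"))
    G <- .gamma_array(params$beta, X)
    E <- .emission_probs(g$Y, params$mu, params$sigma)
    nb <- nrow(g$Y)
    phi <- matrix(params$delta, nrow = nb, ncol = 3, byrow = TRUE) * E[[1]]
    sc <- rowSums(phi)
    ll <- ll + sum(log(sc))
    phi <- phi / sc
    Tt <- ncol(g$Y)
    if (Tt > 1) for (t in 2:Tt) {
      phi <- (phi %*% G[, , t]) * E[[t]]
      sc <- rowSums(phi)
      ll <- ll + sum(log(sc))
      phi <- phi / sc
    }
  }
  ll
}

.pack <- function(mu, lsig, beta, eta_delta) c(mu, lsig, as.numeric(beta), eta_delta)

.unpack <- function(theta, p, covariate_set) {
  nb <- 6L * (1L + p)
  beta <- matrix(theta[7:(6 + nb)], nrow = 6)
  colnames(beta) <- c("(Intercept)", covariate_set)
  ed <- theta[(7 + nb):(8 + nb)]
  d <- exp(c(0, ed)); d <- d / sum(d)
  # floor keeps sigma valid if the optimizer probes extreme log-sigma values
  hmm_params(mu = theta[1:3], sigma = pmax(exp(theta[4:6]), 1e-6),
             beta = beta, delta = d)
}

# permute state labels so mu is ascending; beta rows follow the relabeling
.canonicalize <- function(params) {
  perm <- order(params$mu) # perm[new] = old
  if (identical(perm, 1:3)) return(params)
  tn <- .transition_names()
  beta_new <- params$beta
  k <- 1L
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    old <- sprintf("%d->%d", perm[i], perm[j])
    beta_new[k, ] <- params$beta[match(old, tn), ]
    k <- k + 1L
  }
  out <- hmm_params(params$mu[perm], params$sigma[perm], beta_new,
                    params$delta[perm])
  attributes(out)$std <- attr(params, "std")
  out
}

#' Default initial values for fitting
#'
#' Emission starting values of -1, 3 and 8 deg C with common SD 3 deg C
#' (Cold/Warm/Warmer), transition intercepts at -3 on the logit scale
#' (daily off-diagonal probability about 0.045), zero covariate slopes and
#' a uniform initial distribution.
#'
#' @param mu,sigma,beta_intercept,delta Override any component.
#' @return A list used as `init` by [fit_hmm()].
#' @export
hmm_init <- function(mu = c(-1, 3, 8), sigma = c(3, 3, 3),
                     beta_intercept = -3, delta = rep(1 / 3, 3)) {
  list(mu = mu, sigma = sigma, beta_intercept = beta_intercept, delta = delta)
}

#' Fit the SST habitat-state HMM
#'
#' Maximises [forward_loglik()] by BFGS over unconstrained transformed
#' parameters. Covariates entering the transition model are z-scored
#' internally for optimizer conditioning; fitted coefficients are reported
#' on both the standardized (`beta_std`) and original (`beta`) scales.
#' States are relabelled so fitted means ascend (Cold, Warm, Warmer).
#'
#' @param sst_long Data frame `bird_id, date, sst`.
#' @param covariates Covariate table (`date, year, doy, moon, nao`).
#' @param covariate_set Character subset of
#'   `c("year", "doy", "moon", "nao")` entering the transition model.
#' @param init Starting values, see [hmm_init()].
#' @param control Passed to [stats::optim()] (BFGS); defaults give
#'   `maxit = 500`, `reltol = 1e-10`.
#' @return A `hmm_fit` object: `params` (original scale), `params_std`,
#'   `loglik`, `loglik_init`, `n_params`, `aic`, `covariate_set`,
#'   `convergence` (0 = converged), `counts`.
#' @export
fit_hmm <- function(sst_long, covariates, covariate_set = character(0),
                    init = hmm_init(), control = list()) {
  stopifnot(all(covariate_set %in% c("year", "doy", "moon", "nao")))
  n_obs <- sum(!is.na(sst_long$sst))
  if (length(unique(sst_long$bird_id)) < 2 && n_obs < 60) {
    warning("few birds and observations; HMM fit may be unstable")
  }
  p <- length(covariate_set)
  std <- NULL
  if (p) {
    used_dates <- unique(as.Date(sst_long$date))
    idx <- match(used_dates, as.Date(covariates$date))
    std <- list(center = list(), scale = list())
    for (v in covariate_set) {
      x <- as.numeric(covariates[[v]][idx])
      s <- stats::sd(x)
      std$center[[v]] <- mean(x)
      std$scale[[v]] <- if (is.finite(s) && s > 0) s else 1
    }
  }
  beta0 <- matrix(0, 6, 1 + p,
                  dimnames = list(.transition_names(),
                                  c("(Intercept)", covariate_set)))
  beta0[, 1] <- init$beta_intercept
  theta0 <- .pack(init$mu, log(init$sigma), beta0,
                  log(init$delta[2:3] / init$delta[1]))
  negll <- function(theta) {
    pars <- .unpack(theta, p, covariate_set)
    attr(pars, "std") <- std
    ll <- try(forward_loglik(sst_long, covariates, pars), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  opt <- stats::optim(theta0, negll, method = "BFGS", control = ctrl)
  params_std <- .unpack(opt$par, p, covariate_set)
  attr(params_std, "std") <- std
  params_std <- .canonicalize(params_std)
  # back-transform beta to the original covariate scale
  params <- params_std
  if (p) {
    b <- params_std$beta
    braw <- b
    for (v in covariate_set) braw[, v] <- b[, v] / std$scale[[v]]
    braw[, 1] <- b[, 1] -
      as.numeric(b[, covariate_set, drop = FALSE] %*%
                   (unlist(std$center[covariate_set]) /
                    unlist(std$scale[covariate_set])))
    params <- hmm_params(params_std$mu, params_std$sigma, braw,
                         params_std$delta)
  }
  n_params <- length(theta0)
  ll <- -opt$value
  structure(list(
    params = params, params_std = params_std, loglik = ll,
    loglik_init = -negll(theta0), n_params = n_params,
    aic = 2 * n_params - 2 * ll, covariate_set = covariate_set,
    convergence = opt$convergence, counts = opt$counts,
    n_obs = n_obs
  ), class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Gaussian SST hidden Markov model (3 states)\n")
  cat(sprintf("  covariates on transitions: %s\n",
              if (length(x$covariate_set)) paste(x$covariate_set, collapse = ", ") else "(none)"))
  st <- c("Cold", "Warm", "Warmer")
  for (k in 1:3) {
    cat(sprintf("  %-6s mean %6.2f degC  sd %5.2f degC\n",
                st[k], x$params$mu[k], x$params$sigma[k]))
  }
  cat(sprintf("  logLik %.2f, %d parameters, AIC %.2f, convergence %d\n",
              x$loglik, x$n_params, x$aic, x$convergence))
  invisible(x)
}

#' AIC covariate selection for the transition model
#'
#' Fits the HMM for every subset of the candidate covariates on the
#' transition probabilities and returns the most parsimonious fit by AIC;
#' among models within 2 AIC units of the best, the one with fewest
#' parameters wins. Non-convergent fits are excluded with a warning.
#'
#' @param sst_long,covariates,init,control As in [fit_hmm()].
#' @param candidates Covariates to consider (default all four).
#' @return The selected `hmm_fit`, with a `selection_table` attribute
#'   listing every candidate model's covariates, logLik, parameters, AIC
#'   and delta-AIC.
#' @export
select_model <- function(sst_long, covariates,
                         candidates = c("year", "doy", "moon", "nao"),
                         init = hmm_init(), control = list()) {
  subsets <- unlist(lapply(0:length(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  fits <- lapply(subsets, function(cs) {
    fit_hmm(sst_long, covariates, covariate_set = cs, init = init,
            control = control)
  })
  conv <- vapply(fits, function(f) f$convergence == 0, TRUE)
  if (!all(conv)) {
    warning(sprintf("%d candidate fits did not converge and were excluded",
                    sum(!conv)))
  }
  if (!any(conv)) stop("no candidate model converged", call. = FALSE)
  fits <- fits[conv]; subsets <- subsets[conv]
  aic <- vapply(fits, function(f) f$aic, 0)
  npar <- vapply(fits, function(f) f$n_params, 0L)
  daic <- aic - min(aic)
  near <- which(daic < 2)
  best <- near[order(npar[near], aic[near])][1]
  tab <- data.frame(
    covariates = vapply(subsets, function(s) if (length(s)) paste(s, collapse = "+") else "(intercept)", ""),
    loglik = vapply(fits, function(f) f$loglik, 0),
    n_params = npar, aic = aic, delta_aic = daic
  )
  out <- fits[[best]]
  attr(out, "selection_table") <- tab[order(tab$aic), ]
  out
}

#' Viterbi decoding of habitat states
#'
#' The jointly most probable state path per bird under the fitted
#' covariate-inhomogeneous transition matrices; exact ties break toward the
#' lower (colder) state index, and missing SST days are decoded through the
#' transition structure alone.
#'
#' @param sst_long Data frame `bird_id, date, sst`.
#' @param covariates Covariate table.
#' @param params Fitted [hmm_params()] (or an `hmm_fit`, whose standardized
#'   parameters are used).
#' @return Data frame `bird_id, date, state` with state in 1..3.
#' @export
viterbi_decode <- function(sst_long, covariates, params) {
  if (inherits(params, "hmm_fit")) params <- params$params_std
  covariate_set <- colnames(params$beta)[-1]
  out <- lapply(.bird_groups(sst_long), function(g) {
    X <- .design_matrix(covariates, g$dates, covariate_set,
                        std = attr(params, "std"))
    G <- .gamma_array(params$beta, X)
    E <- .emission_probs(g$Y, params$mu, params$sigma)
    Tt <- ncol(g$Y); nb <- nrow(g$Y)
    paths <- matrix(0L, nb, Tt)
    for (b in seq_len(nb)) {
      lv <- log(params$delta) + log(E[[1]][b, ])
      back <- matrix(0L, 3, Tt)
      if (Tt > 1) for (t in 2:Tt) {
        cand <- lv + log(G[, , t]) # 3x3: [from, to]
        from <- apply(cand, 2, which.max)
        back[, t] <- from
        lv <- cand[cbind(from, 1:3)] + log(E[[t]][b, ])
      }
      s <- integer(Tt)
      s[Tt] <- which.max(lv)
      if (Tt > 1) for (t in Tt:2) s[t - 1L] <- back[s[t], t]
      paths[b, ] <- s
    }
    do.call(rbind, lapply(seq_len(nb), function(b) {
      data.frame(bird_id = g$birds[b], date = g$dates, state = paths[b, ])
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$bird_id, out$date), , drop = FALSE]
}

#' Simulate observations from fitted HMM parameters
#'
#' Draws state sequences from the covariate-dependent transition model and
#' Gaussian observations from the emission model, for each bird and date in
#' a template table. Used by [model_check()] and available for power
#' studies.
#'
#' @param template Data frame `bird_id, date` (an `sst` column, if present,
#'   donates its missingness pattern).
#' @param covariates Covariate table.
#' @param params [hmm_params()] or `hmm_fit`.
#' @return Data frame `bird_id, date, state, sst`.
#' @export
simulate_hmm <- function(template, covariates, params) {
  if (inherits(params, "hmm_fit")) params <- params$params_std
  covariate_set <- colnames(params$beta)[-1]
  sp <- split(template, template$bird_id)
  out <- lapply(sp, function(s) {
    s <- s[order(s$date), , drop = FALSE]
    Tt <- nrow(s)
    X <- .design_matrix(covariates, s$date, covariate_set,
                        std = attr(params, "std"))
    G <- .gamma_array(params$beta, X)
    st <- integer(Tt)
    st[1] <- sample.int(3, 1, prob = params$delta)
    if (Tt > 1) for (t in 2:Tt) {
      st[t] <- sample.int(3, 1, prob = G[st[t - 1L], , t])
    }
    y <- stats::rnorm(Tt, params$mu[st], params$sigma[st])
    if ("sst" %in% names(s)) y[is.na(s$sst)] <- NA_real_
    data.frame(bird_id = s$bird_id, date = s$date, state = st, sst = y)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior-predictive model check
#'
#' Simulates datasets from the fitted model at the observed covariates and
#' compares observed marginal SST quantiles (5/25/50/75/95%) and mean
#' per-bird autocorrelations (lags 1..10) against the simulated 2.5--97.5%
#' envelopes.
#'
#' @param fit An `hmm_fit`.
#' @param sst_long,covariates Observed data.
#' @param n_sims Number of simulated datasets (default 100).
#' @param seed RNG seed for reproducibility.
#' @return A data frame with one row per checked statistic: `statistic`,
#'   `observed`, `lo`, `hi`, `inside`.
#' @export
model_check <- function(fit, sst_long, covariates, n_sims = 100, seed = 1) {
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  lags <- 1:10
  stat_fun <- function(d) {
    q <- stats::quantile(d$sst, probs, na.rm = TRUE, names = FALSE, type = 7)
    acfs <- vapply(split(d, d$bird_id), function(s) {
      s <- s[order(s$date), ]
      x <- s$sst
      if (sum(!is.na(x)) < max(lags) + 5) return(rep(NA_real_, length(lags)))
      a <- stats::acf(x, lag.max = max(lags), plot = FALSE,
                      na.action = stats::na.pass)
      as.numeric(a$acf)[lags + 1L]
    }, numeric(length(lags)))
    c(q, rowMeans(acfs, na.rm = TRUE))
  }
  obs <- stat_fun(sst_long)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sims <- vapply(seq_len(n_sims), function(i) {
    stat_fun(simulate_hmm(sst_long, covariates, fit))
  }, numeric(length(obs)))
  lo <- apply(sims, 1, stats::quantile, 0.025, na.rm = TRUE)
  hi <- apply(sims, 1, stats::quantile, 0.975, na.rm = TRUE)
  data.frame(
    statistic = c(paste0("q", probs * 100), paste0("acf_lag", lags)),
    observed = obs, lo = lo, hi = hi,
    inside = obs >= lo & obs <= hi
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Classify SST values to the most likely habitat state
#'
#' Assigns each SST value to the state whose Gaussian emission density is
#' highest (ties to the lower, colder index). Used to label gridded SST
#' cells with habitat states.
#'
#' @param sst_c Numeric vector of SST values, deg C.
#' @param params [hmm_params()] or `hmm_fit`.
#' @return Integer vector of states in 1..3 (`NA` in, `NA` out).
#' @export
classify_sst_to_state <- function(sst_c, params) {
  if (inherits(params, "hmm_fit")) params <- params$params
  dens <- vapply(1:3, function(k) {
    stats::dnorm(sst_c, params$mu[k], params$sigma[k])
  }, numeric(length(sst_c)))
  dens <- matrix(dens, ncol = 3)
  out <- apply(dens, 1, function(d) if (anyNA(d)) NA_integer_ else which.max(d))
  as.integer(out)
}

#' Label a gridded SST table with habitat states
#'
#' @param grid Data frame with at least `sst_c` (typically
#'   `lat, lon, month, sst_c`).
#' @param params [hmm_params()] or `hmm_fit`.
#' @return `grid` with an integer `state` column appended.
#' @export
classify_sst_grid <- function(grid, params) {
  grid$state <- classify_sst_to_state(grid$sst_c, params)
  grid
}

#' Occupancy summaries of decoded states
#'
#' @param decoded Data frame `bird_id, date, state` from [viterbi_decode()].
#' @return A list: `by_date` (proportion of birds in each state per date;
#'   rows sum to 1) and `by_bird` (days spent in each state per bird; rows
#'   sum to days tracked).
#' @export
occupancy_summary <- function(decoded) {
  tab <- table(date = as.character(decoded$date),
               state = factor(decoded$state, levels = 1:3))
  by_date <- as.data.frame.matrix(prop.table(tab, 1))
  names(by_date) <- paste0("p_state", 1:3)
  by_date <- data.frame(date = as.Date(rownames(by_date)), by_date,
                        n_birds = as.integer(rowSums(tab)), row.names = NULL)
  tb <- table(bird_id = decoded$bird_id,
              state = factor(decoded$state, levels = 1:3))
  by_bird <- as.data.frame.matrix(tb)
  names(by_bird) <- paste0("days_state", 1:3)
  by_bird <- data.frame(bird_id = rownames(by_bird), by_bird, row.names = NULL)
  list(by_date = by_date, by_bird = by_bird)
}

#' Serialize fitted HMM parameters to JSON
#'
#' Writes mu, sigma, beta (with transition and covariate names), delta and
#' any covariate standardization constants to a JSON text file readable by
#' [read_hmm_params()].
#'
#' @param params [hmm_params()] or `hmm_fit` (original-scale parameters).
#' @param path Output path.
#' @export
write_hmm_params <- function(params, path) {
  if (inherits(params, "hmm_fit")) params <- params$params
  obj <- list(
    mu = params$mu, sigma = params$sigma,
    beta = as.data.frame(params$beta),
    transitions = rownames(params$beta),
    delta = params$delta,
    std = attr(params, "std")
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read serialized HMM parameters
#' @param path Path written by [write_hmm_params()].
#' @return An [hmm_params()] object.
#' @export
read_hmm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- as.matrix(obj$beta)
  rownames(beta) <- obj$transitions
  out <- hmm_params(obj$mu, obj$sigma, beta, obj$delta)
  if (!is.null(obj$std) && length(obj$std)) attr(out, "std") <- obj$std
  out
}
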