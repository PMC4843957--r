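#' MCMC chain configuration
#'
#' Settings for the Metropolis-within-Gibbs samplers. Proposal step sizes
#' are tuned by Robbins-Monro adaptation toward \code{target_acceptance}
#' during burn-in only; they are frozen afterwards so the retained draws
#' target the exact invariant distribution.
#'
#' @param burnin number of burn-in sweeps (>= 1).
#' @param samples number of retained draws (>= 1).
#' @param thin keep one sweep in every \code{thin} (>= 1).
#' @param seed RNG seed (integer).
#' @param adapt logical; adapt proposal scales during burn-in.
#' @param target_acceptance Robbins-Monro target acceptance rate for scalar
#'   random-walk blocks (default 0.234).
#' @return An object of class \code{"chain_config"}.
#' @export
chain_config <- function(burnin = 1000L, samples = 1000L, thin = 1L,
                         seed = 1L, adapt = TRUE, target_acceptance = 0.234) {
  stopifnot(burnin >= 1, samples >= 1, thin >= 1,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(burnin = as.integer(burnin), samples = as.integer(samples),
                 thin = as.integer(thin), seed = as.integer(seed),
                 adapt = isTRUE(adapt),
                 target_acceptance = target_acceptance),
            class = "chain_config")
}

#' Scalar random-walk Metropolis step
#'
#' Proposes \code{current + N(0, step_sd^2)} and accepts with the usual
#' Metropolis probability for the (possibly truncated) target; proposals
#' outside \code{[lower, upper]} are rejected immediately, which handles
#' truncation exactly and preserves detailed balance for the truncated
#' target.
#'
#' @param current current value; \code{logpost(current)} must be finite.
#' @param logpost function returning the unnormalised log target at a scalar.
#' @param step_sd proposal standard deviation.
#' @param lower,upper support of the target.
#' @return list with \code{value}, \code{accepted} (logical),
#'   \code{logpost} (log target at the returned value).
#' @export
rw_metropolis_step <- function(current, logpost, step_sd,
                               lower = -Inf, upper = Inf) {
  lp0 <- logpost(current)
  if (!is.finite(lp0)) stop("rw_metropolis_step: log posterior is not ",
                            "finite at the current value")
  prop <- current + stats::rnorm(1, 0, step_sd)
  if (prop < lower || prop > upper)
    return(list(value = current, accepted = FALSE, logpost = lp0))
  lp1 <- logpost(prop)
  if (is.finite(lp1) && log(stats::runif(1)) < lp1 - lp0)
    list(value = prop, accepted = TRUE, logpost = lp1)
  else
    list(value = current, accepted = FALSE, logpost = lp0)
}

## Vectorised random-walk Metropolis over conditionally independent
## coordinates: lp_fun(values) returns the vector of per-coordinate log
## full-conditionals. Coordinates outside [lower, upper] auto-reject.
mh_vec <- function(cur, lp_fun, step_sd, lower = -Inf, upper = Inf) {
  lp0 <- lp_fun(cur)
  prop <- cur + stats::rnorm(length(cur), 0, step_sd)
  ok <- prop >= lower & prop <= upper
  lp1 <- rep(-Inf, length(cur))
  if (any(ok)) {
    tmp <- cur
    tmp[ok] <- prop[ok]
    lp1[ok] <- lp_fun(tmp)[ok]
  }
  acc <- ok & is.finite(lp1) & log(stats::runif(length(cur))) < lp1 - lp0
  cur[acc] <- prop[acc]
  list(value = cur, accepted = acc)
}

## Robbins-Monro step-size adaptation (burn-in only); acc may be a vector
## of 0/1 indicators matched to step_sd
adapt_step <- function(step_sd, acc, iter, target = 0.234) {
  a <- as.numeric(acc)
  gain <- min(0.5, 3 / sqrt(iter + 10))
  new <- pmin(pmax(step_sd * exp(gain * (a - target)), 1e-8), 50)
  new[is.na(a)] <- step_sd[is.na(a)]       # NA: block not updated by MH
  new
}

#' One Metropolis-within-Gibbs sweep
#'
#' Applies every update block of a model once, in the model's fixed order
#' (population level first, then condition, gene and repeat levels). The
#' model object is a list with elements \code{init(data, priors)},
#' \code{sweep(state, tuning)}, \code{tuning0(state)} and
#' \code{monitor(state)}; \code{sweep} returns
#' \code{list(state = , accepted = named list)}.
#'
#' @param model a model object (see Details).
#' @param state current state list.
#' @param tuning named list of proposal step sizes.
#' @return \code{list(state, accepted)}.
#' @export
gibbs_sweep <- function(model, state, tuning) {
  out <- model$sweep(state, tuning)
  if (!is.list(out) || is.null(out$state))
    stop("gibbs_sweep: model$sweep must return list(state, accepted)")
  out
}

#' Run a Metropolis-within-Gibbs chain
#'
#' Generic driver shared by all model fits: seeds the RNG, checks the
#' initial state, adapts proposal scales during burn-in, then records
#' \code{samples} thinned draws with frozen proposals. Identical inputs
#' (including \code{config$seed}) give bit-identical output.
#'
#' @param model model object (see \code{\link{gibbs_sweep}}).
#' @param data model data, passed to \code{model$init}.
#' @param priors prior list, passed to \code{model$init}.
#' @param config a \code{\link{chain_config}}.
#' @return An object of class \code{"qfa_draws"}: list with \code{draws}
#'   (samples x parameters matrix), \code{accept} (mean acceptance rate per
#'   block over the sampling phase), \code{config} and \code{tuning}.
#' @export
run_chain <- function(model, data, priors, config = chain_config()) {
  stopifnot(inherits(config, "chain_config"))
  set.seed(config$seed)
  state <- model$init(data, priors)
  tuning <- model$tuning0(state)
  lp <- model$logpost(state)
  if (!is.finite(lp)) {
    bad <- if (!is.null(model$blame)) model$blame(state) else "unknown"
    stop("run_chain: initial log posterior is not finite (parameter block: ",
         bad, ")")
  }

  for (i in seq_len(config$burnin)) {
    out <- model$sweep(state, tuning)
    state <- out$state
    if (config$adapt) {
      for (b in names(tuning)) {
        a <- out$accepted[[b]]
        if (!is.null(a))
          tuning[[b]] <- adapt_step(tuning[[b]], a, i,
                                    config$target_acceptance)
      }
    }
  }

  m0 <- model$monitor(state)
  draws <- matrix(NA_real_, config$samples, length(m0),
                  dimnames = list(NULL, names(m0)))
  accN <- lapply(tuning, function(s) 0 * as.numeric(s))
  nsweep <- 0L
  for (j in seq_len(config$samples)) {
    for (k in seq_len(config$thin)) {
      out <- model$sweep(state, tuning)
      state <- out$state
      nsweep <- nsweep + 1L
      for (b in names(accN)) {
        a <- as.numeric(out$accepted[[b]])
        if (length(a)) accN[[b]] <- accN[[b]] + ifelse(is.na(a), 0, a)
      }
    }
    draws[j, ] <- model$monitor(state)
  }
  accept <- vapply(accN, function(v) mean(v) / nsweep, numeric(1))

  structure(list(draws = draws, accept = accept, config = config,
                 tuning = tuning, final_state = state),
            class = "qfa_draws")
}

#' Convergence and mixing diagnostics
#'
#' Per-parameter summaries of an MCMC sample: posterior mean and SD,
#' effective sample size (Geyer initial-positive-sequence estimator), a
#' Geweke-style stationarity z score comparing the means of the first 10%
#' and last 50% of the chain, and the lag-1 autocorrelation. A parameter is
#' flagged when |z| > 2 or ESS < 10% of the number of draws. Constant
#' chains (legitimate for indicator variables) are flagged with \code{NA}
#' diagnostics rather than raising an error.
#'
#' @param draws a \code{qfa_draws} object, or a numeric matrix of draws
#'   (rows = iterations).
#' @return Data frame: \code{parameter}, \code{mean}, \code{sd}, \code{ess},
#'   \code{z}, \code{acf1}, \code{flag}.
#' @export
mcmc_diagnostics <- function(draws) {
  x <- if (inherits(draws, "qfa_draws")) draws$draws else as.matrix(draws)
  stopifnot(nrow(x) >= 50)
  res <- lapply(colnames(x), function(p) {
    v <- x[, p]
    n <- length(v)
    if (stats::sd(v) == 0 || !is.finite(stats::sd(v))) {
      return(data.frame(parameter = p, mean = mean(v), sd = 0,
                        ess = NA_real_, z = NA_real_, acf1 = NA_real_,
                        flag = TRUE, stringsAsFactors = FALSE))
    }
    ess <- ess_geyer(v)
    a <- v[seq_len(max(1, floor(0.1 * n)))]
    b <- v[(n - floor(0.5 * n) + 1):n]
    se <- sqrt(spectral_var(a) / length(a) + spectral_var(b) / length(b))
    z <- if (se > 0) (mean(a) - mean(b)) / se else NA_real_
    r1 <- stats::cor(v[-n], v[-1])
    flag <- (is.finite(z) && abs(z) > 2) || ess < 0.1 * n
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v), ess = ess,
               z = z, acf1 = r1, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## Geyer (1992) initial positive sequence ESS
ess_geyer <- function(v) {
  n <- length(v)
  maxlag <- min(n - 1L, 2000L)
  rho <- stats::acf(v, lag.max = maxlag, plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    g <- rho[k] + rho[k + 1]
    if (g <= 0) break
    s <- s + g
    k <- k + 2
  }
  max(1, min(n, n / (1 + 2 * s)))
}

## crude spectral density at frequency zero (batch-mean variance) used for
## the Geweke-style z score
spectral_var <- function(v) {
  n <- length(v)
  b <- max(1L, floor(sqrt(n)))
  nb <- floor(n / b)
  if (nb < 2) return(stats::var(v))
  bm <- colMeans(matrix(v[seq_len(nb * b)], nrow = b))
  b * stats::var(bm)
}
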