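#' Separate hierarchical model (SHM) for one QFA screen
#'
#' Four-level Bayesian logistic growth model fitted to the time courses of
#' one screen (control or query) at a time. At the time-point level the
#' scaled densities are normal about the logistic solution,
#' \eqn{y_{lmn} \sim N\{x(t_{lmn}; K_{lm}, r_{lm}, P), \nu_l^{-1}\}}; the
#' repeat-level parameters \eqn{\log K_{lm} \le 0} and
#' \eqn{\log r_{lm} \le 3.5} are normal about gene-level locations
#' \eqn{K^o_l, r^o_l}, whose natural-scale values have scaled-t (3 df)
#' population priors; measurement precisions \eqn{\nu_l} and the
#' repeat-level precisions \eqn{\tau^K_l, \tau^r_l} have log-normal
#' hierarchical priors. A single inoculum density \eqn{P} is shared by all
#' cultures, since early densities sit below the camera detection
#' threshold and \eqn{P} is only identified by pooling.
#'
#' The truncations encode biology: carrying capacity cannot exceed the
#' maximum observable density (1 after scaling) and \eqn{\log r \le 3.5}
#' rules out doubling times faster than about 30 minutes;
#' \eqn{\log\tau^K_l \ge 0} guards the identifiability of near-dead
#' cultures.
#'
#' @param tc time-course data frame (see \code{\link{read_timecourses}})
#'   containing a single condition.
#' @param priors a \code{\link{qfa_priors}} list for model \code{"shm"}.
#' @param config a \code{\link{chain_config}}.
#' @return An object of class \code{"qfa_shm"}: list with \code{draws}
#'   (a \code{qfa_draws}), \code{data} (culture index), \code{priors},
#'   \code{condition}.
#' @seealso \code{\link{summarize_fitness}}, \code{\link{fit_ihm}},
#'   \code{\link{fit_jhm}}
#' @export
fit_shm <- function(tc, priors = qfa_priors("shm"),
                    config = chain_config()) {
  stopifnot(length(unique(tc$condition)) == 1)
  validate_priors(priors, "shm")
  dat <- build_culture_data(tc)
  model <- shm_model(dat, priors)
  draws <- run_chain(model, dat, priors, config)
  structure(list(draws = draws, data = dat, priors = priors,
                 condition = tc$condition[1]),
            class = "qfa_shm")
}

## ---- model definition -----------------------------------------------

shm_model <- function(dat, priors) {
  pr <- priors
  L <- dat$L; C <- dat$C; cl <- dat$cl
  nK_l <- gcount(cl, L)
  Nobs_l <- gsum(dat$nobs, cl, L)

  init <- function(dat, priors) shm_init(dat, priors)

  logpost <- function(s) shm_log_posterior_state(s, dat, pr)

  tuning0 <- function(s) list(
    lK = rep(0.03, C), lr = rep(0.03, C),
    Klo = rep(0.05, L), rlo = rep(0.05, L),
    ltK = rep(0.5, L), ltr = rep(0.5, L), lnu = rep(0.3, L),
    lP = 0.02, lKp = 0.1, lrp = 0.1, lsKo = 0.5, lsro = 0.5,
    lsnu = 0.5, lstK = 0.5, lstr = 0.5)

  sweep <- function(s, tun) {
    acc <- list()
    eKlo <- exp(s$Klo); erlo <- exp(s$rlo)

    ## -- population level --
    st <- rw_metropolis_step(s$lKp, function(v)
      ldnorm_prec(v, pr$K_mu, pr$eta_K_p) +
        sum(ldt3_prec(eKlo, exp(v), exp(s$lsKo))), tun$lKp)
    s$lKp <- st$value; acc$lKp <- st$accepted

    st <- rw_metropolis_step(s$lsKo, function(v)
      ldnorm_prec(v, pr$eta_K_o, pr$psi_K_o) +
        sum(ldt3_prec(eKlo, exp(s$lKp), exp(v))), tun$lsKo)
    s$lsKo <- st$value; acc$lsKo <- st$accepted

    st <- rw_metropolis_step(s$lrp, function(v)
      ldnorm_prec(v, pr$r_mu, pr$eta_r_p) +
        sum(ldt3_prec(erlo, exp(v), exp(s$lsro))), tun$lrp)
    s$lrp <- st$value; acc$lrp <- st$accepted

    st <- rw_metropolis_step(s$lsro, function(v)
      ldnorm_prec(v, pr$eta_r_o, pr$psi_r_o) +
        sum(ldt3_prec(erlo, exp(s$lrp), exp(v))), tun$lsro)
    s$lsro <- st$value; acc$lsro <- st$accepted

    ## direct conjugate draws for the normal hyper-means
    s$nup <- rnorm_conj(pr$nu_mu, pr$eta_nu_p, exp(s$lsnu), sum(s$lnu), L)
    s$tKp <- rnorm_conj(pr$tau_K_mu, pr$eta_tau_K_p, exp(s$lstK),
                        sum(s$ltK), L)
    s$trp <- rnorm_conj(pr$tau_r_mu, pr$eta_tau_r_p, exp(s$lstr),
                        sum(s$ltr), L)

    st <- rw_metropolis_step(s$lsnu, function(v)
      ldnorm_prec(v, pr$eta_nu, pr$psi_nu) +
        sum(ldnorm_prec(s$lnu, s$nup, exp(v))), tun$lsnu)
    s$lsnu <- st$value; acc$lsnu <- st$accepted

    st <- rw_metropolis_step(s$lstK, function(v)
      ldnorm_prec(v, pr$eta_tau_K, pr$psi_tau_K) +
        sum(ldnorm_prec(s$ltK, s$tKp, exp(v))), tun$lstK)
    s$lstK <- st$value; acc$lstK <- st$accepted

    st <- rw_metropolis_step(s$lstr, function(v)
      ldnorm_prec(v, pr$eta_tau_r, pr$psi_tau_r) +
        sum(ldnorm_prec(s$ltr, s$trp, exp(v))), tun$lstr)
    s$lstr <- st$value; acc$lstr <- st$accepted

    ## shared inoculum density P (full-likelihood Metropolis)
    nu_c <- exp(s$lnu)[cl]
    lpP <- function(lP, rss) ldnorm_prec(lP, pr$P_mu, pr$eta_P) -
      0.5 * sum(nu_c * rss)
    propP <- s$lP + stats::rnorm(1, 0, tun$lP)
    rssP <- rss_cultures(dat, exp(s$lK), exp(s$lr), exp(propP))
    aP <- log(stats::runif(1)) < lpP(propP, rssP) - lpP(s$lP, s$rss)
    if (aP) { s$lP <- propP; s$rss <- rssP }
    acc$lP <- aP

    ## -- gene (orf-deletion) level, vectorised --
    tauK <- exp(s$ltK); taur <- exp(s$ltr)
    sumlK <- gsum(s$lK, cl, L); sumlr <- gsum(s$lr, cl, L)

    lpKlo <- function(v) lp_t3exp(v, exp(s$lKp), exp(s$lsKo)) -
      0.5 * tauK * (nK_l * v^2 - 2 * v * sumlK)
    prop <- s$Klo + stats::rnorm(L, 0, tun$Klo)
    a <- log(stats::runif(L)) < lpKlo(prop) - lpKlo(s$Klo)
    s$Klo[a] <- prop[a]; acc$Klo <- a

    lprlo <- function(v) lp_t3exp(v, exp(s$lrp), exp(s$lsro)) -
      0.5 * taur * (nK_l * v^2 - 2 * v * sumlr)
    prop <- s$rlo + stats::rnorm(L, 0, tun$rlo)
    a <- log(stats::runif(L)) < lprlo(prop) - lprlo(s$rlo)
    s$rlo[a] <- prop[a]; acc$rlo <- a

    SSK <- gsum((s$lK - s$Klo[cl])^2, cl, L)
    lpltK <- function(v) ldnorm_prec(v, s$tKp, exp(s$lstK)) +
      0.5 * nK_l * v - 0.5 * exp(v) * SSK
    prop <- s$ltK + stats::rnorm(L, 0, tun$ltK)
    a <- prop >= 0 & log(stats::runif(L)) < lpltK(prop) - lpltK(s$ltK)
    s$ltK[a] <- prop[a]; acc$ltK <- a

    SSr <- gsum((s$lr - s$rlo[cl])^2, cl, L)
    lpltr <- function(v) ldnorm_prec(v, s$trp, exp(s$lstr)) +
      0.5 * nK_l * v - 0.5 * exp(v) * SSr
    prop <- s$ltr + stats::rnorm(L, 0, tun$ltr)
    a <- log(stats::runif(L)) < lpltr(prop) - lpltr(s$ltr)
    s$ltr[a] <- prop[a]; acc$ltr <- a

    RSS_l <- gsum(s$rss, cl, L)
    lplnu <- function(v) ldnorm_prec(v, s$nup, exp(s$lsnu)) +
      0.5 * Nobs_l * v - 0.5 * exp(v) * RSS_l
    prop <- s$lnu + stats::rnorm(L, 0, tun$lnu)
    a <- log(stats::runif(L)) < lplnu(prop) - lplnu(s$lnu)
    s$lnu[a] <- prop[a]; acc$lnu <- a

    ## -- repeat (culture) level, vectorised --
    tauK_c <- exp(s$ltK)[cl]; taur_c <- exp(s$ltr)[cl]
    nu_c <- exp(s$lnu)[cl]
    P <- exp(s$lP)

    prop <- s$lK + stats::rnorm(C, 0, tun$lK)
    ok <- prop <= 0
    rss_p <- rss_cultures(dat, exp(prop), exp(s$lr), P)
    dlp <- ldnorm_prec(prop, s$Klo[cl], tauK_c) -
      ldnorm_prec(s$lK, s$Klo[cl], tauK_c) -
      0.5 * nu_c * (rss_p - s$rss)
    a <- ok & log(stats::runif(C)) < dlp
    s$lK[a] <- prop[a]; s$rss[a] <- rss_p[a]; acc$lK <- a

    prop <- s$lr + stats::rnorm(C, 0, tun$lr)
    ok <- prop <= 3.5
    rss_p <- rss_cultures(dat, exp(s$lK), exp(prop), P)
    dlp <- ldnorm_prec(prop, s$rlo[cl], taur_c) -
      ldnorm_prec(s$lr, s$rlo[cl], taur_c) -
      0.5 * nu_c * (rss_p - s$rss)
    a <- ok & log(stats::runif(C)) < dlp
    s$lr[a] <- prop[a]; s$rss[a] <- rss_p[a]; acc$lr <- a

    list(state = s, accepted = acc)
  }

  monitor <- function(s) {
    cid <- paste(dat$orf_c, dat$rep, sep = ".")
    c(stats::setNames(exp(s$lK), paste0("K_", cid)),
      stats::setNames(exp(s$lr), paste0("r_", cid)),
      stats::setNames(exp(s$Klo), paste0("eKo_", dat$orfs)),
      stats::setNames(exp(s$rlo), paste0("ero_", dat$orfs)),
      stats::setNames(exp(s$lnu), paste0("nu_", dat$orfs)),
      stats::setNames(exp(s$ltK), paste0("tauK_", dat$orfs)),
      stats::setNames(exp(s$ltr), paste0("taur_", dat$orfs)),
      P = exp(s$lP), K_p = exp(s$lKp), r_p = exp(s$lrp),
      nu_p = s$nup, sigma_nu = exp(s$lsnu),
      sigma_K_o = exp(s$lsKo), sigma_r_o = exp(s$lsro),
      tau_K_p = s$tKp, tau_r_p = s$trp,
      sigma_tau_K = exp(s$lstK), sigma_tau_r = exp(s$lstr))
  }

  blame <- function(s) {
    if (any(!is.finite(s$lK)) || any(s$lK > 0)) return("log K_lm")
    if (any(!is.finite(s$lr)) || any(s$lr > 3.5)) return("log r_lm")
    if (any(s$ltK < 0)) return("log tau_K_l")
    "hyperparameters"
  }

  list(init = init, sweep = sweep, monitor = monitor, logpost = logpost,
       tuning0 = tuning0, blame = blame)
}

## initial state: least-squares repeat-level fits with P at its prior
## median, gene-level locations from medians of their children, precisions
## by method of moments
shm_init <- function(dat, pr) {
  C <- dat$C; L <- dat$L
  P0 <- exp(pr$P_mu)
  lK <- numeric(C); lr <- numeric(C)
  for (i in seq_len(C)) {
    ti <- dat$tmat[i, dat$obs[i, ]]
    yi <- dat$ymat[i, dat$obs[i, ]]
    f <- ls_fit_logistic(ti, yi, P_fixed = P0)
    lK[i] <- min(log(max(f$K, 2 * P0)), -1e-6)
    lr[i] <- min(log(max(f$r, 0.05)), 3.5 - 1e-6)
  }
  Klo <- as.numeric(tapply(lK, dat$cl, stats::median))
  rlo <- as.numeric(tapply(lr, dat$cl, stats::median))
  mom_prec <- function(x, g) {
    v <- as.numeric(tapply(x, g, stats::var))
    v[!is.finite(v) | v < 1e-6] <- 1e-2
    1 / v
  }
  ltK <- pmin(pmax(log(mom_prec(lK, dat$cl)), 0), 12)
  ltr <- pmin(pmax(log(mom_prec(lr, dat$cl)), -2), 12)
  rssK <- rss_cultures(dat, exp(lK), exp(lr), P0)
  RSS_l <- gsum(rssK, dat$cl, L)
  Nobs_l <- gsum(dat$nobs, dat$cl, L)
  lnu <- log(pmax(Nobs_l, 1) / pmax(RSS_l, 1e-12))
  lnu <- pmin(pmax(lnu, 0), 25)

  list(lK = lK, lr = lr, Klo = Klo, rlo = rlo, ltK = ltK, ltr = ltr,
       lnu = lnu, lP = pr$P_mu,
       lKp = log(max(stats::median(exp(Klo)), 1e-4)),
       lrp = log(max(stats::median(exp(rlo)), 1e-3)),
       lsKo = log(1 / max(stats::var(exp(Klo)), 1e-4)),
       lsro = log(1 / max(stats::var(exp(rlo)), 1e-4)),
       nup = mean(lnu), lsnu = log(1 / max(stats::var(lnu), 0.05)),
       tKp = max(mean(ltK), 0), lstK = log(1 / max(stats::var(ltK), 0.05)),
       trp = mean(ltr), lstr = log(1 / max(stats::var(ltr), 0.05)),
       rss = rssK)
}

#' Unnormalised SHM log posterior
#'
#' Sum of every density contribution of the separate hierarchical model at
#' the time-point, repeat, gene and population levels, with \code{-Inf}
#' whenever a truncation is violated. Used for validating states and in
#' tests; the sampler uses block-local differences of the same terms.
#'
#' @param state named list of model parameters (log-scale coordinates, as
#'   produced by the sampler; see source of \code{shm_model}).
#' @param tc time-course data frame (single condition).
#' @param priors \code{\link{qfa_priors}} for \code{"shm"}.
#' @return Scalar unnormalised log posterior.
#' @export
shm_log_posterior <- function(state, tc, priors) {
  dat <- build_culture_data(tc)
  s <- state
  if (is.null(s$rss))
    s$rss <- rss_cultures(dat, exp(s$lK), exp(s$lr), exp(s$lP))
  shm_log_posterior_state(s, dat, priors)
}

shm_log_posterior_state <- function(s, dat, pr) {
  if (any(s$lK > 0) || any(s$lr > 3.5) || any(s$ltK < 0)) return(-Inf)
  cl <- dat$cl
  nu_c <- exp(s$lnu)[cl]
  rss <- rss_cultures(dat, exp(s$lK), exp(s$lr), exp(s$lP))
  obs <- sum(0.5 * dat$nobs * (s$lnu[cl] - log(2 * pi)) - 0.5 * nu_c * rss)
  lp <- obs +
    sum(ldnorm_prec(s$lK, s$Klo[cl], exp(s$ltK)[cl])) +
    sum(ldnorm_prec(s$lr, s$rlo[cl], exp(s$ltr)[cl])) +
    sum(ldnorm_prec(s$ltK, s$tKp, exp(s$lstK))) +
    sum(ldnorm_prec(s$ltr, s$trp, exp(s$lstr))) +
    sum(lp_t3exp(s$Klo, exp(s$lKp), exp(s$lsKo))) +
    sum(lp_t3exp(s$rlo, exp(s$lrp), exp(s$lsro))) +
    sum(ldnorm_prec(s$lnu, s$nup, exp(s$lsnu))) +
    ldnorm_prec(s$lKp, pr$K_mu, pr$eta_K_p) +
    ldnorm_prec(s$lrp, pr$r_mu, pr$eta_r_p) +
    ldnorm_prec(s$lP, pr$P_mu, pr$eta_P) +
    ldnorm_prec(s$nup, pr$nu_mu, pr$eta_nu_p) +
    ldnorm_prec(s$tKp, pr$tau_K_mu, pr$eta_tau_K_p) +
    ldnorm_prec(s$trp, pr$tau_r_mu, pr$eta_tau_r_p) +
    ldnorm_prec(s$lsKo, pr$eta_K_o, pr$psi_K_o) +
    ldnorm_prec(s$lsro, pr$eta_r_o, pr$psi_r_o) +
    ldnorm_prec(s$lsnu, pr$eta_nu, pr$psi_nu) +
    ldnorm_prec(s$lstK, pr$eta_tau_K, pr$psi_tau_K) +
    ldnorm_prec(s$lstr, pr$eta_tau_r, pr$psi_tau_r)
  lp
}

#' Per-culture fitness from SHM posterior summaries
#'
#' Posterior means of the repeat-level logistic parameters
#' \eqn{(K_{lm}, r_{lm})} and the shared \eqn{P} are plugged into the
#' chosen fitness measure, giving the per-culture fitness table passed to
#' the interaction model in the two-stage analysis. Cultures whose
#' summarised curve cannot double (\eqn{K \le 2P}) are flagged dead with
#' fitness 0.
#'
#' @param fit a \code{qfa_shm} object.
#' @param measure \code{"DRDP"} (default), \code{"DR"} or \code{"DP"}.
#' @return Data frame: \code{orf}, \code{condition}, \code{repeat},
#'   \code{K}, \code{r}, \code{P}, \code{fitness}, \code{dead_flag}.
#' @export
summarize_fitness <- function(fit, measure = c("DRDP", "DR", "DP")) {
  stopifnot(inherits(fit, "qfa_shm"))
  measure <- match.arg(measure)
  dm <- colMeans(fit$draws$draws)
  dat <- fit$data
  cid <- paste(dat$orf_c, dat$rep, sep = ".")
  K <- dm[paste0("K_", cid)]
  r <- dm[paste0("r_", cid)]
  P <- dm["P"]
  dead <- K <= 2 * P
  f <- numeric(dat$C)
  if (measure == "DP") {
    f <- doubling_potential(pmax(K, P), P)
  } else {
    dr <- ifelse(dead, 0, doubling_rate(pmax(K, 2.000001 * P), r, P))
    dr[dead] <- 0
    f <- if (measure == "DR") dr else dr * doubling_potential(pmax(K, P), P)
  }
  data.frame(orf = dat$orf_c, condition = dat$cond, `repeat` = dat$rep,
             K = as.numeric(K), r = as.numeric(r), P = as.numeric(P),
             fitness = as.numeric(f), dead_flag = dead,
             check.names = FALSE, stringsAsFactors = FALSE,
             row.names = NULL)
}
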