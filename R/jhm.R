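#' Joint hierarchical model (JHM) for a pair of QFA screens
#'
#' One-stage Bayesian analysis: growth curves, condition effects and
#' genetic interactions are inferred simultaneously from the raw time
#' courses of both screens, so no univariate fitness summary is passed
#' between models and evidence for interaction pools across the two
#' logistic growth parameters. Repeat-level parameters are
#' \deqn{\log K_{clm} \sim N\{\alpha_c + K^o_l + \delta_l\gamma_{cl},
#'   (\tau^K_{cl})^{-1}\} I(-\infty, 0],}
#' \deqn{\log r_{clm} \sim N\{\beta_c + r^o_l + \delta_l\omega_{cl},
#'   (\tau^r_{cl})^{-1}\} I(-\infty, 3.5],}
#' with \eqn{\alpha_0 = \beta_0 = 0}, \eqn{\gamma_{0l} = \omega_{0l} = 0},
#' a single shared inoculum \eqn{P}, and condition-indexed precision
#' hierarchies. One indicator \eqn{\delta_l} gates both channels, so a gene
#' can be called on carrying-capacity evidence alone, growth-rate evidence
#' alone, or both - interactions that cancel in a combined fitness score
#' (and are invisible to the two-stage path) remain detectable.
#' \eqn{\delta_l} is drawn from its exact Bernoulli full conditional whose
#' likelihood ratio aggregates the K and r channels over all of the gene's
#' query repeats.
#'
#' @param tc time-course data frame containing both conditions (0 and 1).
#' @param priors \code{\link{qfa_priors}} for \code{"jhm"}.
#' @param config a \code{\link{chain_config}}.
#' @param query_effect call-labelling convention, see
#'   \code{\link{classify_and_rank}}.
#' @return Object of class \code{"qfa_jhm"}: \code{draws}, \code{calls}
#'   (via \code{\link{jhm_fitness_and_calls}}), \code{orfs}, \code{data},
#'   \code{priors}.
#' @export
fit_jhm <- function(tc, priors = qfa_priors("jhm"), config = chain_config(),
                    query_effect = c("deleterious", "beneficial")) {
  query_effect <- match.arg(query_effect)
  validate_priors(priors, "jhm")
  stopifnot(all(sort(unique(tc$condition)) == 0:1))
  dat <- build_culture_data(tc)
  model <- jhm_model(dat, priors)
  draws <- run_chain(model, dat, priors, config)
  fit <- structure(list(draws = draws, orfs = dat$orfs, data = dat,
                        priors = priors, query_effect = query_effect),
                   class = "qfa_jhm")
  fit$calls <- jhm_fitness_and_calls(fit, query_effect = query_effect)$calls
  fit
}

jhm_model <- function(dat, pr) {
  L <- dat$L; C <- dat$C; cl <- dat$cl
  is_q <- dat$cond == 1L
  gc <- dat$cond * L + cl                 # gene-condition group, 1..2L
  cond_g <- rep(0:1, each = L)            # condition of each group
  n_g <- gcount(gc, 2 * L)
  Nobs_g <- gsum(dat$nobs, gc, 2 * L)
  qc <- which(is_q)                       # query culture indices

  shiftK <- function(s) (s$alpha1 + s$delta[cl] * s$gam[cl]) * is_q
  shiftr <- function(s) (s$beta1 + s$delta[cl] * s$om[cl]) * is_q

  init <- function(dat, priors) jhm_init(dat, pr, L, cl, is_q, gc)

  logpost <- function(s) jhm_log_posterior_state(s, dat, pr)

  tuning0 <- function(s) list(
    lK = rep(0.03, C), lr = rep(0.03, C),
    Klo = rep(0.05, L), rlo = rep(0.05, L),
    gam = rep(0.1, L), om = rep(0.1, L),
    ltK = rep(0.5, 2 * L), ltr = rep(0.5, 2 * L), lnu = rep(0.3, 2 * L),
    lP = 0.02, lKp = 0.1, lrp = 0.1, lsKo = 0.5, lsro = 0.5,
    lsnu = 0.5, lsg = 0.5, lso = 0.5,
    lstK = rep(0.5, 2), lstr = rep(0.5, 2))

  sweep <- function(s, tun) {
    acc <- list()
    eKlo <- exp(s$Klo); erlo <- exp(s$rlo)

    ## population level
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

    s$nup <- rnorm_conj(pr$nu_mu, pr$eta_nu_p, exp(s$lsnu), sum(s$lnu),
                        2 * L)
    st <- rw_metropolis_step(s$lsnu, function(v)
      ldnorm_prec(v, pr$eta_nu, pr$psi_nu) +
        sum(ldnorm_prec(s$lnu, s$nup, exp(v))), tun$lsnu)
    s$lsnu <- st$value; acc$lsnu <- st$accepted

    st <- rw_metropolis_step(s$lsg, function(v)
      ldnorm_prec(v, pr$eta_gamma, pr$psi_gamma) +
        sum(lp_t3exp(s$gam, 1, exp(v))), tun$lsg)
    s$lsg <- st$value; acc$lsg <- st$accepted
    st <- rw_metropolis_step(s$lso, function(v)
      ldnorm_prec(v, pr$eta_omega, pr$psi_omega) +
        sum(lp_t3exp(s$om, 1, exp(v))), tun$lso)
    s$lso <- st$value; acc$lso <- st$accepted

    ## condition level: precision hierarchies, per condition
    accK <- logical(2); accr <- logical(2)
    for (ci in 1:2) {
      gi <- which(cond_g == ci - 1)
      s$tKp_c[ci] <- rnorm_conj(pr$tau_K_mu, pr$eta_tau_K_p,
                                exp(s$lstK_c[ci]), sum(s$ltK[gi]), L)
      st <- rw_metropolis_step(s$lstK_c[ci], function(v)
        ldnorm_prec(v, pr$eta_tau_K, pr$psi_tau_K) +
          sum(ldnorm_prec(s$ltK[gi], s$tKp_c[ci], exp(v))), tun$lstK[ci])
      s$lstK_c[ci] <- st$value; accK[ci] <- st$accepted
      s$trp_c[ci] <- rnorm_conj(pr$tau_r_mu, pr$eta_tau_r_p,
                                exp(s$lstr_c[ci]), sum(s$ltr[gi]), L)
      st <- rw_metropolis_step(s$lstr_c[ci], function(v)
        ldnorm_prec(v, pr$eta_tau_r, pr$psi_tau_r) +
          sum(ldnorm_prec(s$ltr[gi], s$trp_c[ci], exp(v))), tun$lstr[ci])
      s$lstr_c[ci] <- st$value; accr[ci] <- st$accepted
    }
    acc$lstK <- accK; acc$lstr <- accr

    ## condition effects: conjugate normal draws (query repeat level)
    tauK_q <- exp(s$ltK)[gc[qc]]
    zK <- s$lK[qc] - s$Klo[cl[qc]] - (s$delta * s$gam)[cl[qc]]
    s$alpha1 <- rnorm_conj(pr$alpha_mu, pr$eta_alpha, 1,
                           sum(tauK_q * zK), sum(tauK_q))
    taur_q <- exp(s$ltr)[gc[qc]]
    zr <- s$lr[qc] - s$rlo[cl[qc]] - (s$delta * s$om)[cl[qc]]
    s$beta1 <- rnorm_conj(pr$beta_mu, pr$eta_beta, 1,
                          sum(taur_q * zr), sum(taur_q))

    ## shared inoculum density
    nu_c <- exp(s$lnu)[gc]
    lpP <- function(lP, rss) ldnorm_prec(lP, pr$P_mu, pr$eta_P) -
      0.5 * sum(nu_c * rss)
    propP <- s$lP + stats::rnorm(1, 0, tun$lP)
    rssP <- rss_cultures(dat, exp(s$lK), exp(s$lr), exp(propP))
    aP <- log(stats::runif(1)) < lpP(propP, rssP) - lpP(s$lP, s$rss)
    if (aP) { s$lP <- propP; s$rss <- rssP }
    acc$lP <- aP

    ## gene level: locations (weighted by per-group precisions)
    tauK_c <- exp(s$ltK)[gc]; taur_c <- exp(s$ltr)[gc]
    zK <- s$lK - shiftK(s)
    SwK <- gsum(tauK_c, cl, L); SwzK <- gsum(tauK_c * zK, cl, L)
    lpKlo <- function(v) lp_t3exp(v, exp(s$lKp), exp(s$lsKo)) -
      0.5 * (SwK * v^2 - 2 * v * SwzK)
    prop <- s$Klo + stats::rnorm(L, 0, tun$Klo)
    a <- log(stats::runif(L)) < lpKlo(prop) - lpKlo(s$Klo)
    s$Klo[a] <- prop[a]; acc$Klo <- a

    zr <- s$lr - shiftr(s)
    Swr <- gsum(taur_c, cl, L); Swzr <- gsum(taur_c * zr, cl, L)
    lprlo <- function(v) lp_t3exp(v, exp(s$lrp), exp(s$lsro)) -
      0.5 * (Swr * v^2 - 2 * v * Swzr)
    prop <- s$rlo + stats::rnorm(L, 0, tun$rlo)
    a <- log(stats::runif(L)) < lprlo(prop) - lprlo(s$rlo)
    s$rlo[a] <- prop[a]; acc$rlo <- a

    ## delta: exact Bernoulli, K and r channels pooled over query repeats
    tq <- exp(s$ltK)[gc[qc]]; tr_ <- exp(s$ltr)[gc[qc]]
    lq <- cl[qc]
    m0K <- s$alpha1 + s$Klo[lq];  m1K <- m0K + s$gam[lq]
    m0r <- s$beta1 + s$rlo[lq];   m1r <- m0r + s$om[lq]
    dll <- gsum(-0.5 * tq * ((s$lK[qc] - m1K)^2 - (s$lK[qc] - m0K)^2) -
                  0.5 * tr_ * ((s$lr[qc] - m1r)^2 - (s$lr[qc] - m0r)^2),
                lq, L)
    s$delta <- stats::rbinom(L, 1, stats::plogis(stats::qlogis(pr$p) + dll))

    ## interaction effects: Metropolis when active, prior refresh when idle
    sg <- exp(s$lsg); so <- exp(s$lso)
    likg <- function(v) gsum(-0.5 * tq *
                               (s$lK[qc] - (s$alpha1 + s$Klo[lq] + v[lq]))^2,
                             lq, L)
    lpG <- function(v) lp_t3exp(v, 1, sg) + s$delta * likg(v)
    prop <- s$gam + stats::rnorm(L, 0, tun$gam)
    a <- log(stats::runif(L)) < lpG(prop) - lpG(s$gam)
    a <- a & s$delta == 1L
    s$gam[a] <- prop[a]
    idle <- s$delta == 0L
    if (any(idle))
      s$gam[idle] <- log(vapply(which(idle), function(i)
        rkernel(qfa_kernel("scaled_t3", 1, sg, lower = 1e-12)), numeric(1)))
    accg <- as.numeric(a); accg[idle] <- NA
    acc$gam <- accg

    liko <- function(v) gsum(-0.5 * tr_ *
                               (s$lr[qc] - (s$beta1 + s$rlo[lq] + v[lq]))^2,
                             lq, L)
    lpO <- function(v) lp_t3exp(v, 1, so) + s$delta * liko(v)
    prop <- s$om + stats::rnorm(L, 0, tun$om)
    a <- log(stats::runif(L)) < lpO(prop) - lpO(s$om)
    a <- a & s$delta == 1L
    s$om[a] <- prop[a]
    if (any(idle))
      s$om[idle] <- log(vapply(which(idle), function(i)
        rkernel(qfa_kernel("scaled_t3", 1, so, lower = 1e-12)), numeric(1)))
    acco <- as.numeric(a); acco[idle] <- NA
    acc$om <- acco

    ## gene-condition precisions
    mK <- s$Klo[cl] + shiftK(s)
    SSK <- gsum((s$lK - mK)^2, gc, 2 * L)
    lpltK <- function(v) ldnorm_prec(v, s$tKp_c[cond_g + 1],
                                     exp(s$lstK_c)[cond_g + 1]) +
      0.5 * n_g * v - 0.5 * exp(v) * SSK
    prop <- s$ltK + stats::rnorm(2 * L, 0, tun$ltK)
    a <- prop >= 0 & log(stats::runif(2 * L)) < lpltK(prop) - lpltK(s$ltK)
    s$ltK[a] <- prop[a]; acc$ltK <- a

    mr <- s$rlo[cl] + shiftr(s)
    SSr <- gsum((s$lr - mr)^2, gc, 2 * L)
    lpltr <- function(v) ldnorm_prec(v, s$trp_c[cond_g + 1],
                                     exp(s$lstr_c)[cond_g + 1]) +
      0.5 * n_g * v - 0.5 * exp(v) * SSr
    prop <- s$ltr + stats::rnorm(2 * L, 0, tun$ltr)
    a <- log(stats::runif(2 * L)) < lpltr(prop) - lpltr(s$ltr)
    s$ltr[a] <- prop[a]; acc$ltr <- a

    RSS_g <- gsum(s$rss, gc, 2 * L)
    lplnu <- function(v) ldnorm_prec(v, s$nup, exp(s$lsnu)) +
      0.5 * Nobs_g * v - 0.5 * exp(v) * RSS_g
    prop <- s$lnu + stats::rnorm(2 * L, 0, tun$lnu)
    a <- log(stats::runif(2 * L)) < lplnu(prop) - lplnu(s$lnu)
    s$lnu[a] <- prop[a]; acc$lnu <- a

    ## repeat (culture) level
    tauK_c <- exp(s$ltK)[gc]; taur_c <- exp(s$ltr)[gc]
    nu_c <- exp(s$lnu)[gc]
    P <- exp(s$lP)
    mK <- s$Klo[cl] + shiftK(s)
    prop <- s$lK + stats::rnorm(C, 0, tun$lK)
    ok <- prop <= 0
    rss_p <- rss_cultures(dat, exp(prop), exp(s$lr), P)
    dlp <- ldnorm_prec(prop, mK, tauK_c) - ldnorm_prec(s$lK, mK, tauK_c) -
      0.5 * nu_c * (rss_p - s$rss)
    a <- ok & log(stats::runif(C)) < dlp
    s$lK[a] <- prop[a]; s$rss[a] <- rss_p[a]; acc$lK <- a

    mr <- s$rlo[cl] + shiftr(s)
    prop <- s$lr + stats::rnorm(C, 0, tun$lr)
    ok <- prop <= 3.5
    rss_p <- rss_cultures(dat, exp(s$lK), exp(prop), P)
    dlp <- ldnorm_prec(prop, mr, taur_c) - ldnorm_prec(s$lr, mr, taur_c) -
      0.5 * nu_c * (rss_p - s$rss)
    a <- ok & log(stats::runif(C)) < dlp
    s$lr[a] <- prop[a]; s$rss[a] <- rss_p[a]; acc$lr <- a

    list(state = s, accepted = acc)
  }

  monitor <- function(s) {
    orfs <- dat$orfs
    cid <- paste(dat$orf_c, dat$cond, dat$rep, sep = ".")
    gid <- paste(rep(orfs, 2), rep(0:1, each = L), sep = ".")
    c(stats::setNames(exp(s$lK), paste0("K_", cid)),
      stats::setNames(exp(s$lr), paste0("r_", cid)),
      stats::setNames(exp(s$Klo), paste0("eKo_", orfs)),
      stats::setNames(exp(s$rlo), paste0("ero_", orfs)),
      stats::setNames(as.numeric(s$delta), paste0("delta_", orfs)),
      stats::setNames(s$gam, paste0("gamma_", orfs)),
      stats::setNames(s$om, paste0("omega_", orfs)),
      stats::setNames(s$delta * s$gam, paste0("dg_", orfs)),
      stats::setNames(s$delta * s$om, paste0("dw_", orfs)),
      stats::setNames(exp(s$ltK), paste0("tauK_", gid)),
      stats::setNames(exp(s$ltr), paste0("taur_", gid)),
      stats::setNames(exp(s$lnu), paste0("nu_", gid)),
      alpha1 = s$alpha1, beta1 = s$beta1,
      P = exp(s$lP), K_p = exp(s$lKp), r_p = exp(s$lrp),
      nu_p = s$nup, sigma_nu = exp(s$lsnu),
      sigma_K_o = exp(s$lsKo), sigma_r_o = exp(s$lsro),
      sigma_gamma = exp(s$lsg), sigma_omega = exp(s$lso),
      tau_K_p0 = s$tKp_c[1], tau_K_p1 = s$tKp_c[2],
      tau_r_p0 = s$trp_c[1], tau_r_p1 = s$trp_c[2])
  }

  blame <- function(s) {
    if (any(!is.finite(s$lK)) || any(s$lK > 0)) return("log K_clm")
    if (any(!is.finite(s$lr)) || any(s$lr > 3.5)) return("log r_clm")
    if (any(s$ltK < 0)) return("log tau_K_cl")
    "hyperparameters"
  }

  list(init = init, sweep = sweep, monitor = monitor, logpost = logpost,
       tuning0 = tuning0, blame = blame)
}

jhm_init <- function(dat, pr, L, cl, is_q, gc) {
  C <- dat$C
  P0 <- exp(pr$P_mu)
  lK <- numeric(C); lr <- numeric(C)
  for (i in seq_len(C)) {
    ti <- dat$tmat[i, dat$obs[i, ]]
    yi <- dat$ymat[i, dat$obs[i, ]]
    f <- ls_fit_logistic(ti, yi, P_fixed = P0)
    lK[i] <- min(log(max(f$K, 2 * P0)), -1e-6)
    lr[i] <- min(log(max(f$r, 0.05)), 3.5 - 1e-6)
  }
  med_by <- function(x, idx) {
    out <- numeric(L) + stats::median(x)
    m <- tapply(x, idx, stats::median)
    out[as.integer(names(m))] <- m
    out
  }
  Klo <- med_by(lK[!is_q], cl[!is_q])
  rlo <- med_by(lr[!is_q], cl[!is_q])
  alpha1 <- mean(lK[is_q]) - mean(lK[!is_q])
  beta1 <- mean(lr[is_q]) - mean(lr[!is_q])
  mK <- Klo[cl] + alpha1 * is_q
  mr <- rlo[cl] + beta1 * is_q
  mom <- function(resid, g, lo) {
    v <- numeric(2 * L) + 1e-2
    vv <- tapply(resid^2, g, mean)
    vv[!is.finite(vv) | vv < 1e-6] <- 1e-2
    v[as.integer(names(vv))] <- vv
    pmin(pmax(log(1 / v), lo), 12)
  }
  ltK <- mom(lK - mK, gc, 0)
  ltr <- mom(lr - mr, gc, -2)
  rss <- rss_cultures(dat, exp(lK), exp(lr), P0)
  RSS_g <- gsum(rss, gc, 2 * L); Nobs_g <- gsum(dat$nobs, gc, 2 * L)
  lnu <- pmin(pmax(log(pmax(Nobs_g, 1) / pmax(RSS_g, 1e-12)), 0), 25)

  list(lK = lK, lr = lr, Klo = Klo, rlo = rlo,
       delta = integer(L), gam = numeric(L), om = numeric(L),
       alpha1 = alpha1, beta1 = beta1,
       ltK = ltK, ltr = ltr, lnu = lnu, lP = pr$P_mu,
       lKp = log(max(stats::median(exp(Klo)), 1e-4)),
       lrp = log(max(stats::median(exp(rlo)), 1e-3)),
       lsKo = log(1 / max(stats::var(exp(Klo)), 1e-4)),
       lsro = log(1 / max(stats::var(exp(rlo)), 1e-4)),
       nup = mean(lnu), lsnu = log(1 / max(stats::var(lnu), 0.05)),
       tKp_c = rep(max(mean(ltK), 0), 2),
       lstK_c = rep(log(1 / max(stats::var(ltK), 0.05)), 2),
       trp_c = rep(mean(ltr), 2),
       lstr_c = rep(log(1 / max(stats::var(ltr), 0.05)), 2),
       lsg = pr$eta_gamma, lso = pr$eta_omega,
       rss = rss)
}

#' Unnormalised JHM log posterior
#'
#' Full joint density of the joint hierarchical model at a given state;
#' \code{-Inf} whenever a truncation is violated. Used in tests against an
#' independently assembled sum of density terms.
#'
#' @param state named list of parameters (see source of \code{jhm_model}).
#' @param tc two-condition time-course data frame.
#' @param priors \code{\link{qfa_priors}} for \code{"jhm"}.
#' @return Scalar unnormalised log posterior.
#' @export
jhm_log_posterior <- function(state, tc, priors) {
  dat <- build_culture_data(tc)
  s <- state
  if (is.null(s$rss))
    s$rss <- rss_cultures(dat, exp(s$lK), exp(s$lr), exp(s$lP))
  jhm_log_posterior_state(s, dat, priors)
}

jhm_log_posterior_state <- function(s, dat, pr) {
  if (any(s$lK > 0) || any(s$lr > 3.5) || any(s$ltK < 0)) return(-Inf)
  L <- dat$L; cl <- dat$cl
  is_q <- dat$cond == 1L
  gc <- dat$cond * L + cl
  cond_g <- rep(0:1, each = L)
  mK <- s$Klo[cl] + (s$alpha1 + s$delta[cl] * s$gam[cl]) * is_q
  mr <- s$rlo[cl] + (s$beta1 + s$delta[cl] * s$om[cl]) * is_q
  nu_c <- exp(s$lnu)[gc]
  rss <- rss_cultures(dat, exp(s$lK), exp(s$lr), exp(s$lP))
  obs <- sum(0.5 * dat$nobs * (s$lnu[gc] - log(2 * pi)) - 0.5 * nu_c * rss)
  obs +
    sum(ldnorm_prec(s$lK, mK, exp(s$ltK)[gc])) +
    sum(ldnorm_prec(s$lr, mr, exp(s$ltr)[gc])) +
    sum(ldnorm_prec(s$ltK, s$tKp_c[cond_g + 1], exp(s$lstK_c)[cond_g + 1])) +
    sum(ldnorm_prec(s$ltr, s$trp_c[cond_g + 1], exp(s$lstr_c)[cond_g + 1])) +
    sum(ldnorm_prec(s$lnu, s$nup, exp(s$lsnu))) +
    sum(lp_t3exp(s$Klo, exp(s$lKp), exp(s$lsKo))) +
    sum(lp_t3exp(s$rlo, exp(s$lrp), exp(s$lsro))) +
    sum(lp_t3exp(s$gam, 1, exp(s$lsg))) +
    sum(lp_t3exp(s$om, 1, exp(s$lso))) +
    sum(ifelse(s$delta == 1L, log(pr$p), log(1 - pr$p))) +
    ldnorm_prec(s$alpha1, pr$alpha_mu, pr$eta_alpha) +
    ldnorm_prec(s$beta1, pr$beta_mu, pr$eta_beta) +
    sum(ldnorm_prec(s$tKp_c, pr$tau_K_mu, pr$eta_tau_K_p)) +
    sum(ldnorm_prec(s$trp_c, pr$tau_r_mu, pr$eta_tau_r_p)) +
    sum(ldnorm_prec(s$lstK_c, pr$eta_tau_K, pr$psi_tau_K)) +
    sum(ldnorm_prec(s$lstr_c, pr$eta_tau_r, pr$psi_tau_r)) +
    ldnorm_prec(s$lKp, pr$K_mu, pr$eta_K_p) +
    ldnorm_prec(s$lrp, pr$r_mu, pr$eta_r_p) +
    ldnorm_prec(s$lP, pr$P_mu, pr$eta_P) +
    ldnorm_prec(s$nup, pr$nu_mu, pr$eta_nu_p) +
    ldnorm_prec(s$lsKo, pr$eta_K_o, pr$psi_K_o) +
    ldnorm_prec(s$lsro, pr$eta_r_o, pr$psi_r_o) +
    ldnorm_prec(s$lsnu, pr$eta_nu, pr$psi_nu) +
    ldnorm_prec(s$lsg, pr$eta_gamma, pr$psi_gamma) +
    ldnorm_prec(s$lso, pr$eta_omega, pr$psi_omega)
}

#' Gene-level fitness plug-ins and interaction calls from a JHM fit
#'
#' Control fitness is evaluated from the posterior means of
#' \eqn{(\exp(K^o_l), \exp(r^o_l))} and query fitness from those of
#' \eqn{(\exp(\alpha_1 + K^o_l + \delta_l\gamma_{1l}),
#' \exp(\beta_1 + r^o_l + \delta_l\omega_{1l}))}, with the shared posterior
#' mean \eqn{P}. A gene is a significant interactor iff its posterior
#' indicator mean exceeds 0.5. The overall direction (suppressor/enhancer
#' of a deleterious query's fitness defect) comes from the sign of the
#' combined fitness shift relative to the no-interaction expectation;
#' per-channel effects (posterior means of \eqn{\delta\gamma} and
#' \eqn{\delta\omega}) are also reported, since a gene may be a suppressor
#' in terms of carrying capacity but an enhancer in terms of growth rate.
#'
#' @param fit a \code{qfa_jhm} object.
#' @param measure fitness measure for the plug-in fitnesses.
#' @param query_effect labelling convention (see
#'   \code{\link{classify_and_rank}}).
#' @return List with \code{fitness} (per-gene control/query fitness table)
#'   and \code{calls} (ranked calls with \code{strength_K},
#'   \code{strength_r}).
#' @export
jhm_fitness_and_calls <- function(fit, measure = c("DRDP", "DR", "DP"),
                                  query_effect = c("deleterious",
                                                   "beneficial")) {
  stopifnot(inherits(fit, "qfa_jhm"))
  measure <- match.arg(measure)
  query_effect <- match.arg(query_effect)
  d <- fit$draws$draws
  orfs <- fit$orfs
  eKo <- d[, paste0("eKo_", orfs), drop = FALSE]
  ero <- d[, paste0("ero_", orfs), drop = FALSE]
  dg <- d[, paste0("dg_", orfs), drop = FALSE]
  dw <- d[, paste0("dw_", orfs), drop = FALSE]
  a1 <- d[, "alpha1"]; b1 <- d[, "beta1"]
  P <- mean(d[, "P"])

  K0 <- colMeans(eKo); r0 <- colMeans(ero)
  Kq <- colMeans(exp(a1) * eKo * exp(dg))
  rq <- colMeans(exp(b1) * ero * exp(dw))
  Kq0 <- colMeans(exp(a1) * eKo)          # no-interaction expectation
  rq0 <- colMeans(exp(b1) * ero)

  fit_of <- function(K, r) {
    dead <- K <= 2 * P
    f <- switch(measure,
      DP = doubling_potential(pmax(K, P), P),
      DR = ifelse(dead, 0, doubling_rate(pmax(K, 2.000001 * P), r, P)),
      DRDP = ifelse(dead, 0,
                    doubling_rate(pmax(K, 2.000001 * P), r, P) *
                      doubling_potential(pmax(K, P), P)))
    f[dead & measure != "DP"] <- 0
    f
  }
  F0 <- fit_of(K0, r0); Fq <- fit_of(Kq, rq); Fq0 <- fit_of(Kq0, rq0)

  delta_hat <- colMeans(d[, paste0("delta_", orfs), drop = FALSE])
  strength_K <- colMeans(dg); strength_r <- colMeans(dw)
  shift <- Fq - Fq0
  pos <- if (query_effect == "deleterious") "suppressor" else "enhancer"
  neg <- if (query_effect == "deleterious") "enhancer" else "suppressor"
  direction <- ifelse(shift > 0, pos, ifelse(shift < 0, neg, "none"))
  significant <- delta_hat > 0.5
  calls <- data.frame(orf = orfs, delta_hat = as.numeric(delta_hat),
                      strength = as.numeric(shift),
                      strength_K = as.numeric(strength_K),
                      strength_r = as.numeric(strength_r),
                      direction = direction,
                      label = ifelse(significant, direction, "none"),
                      significant = significant,
                      stringsAsFactors = FALSE, row.names = NULL)
  calls <- calls[order(-abs(calls$strength)), , drop = FALSE]
  calls$rank <- seq_len(nrow(calls))
  rownames(calls) <- NULL
  fitness <- data.frame(orf = orfs, F_control = as.numeric(F0),
                        F_query = as.numeric(Fq),
                        F_query_independent = as.numeric(Fq0),
                        K_control = as.numeric(K0), r_control = as.numeric(r0),
                        K_query = as.numeric(Kq), r_query = as.numeric(rq),
                        P = P, stringsAsFactors = FALSE, row.names = NULL)
  list(fitness = fitness, calls = calls)
}

#' Fitted and expected-no-interaction growth curves for one gene
#'
#' Evaluates, on a time grid, the query-condition growth curve at the
#' gene-level posterior means (i) as fitted (interaction terms included)
#' and (ii) expected under no interaction (indicator forced to 0, i.e.
#' \eqn{K = \exp(\alpha_1 + K^o_l)}, \eqn{r = \exp(\beta_1 + r^o_l)}).
#' Divergence of the two curves is the visual evidence of interaction.
#'
#' @param fit a \code{qfa_jhm} object.
#' @param orf gene identifier.
#' @param t time grid, days.
#' @return Data frame: \code{t}, \code{fitted}, \code{expected}.
#' @export
expected_curve_no_interaction <- function(fit, orf,
                                          t = seq(0, 4, length.out = 50)) {
  stopifnot(inherits(fit, "qfa_jhm"), orf %in% fit$orfs)
  d <- fit$draws$draws
  eKo <- d[, paste0("eKo_", orf)]; ero <- d[, paste0("ero_", orf)]
  dg <- d[, paste0("dg_", orf)]; dw <- d[, paste0("dw_", orf)]
  a1 <- d[, "alpha1"]; b1 <- d[, "beta1"]
  P <- mean(d[, "P"])
  Kf <- mean(exp(a1) * eKo * exp(dg)); rf <- mean(exp(b1) * ero * exp(dw))
  Ke <- mean(exp(a1) * eKo); re <- mean(exp(b1) * ero)
  data.frame(t = t,
             fitted = logistic_solution(t, Kf, rf, P),
             expected = logistic_solution(t, Ke, re, P))
}
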