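#' Interaction hierarchical model (IHM) on per-culture fitnesses
#'
#' Second stage of the two-stage Bayesian QFA analysis. Given per-culture
#' fitness scores from a control and a query screen, replicate fitnesses
#' are modelled as \eqn{F_{clm} \sim N\{\hat F_{cl}, \nu_{cl}^{-1}\}} with
#' \deqn{\hat F_{cl} = \exp(\alpha_c + Z_l + \delta_l \gamma_{cl}),}
#' \eqn{\alpha_0 = 0}, \eqn{\gamma_{0l} = 0}. Under Fisher's multiplicative
#' model of genetic independence the query/control fitness ratio is the
#' constant \eqn{e^{\alpha_1}} for every gene; the Bernoulli indicator
#' \eqn{\delta_l \sim \mathrm{Bern}(p)} switches on a gene-specific
#' deviation \eqn{\gamma_{1l}}, so the posterior mean \eqn{\hat\delta_l} is
#' the probability that gene \eqn{l} interacts with the query mutation.
#' Genes with \eqn{\hat\delta_l > 0.5} are called significant; the ranking
#' statistic is the posterior mean of \eqn{\delta_l\gamma_{1l}}.
#' Per-condition-per-gene precisions \eqn{\nu_{cl}} let the variance differ
#' between screens and between genes.
#'
#' \eqn{\delta_l} is drawn exactly from its Bernoulli full conditional;
#' when \eqn{\delta_l = 0} the idle \eqn{\gamma_{1l}} is refreshed from its
#' prior so it stays well defined.
#'
#' @param fitness data frame with columns \code{orf}, \code{condition}
#'   (0/1), \code{repeat} and \code{fitness} (per-culture fitness, any
#'   measure; the default pipeline uses DRDP).
#' @param priors \code{\link{qfa_priors}} for \code{"ihm"} (includes
#'   \code{p}, the prior interaction probability, default 0.05).
#' @param config a \code{\link{chain_config}}.
#' @param query_effect direction of the query condition's average fitness
#'   effect; used only to label calls (see
#'   \code{\link{classify_and_rank}}).
#' @return Object of class \code{"qfa_ihm"}: \code{draws}, \code{calls}
#'   (ranked interaction calls), \code{orfs}, \code{priors}.
#' @export
fit_ihm <- function(fitness, priors = qfa_priors("ihm"),
                    config = chain_config(),
                    query_effect = c("deleterious", "beneficial")) {
  query_effect <- match.arg(query_effect)
  validate_priors(priors, "ihm")
  if (!"fitness" %in% names(fitness) && "DRDP" %in% names(fitness))
    fitness$fitness <- fitness$DRDP
  stopifnot(all(c("orf", "condition", "fitness") %in% names(fitness)),
            all(fitness$condition %in% 0:1),
            length(unique(fitness$condition)) == 2)
  dat <- ihm_data(fitness)
  model <- ihm_model(dat, priors)
  draws <- run_chain(model, dat, priors, config)
  fit <- structure(list(draws = draws, orfs = dat$orfs, priors = priors,
                        data = dat, query_effect = query_effect),
                   class = "qfa_ihm")
  fit$calls <- classify_and_rank(fit, query_effect = query_effect)
  fit
}

ihm_data <- function(fitness) {
  orfs <- sort(unique(fitness$orf))
  L <- length(orfs)
  l <- match(fitness$orf, orfs)
  cond <- as.integer(fitness$condition)
  g <- cond * L + l                      # 1..L control, L+1..2L query
  list(orfs = orfs, L = L, F = fitness$fitness, l = l, cond = cond, g = g,
       is_q = cond == 1L, n_g = gcount(g, 2 * L))
}

ihm_model <- function(dat, pr) {
  L <- dat$L
  Fv <- dat$F; lidx <- dat$l; g <- dat$g; is_q <- dat$is_q
  n_g <- dat$n_g
  qobs <- which(is_q)
  lq <- lidx[qobs]; Fq <- Fv[qobs]; gq <- g[qobs]

  mu_obs <- function(Zl, alpha1, dg)
    exp(Zl[lidx] + (alpha1 + dg[lidx]) * is_q)

  init <- function(dat, priors) {
    mc <- tapply(Fv[!is_q], lidx[!is_q], mean)
    mq <- tapply(Fq, lq, mean)
    Zl <- numeric(L) + log(max(mean(Fv[!is_q]), 0.05))
    Zl[as.integer(names(mc))] <- log(pmax(mc, 0.05))
    a1 <- log(max(mean(Fq), 0.02) / max(mean(Fv[!is_q]), 0.02))
    lnu <- numeric(2 * L) + 0
    vg <- tapply(Fv, g, stats::var)
    vg[!is.finite(vg) | vg < 1e-8] <- stats::var(Fv)
    lnu[as.integer(names(vg))] <- -log(vg)
    list(Zl = Zl, delta = integer(L), gam = numeric(L),
         lnu = lnu, alpha1 = a1,
         lZp = log(max(mean(exp(Zl)), 0.05)),
         lsZ = log(1 / max(stats::var(exp(Zl)), 1e-3)),
         nup = mean(lnu), lsnu = log(1 / max(stats::var(lnu), 0.05)),
         lsg = pr$eta_gamma)
  }

  logpost <- function(s) ihm_log_posterior_state(s, dat, pr)

  tuning0 <- function(s) list(
    Zl = rep(0.05, L), gam = rep(0.2, L), lnu = rep(0.4, 2 * L),
    alpha1 = 0.05, lZp = 0.1, lsZ = 0.5, lsnu = 0.5, lsg = 0.5)

  sweep <- function(s, tun) {
    acc <- list()
    eZ <- exp(s$Zl)

    st <- rw_metropolis_step(s$lZp, function(v)
      ldnorm_prec(v, pr$Z_mu, pr$eta_Z_p) +
        sum(ldt3_prec(eZ, exp(v), exp(s$lsZ))), tun$lZp)
    s$lZp <- st$value; acc$lZp <- st$accepted

    st <- rw_metropolis_step(s$lsZ, function(v)
      ldnorm_prec(v, pr$eta_Z, pr$psi_Z) +
        sum(ldt3_prec(eZ, exp(s$lZp), exp(v))), tun$lsZ)
    s$lsZ <- st$value; acc$lsZ <- st$accepted

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

    ## condition effect alpha_1 (query-likelihood Metropolis)
    nuq <- exp(s$lnu)[gq]
    dg <- s$delta * s$gam
    lik_a <- function(a) -0.5 * sum(nuq * (Fq - exp(a + s$Zl[lq] +
                                                      dg[lq]))^2)
    st <- rw_metropolis_step(s$alpha1, function(v)
      ldnorm_prec(v, pr$alpha_mu, pr$eta_alpha) + lik_a(v), tun$alpha1)
    s$alpha1 <- st$value; acc$alpha1 <- st$accepted

    ## gene level
    nu_o <- exp(s$lnu)[g]
    gene_ll <- function(Zl) {
      mu <- mu_obs(Zl, s$alpha1, dg)
      gsum(-0.5 * nu_o * (Fv - mu)^2, lidx, L)
    }
    lpZ <- function(v) lp_t3exp(v, exp(s$lZp), exp(s$lsZ)) + gene_ll(v)
    prop <- s$Zl + stats::rnorm(L, 0, tun$Zl)
    a <- log(stats::runif(L)) < lpZ(prop) - lpZ(s$Zl)
    s$Zl[a] <- prop[a]; acc$Zl <- a

    ## delta: exact Bernoulli full conditional over the query likelihood
    mu1 <- exp(s$alpha1 + s$Zl[lq] + s$gam[lq])
    mu0 <- exp(s$alpha1 + s$Zl[lq])
    dll <- gsum(-0.5 * nuq * ((Fq - mu1)^2 - (Fq - mu0)^2), lq, L)
    p1 <- stats::plogis(stats::qlogis(pr$p) + dll)
    s$delta <- stats::rbinom(L, 1, p1)

    ## gamma: Metropolis when active, prior refresh when idle
    sg <- exp(s$lsg)
    lik_g <- function(v) {
      mu <- exp(s$alpha1 + s$Zl[lq] + v[lq])
      gsum(-0.5 * nuq * (Fq - mu)^2, lq, L)
    }
    lpG <- function(v) lp_t3exp(v, 1, sg) + s$delta * lik_g(v)
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

    ## per-condition-per-gene precisions
    dg <- s$delta * s$gam
    mu <- mu_obs(s$Zl, s$alpha1, dg)
    RSS_g <- gsum((Fv - mu)^2, g, 2 * L)
    lpnu <- function(v) ldnorm_prec(v, s$nup, exp(s$lsnu)) +
      0.5 * n_g * v - 0.5 * exp(v) * RSS_g
    prop <- s$lnu + stats::rnorm(2 * L, 0, tun$lnu)
    a <- log(stats::runif(2 * L)) < lpnu(prop) - lpnu(s$lnu)
    s$lnu[a] <- prop[a]; acc$lnu <- a

    list(state = s, accepted = acc)
  }

  monitor <- function(s) {
    orfs <- dat$orfs
    c(stats::setNames(as.numeric(s$delta), paste0("delta_", orfs)),
      stats::setNames(s$gam, paste0("gamma_", orfs)),
      stats::setNames(s$delta * s$gam, paste0("dg_", orfs)),
      stats::setNames(exp(s$Zl), paste0("eZ_", orfs)),
      alpha1 = s$alpha1, Z_p = exp(s$lZp), sigma_Z = exp(s$lsZ),
      nu_p = s$nup, sigma_nu = exp(s$lsnu), sigma_gamma = exp(s$lsg))
  }

  blame <- function(s) "initial IHM state"

  list(init = init, sweep = sweep, monitor = monitor, logpost = logpost,
       tuning0 = tuning0, blame = blame)
}

#' Unnormalised IHM log posterior
#'
#' Full joint density of the interaction model at a given state; used in
#' tests against independently assembled term sums. Genes present in only
#' one condition contribute prior-only terms for the missing condition.
#'
#' @param state named list (see source of \code{ihm_model}).
#' @param fitness fitness table as for \code{\link{fit_ihm}}.
#' @param priors \code{\link{qfa_priors}} for \code{"ihm"}.
#' @return Scalar unnormalised log posterior.
#' @export
ihm_log_posterior <- function(state, fitness, priors) {
  if (!"fitness" %in% names(fitness) && "DRDP" %in% names(fitness))
    fitness$fitness <- fitness$DRDP
  ihm_log_posterior_state(state, ihm_data(fitness), priors)
}

ihm_log_posterior_state <- function(s, dat, pr) {
  if (any(exp(s$gam) < 0) || any(!is.finite(s$Zl))) return(-Inf)
  dg <- s$delta * s$gam
  mu <- exp(s$Zl[dat$l] + (s$alpha1 + dg[dat$l]) * dat$is_q)
  nu_o <- exp(s$lnu)[dat$g]
  obs <- sum(0.5 * (s$lnu[dat$g] - log(2 * pi)) - 0.5 * nu_o * (dat$F - mu)^2)
  obs +
    sum(lp_t3exp(s$Zl, exp(s$lZp), exp(s$lsZ))) +
    sum(lp_t3exp(s$gam, 1, exp(s$lsg))) +
    sum(ifelse(s$delta == 1L, log(pr$p), log(1 - pr$p))) +
    sum(ldnorm_prec(s$lnu, s$nup, exp(s$lsnu))) +
    ldnorm_prec(s$alpha1, pr$alpha_mu, pr$eta_alpha) +
    ldnorm_prec(s$lZp, pr$Z_mu, pr$eta_Z_p) +
    ldnorm_prec(s$lsZ, pr$eta_Z, pr$psi_Z) +
    ldnorm_prec(s$nup, pr$nu_mu, pr$eta_nu_p) +
    ldnorm_prec(s$lsnu, pr$eta_nu, pr$psi_nu) +
    ldnorm_prec(s$lsg, pr$eta_gamma, pr$psi_gamma)
}

#' Exact Bernoulli full-conditional for one interaction indicator
#'
#' The posterior odds of \eqn{\delta_l = 1} given everything else are the
#' prior odds \eqn{p/(1-p)} times the likelihood ratio of that gene's query
#' observations under \eqn{\gamma_{1l}} switched on versus off. Exposed for
#' testing; the samplers use the same computation vectorised.
#'
#' @param p prior interaction probability.
#' @param loglik_ratio log likelihood ratio (interaction vs none).
#' @return Probability that \eqn{\delta_l = 1}.
#' @export
delta_posterior_prob <- function(p, loglik_ratio) {
  stopifnot(p >= 0, p <= 1)
  stats::plogis(stats::qlogis(p) + loglik_ratio)
}

#' Classify and rank interaction calls
#'
#' Builds the ranked list of interaction calls from a fitted interaction or
#' joint model: the evidence is \eqn{\hat\delta_l} (posterior mean of the
#' indicator), the strength the posterior mean of
#' \eqn{\delta_l\gamma_{1l}}, and the call is significant iff
#' \eqn{\hat\delta_l > 0.5} (strictly). For a query that decreases fitness
#' (the usual case), genes above the genetic-independence line (positive
#' strength) suppress the query's fitness defect and genes below it enhance
#' it; the convention flips for a beneficial query.
#'
#' @param fit a \code{qfa_ihm} or \code{qfa_jhm} object.
#' @param query_effect \code{"deleterious"} (default) or
#'   \code{"beneficial"}.
#' @return Data frame sorted by decreasing |strength|: \code{orf},
#'   \code{delta_hat}, \code{strength}, \code{direction}, \code{label},
#'   \code{significant}, \code{rank} (1..n, no gaps).
#' @export
classify_and_rank <- function(fit, query_effect = c("deleterious",
                                                    "beneficial")) {
  query_effect <- match.arg(query_effect)
  stopifnot(inherits(fit, c("qfa_ihm", "qfa_jhm")))
  if (inherits(fit, "qfa_jhm"))
    return(jhm_fitness_and_calls(fit, query_effect = query_effect)$calls)
  d <- fit$draws$draws
  orfs <- fit$orfs
  delta_hat <- colMeans(d[, paste0("delta_", orfs), drop = FALSE])
  strength <- colMeans(d[, paste0("dg_", orfs), drop = FALSE])
  pos <- if (query_effect == "deleterious") "suppressor" else "enhancer"
  neg <- if (query_effect == "deleterious") "enhancer" else "suppressor"
  direction <- ifelse(strength > 0, pos, ifelse(strength < 0, neg, "none"))
  significant <- delta_hat > 0.5
  label <- ifelse(significant, direction, "none")
  out <- data.frame(orf = orfs, delta_hat = as.numeric(delta_hat),
                    strength = as.numeric(strength), direction = direction,
                    label = label, significant = significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$strength)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
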