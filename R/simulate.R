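#' Simulate a QFA screen from the growth-model generative process
#'
#' Ancestral sampling down the separate hierarchical model: gene-level
#' locations are drawn from truncated scaled-t population distributions
#' (rejection sampling honours the truncations, capped at 1e4 tries),
#' repeat-level log parameters from their normal layers, and observations
#' as Gaussian noise about the logistic solution, truncated to the valid
#' density scale [0, 1].
#'
#' Default design and truth mirror a realistically scaled-down screen:
#' carrying capacities near 0.13 (13\% of the maximum observable density),
#' growth rates near 2.6 per day, inoculum \code{P = exp(-9.04)} (the prior
#' median), 5\% biological scatter between replicates and measurement noise
#' with precision \code{exp(19.82)} (the prior mean), i.e. tiny relative to
#' the plateau but comparable to the inoculum, as in plate photography.
#'
#' @param L number of gene deletions; \code{M} replicates per gene;
#'   \code{N} time points per culture.
#' @param t_max last sampling time, days (grid is uniform from 0).
#' @param condition screen label written to the output (0 or 1).
#' @param truth named list overriding any of the generative values:
#'   \code{P}, \code{Kp}, \code{sigma_K_o}, \code{rp}, \code{sigma_r_o}
#'   (t3 location and precision of the gene level), \code{tau_K_p},
#'   \code{sigma_tau_K}, \code{tau_r_p}, \code{sigma_tau_r} (log-precision
#'   layers), \code{nu_p}, \code{sigma_nu} (noise layer), or directly the
#'   gene-level vectors \code{Klo}, \code{rlo} (log scale).
#' @param seed RNG seed.
#' @return List with \code{tc} (time-course data frame, schema of
#'   \code{\link{read_timecourses}}) and \code{truth} (all generative
#'   values incl. per-culture \code{K_lm}, \code{r_lm}).
#' @export
simulate_shm <- function(L = 50, M = 8, N = 12, t_max = 4, condition = 0,
                         truth = list(), seed = 1) {
  set.seed(seed)
  tr <- utils::modifyList(list(
    P = exp(-9.04),
    Kp = exp(-2.01), sigma_K_o = 1 / 0.02^2,
    rp = exp(0.97),  sigma_r_o = 1 / 0.3^2,
    tau_K_p = 6, sigma_tau_K = 25,
    tau_r_p = 6, sigma_tau_r = 25,
    nu_p = 19.82, sigma_nu = 4), truth)

  if (is.null(tr$Klo))
    tr$Klo <- log(vapply(seq_len(L), function(i)
      rkernel(qfa_kernel("scaled_t3", tr$Kp, tr$sigma_K_o, lower = 1e-8)),
      numeric(1)))
  if (is.null(tr$rlo))
    tr$rlo <- log(vapply(seq_len(L), function(i)
      rkernel(qfa_kernel("scaled_t3", tr$rp, tr$sigma_r_o, lower = 1e-8)),
      numeric(1)))
  stopifnot(length(tr$Klo) == L, length(tr$rlo) == L)

  if (is.null(tr$tau_K_l))
    tr$tau_K_l <- exp(rtnorm(L, tr$tau_K_p, 1 / sqrt(tr$sigma_tau_K),
                             lower = 0))
  if (is.null(tr$tau_r_l))
    tr$tau_r_l <- exp(stats::rnorm(L, tr$tau_r_p, 1 / sqrt(tr$sigma_tau_r)))
  if (is.null(tr$nu_l))
    tr$nu_l <- exp(stats::rnorm(L, tr$nu_p, 1 / sqrt(tr$sigma_nu)))

  orfs <- sprintf("orf%03d", seq_len(L))
  tt <- seq(0, t_max, length.out = N)
  lK <- matrix(NA_real_, L, M); lr <- matrix(NA_real_, L, M)
  rows <- vector("list", L * M)
  k <- 0
  for (l in seq_len(L)) for (m in seq_len(M)) {
    lK[l, m] <- rtnorm(1, tr$Klo[l], 1 / sqrt(tr$tau_K_l[l]), upper = 0)
    lr[l, m] <- rtnorm(1, tr$rlo[l], 1 / sqrt(tr$tau_r_l[l]), upper = 3.5)
    x <- logistic_solution(tt, exp(lK[l, m]), exp(lr[l, m]), tr$P)
    y <- if (is.finite(tr$nu_l[l]))
      rtnorm(N, x, 1 / sqrt(tr$nu_l[l]), lower = 0, upper = 1) else x
    k <- k + 1
    rows[[k]] <- data.frame(orf = orfs[l], condition = condition,
                            `repeat` = m, time_days = tt, density = y,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  tr$K_lm <- lK; tr$r_lm <- lr
  tr$design <- list(L = L, M = M, N = N, t_max = t_max, seed = seed)
  tr$orfs <- orfs
  list(tc = do.call(rbind, rows), truth = tr)
}

#' Simulate per-culture fitness screens from the interaction model
#'
#' Generative twin of the fitness-level interaction model: gene fitness
#' locations \eqn{\exp(Z_l)} are scaled-t about a population location,
#' interaction indicators \eqn{\delta_l} are Bernoulli(\code{p}) unless a
#' fixed set of interactors is designated, interaction strengths
#' \eqn{\exp(\gamma_{1l})} are scaled-t about 1 (truncated at 0), and
#' replicate fitnesses are normal about
#' \eqn{\exp(\alpha_c + Z_l + \delta_l\gamma_{cl})}.
#'
#' @param L genes; \code{M} replicates per gene and condition.
#' @param p prior/realised interaction probability (ignored when
#'   \code{interactors} is given).
#' @param interactors optional integer indices of the genes that interact.
#' @param gamma optional vector (length \code{L} or one per interactor) of
#'   log interaction strengths; by default drawn from the scaled-t layer.
#' @param alpha1 condition effect (log scale); negative for a deleterious
#'   query.
#' @param truth named list overriding \code{Zp, sigma_Z, nu_p, sigma_nu,
#'   sigma_gamma}.
#' @param seed RNG seed.
#' @return List with \code{fitness} (data frame \code{orf}, \code{condition},
#'   \code{repeat}, \code{fitness}) and \code{truth}.
#' @export
simulate_ihm <- function(L = 100, M = 8, p = 0.05, interactors = NULL,
                         gamma = NULL, alpha1 = -0.7, truth = list(),
                         seed = 1) {
  stopifnot(p >= 0, p <= 1)
  set.seed(seed)
  tr <- utils::modifyList(list(
    Zp = exp(3.66), sigma_Z = 1 / 8^2,
    nu_p = -2.2, sigma_nu = 4,
    sigma_gamma = 1 / 0.45^2), truth)
  tr$alpha1 <- alpha1

  tr$Zl <- log(vapply(seq_len(L), function(i)
    rkernel(qfa_kernel("scaled_t3", tr$Zp, tr$sigma_Z, lower = 1e-8)),
    numeric(1)))
  if (is.null(interactors)) {
    tr$delta <- stats::rbinom(L, 1, p)
  } else {
    tr$delta <- integer(L); tr$delta[interactors] <- 1L
  }
  if (is.null(gamma)) {
    tr$gamma <- log(vapply(seq_len(L), function(i)
      rkernel(qfa_kernel("scaled_t3", 1, tr$sigma_gamma, lower = 1e-8)),
      numeric(1)))
  } else {
    tr$gamma <- numeric(L)
    if (length(gamma) == L) tr$gamma <- gamma
    else tr$gamma[which(tr$delta == 1L)] <- gamma
  }
  tr$nu_cl <- matrix(exp(stats::rnorm(2 * L, tr$nu_p, 1 / sqrt(tr$sigma_nu))),
                     2, L)

  orfs <- sprintf("orf%03d", seq_len(L))
  out <- expand.grid(`repeat` = seq_len(M), orf = seq_len(L),
                     condition = 0:1, stringsAsFactors = FALSE)
  mu <- ifelse(out$condition == 0, exp(tr$Zl[out$orf]),
               exp(tr$alpha1 + tr$Zl[out$orf] +
                     tr$delta[out$orf] * tr$gamma[out$orf]))
  sd <- 1 / sqrt(tr$nu_cl[cbind(out$condition + 1, out$orf)])
  f <- stats::rnorm(nrow(out), mu, sd)
  fitness <- data.frame(orf = orfs[out$orf], condition = out$condition,
                        `repeat` = out[["repeat"]], fitness = f,
                        check.names = FALSE, stringsAsFactors = FALSE)
  tr$design <- list(L = L, M = M, seed = seed)
  tr$orfs <- orfs
  list(fitness = fitness, truth = tr)
}

#' Simulate a two-condition screen from the joint model
#'
#' Generative twin of the joint hierarchical model: one growth-model
#' hierarchy per condition sharing gene-level locations and \code{P}, with
#' the query condition shifted by \eqn{\alpha_1} (carrying capacity channel)
#' and \eqn{\beta_1} (growth-rate channel), and designated interactors
#' additionally shifted by \eqn{\gamma_{1l}} and/or \eqn{\omega_{1l}}.
#'
#' @param L,M,N,t_max design (per condition), as in
#'   \code{\link{simulate_shm}}.
#' @param p interaction probability when \code{interactors} is not given.
#' @param interactors integer indices of interacting genes.
#' @param channel character vector, one per interactor: \code{"K"},
#'   \code{"r"} or \code{"both"}.
#' @param gamma,omega log-scale effects per interactor (recycled).
#' @param alpha1,beta1 condition effects on log K and log r.
#' @param truth overrides as in \code{\link{simulate_shm}}.
#' @param seed RNG seed.
#' @return List with \code{tc} (both conditions) and \code{truth}
#'   (including per-gene \code{delta}, \code{gamma}, \code{omega},
#'   \code{channel}).
#' @export
simulate_jhm <- function(L = 50, M = 4, N = 10, t_max = 4, p = 0.05,
                         interactors = NULL, channel = "both",
                         gamma = -0.5, omega = -0.5,
                         alpha1 = -0.1, beta1 = -0.3,
                         truth = list(), seed = 1) {
  set.seed(seed)
  tr <- utils::modifyList(list(
    P = exp(-9.04),
    Kp = exp(-2.01), sigma_K_o = 1 / 0.02^2,
    rp = exp(0.97),  sigma_r_o = 1 / 0.3^2,
    tau_K_p = 6, sigma_tau_K = 25,
    tau_r_p = 6, sigma_tau_r = 25,
    nu_p = 19.82, sigma_nu = 4), truth)
  tr$alpha1 <- alpha1; tr$beta1 <- beta1

  if (is.null(interactors)) interactors <- which(stats::rbinom(L, 1, p) == 1)
  nI <- length(interactors)
  channel <- rep(channel, length.out = nI)
  gamma <- rep(gamma, length.out = nI)
  omega <- rep(omega, length.out = nI)
  tr$delta <- integer(L); tr$delta[interactors] <- 1L
  tr$gamma <- numeric(L); tr$omega <- numeric(L)
  tr$channel <- rep("none", L)
  if (nI) {
    tr$channel[interactors] <- channel
    tr$gamma[interactors] <- ifelse(channel %in% c("K", "both"), gamma, 0)
    tr$omega[interactors] <- ifelse(channel %in% c("r", "both"), omega, 0)
  }

  if (is.null(tr$Klo))
    tr$Klo <- log(vapply(seq_len(L), function(i)
      rkernel(qfa_kernel("scaled_t3", tr$Kp, tr$sigma_K_o, lower = 1e-8)),
      numeric(1)))
  if (is.null(tr$rlo))
    tr$rlo <- log(vapply(seq_len(L), function(i)
      rkernel(qfa_kernel("scaled_t3", tr$rp, tr$sigma_r_o, lower = 1e-8)),
      numeric(1)))
  if (is.null(tr$tau_K_cl))
    tr$tau_K_cl <- matrix(exp(rtnorm(2 * L, tr$tau_K_p,
                                     1 / sqrt(tr$sigma_tau_K), lower = 0)),
                          2, L)
  if (is.null(tr$tau_r_cl))
    tr$tau_r_cl <- matrix(exp(stats::rnorm(2 * L, tr$tau_r_p,
                                           1 / sqrt(tr$sigma_tau_r))), 2, L)
  if (is.null(tr$nu_cl))
    tr$nu_cl <- matrix(exp(stats::rnorm(2 * L, tr$nu_p,
                                        1 / sqrt(tr$sigma_nu))), 2, L)

  orfs <- sprintf("orf%03d", seq_len(L))
  tt <- seq(0, t_max, length.out = N)
  rows <- vector("list", 2 * L * M)
  k <- 0
  for (cc in 0:1) for (l in seq_len(L)) {
    mK <- tr$Klo[l] + if (cc == 1) tr$alpha1 + tr$delta[l] * tr$gamma[l] else 0
    mr <- tr$rlo[l] + if (cc == 1) tr$beta1 + tr$delta[l] * tr$omega[l] else 0
    for (m in seq_len(M)) {
      lK <- rtnorm(1, mK, 1 / sqrt(tr$tau_K_cl[cc + 1, l]), upper = 0)
      lr <- rtnorm(1, mr, 1 / sqrt(tr$tau_r_cl[cc + 1, l]), upper = 3.5)
      x <- logistic_solution(tt, exp(lK), exp(lr), tr$P)
      y <- if (is.finite(tr$nu_cl[cc + 1, l]))
        rtnorm(N, x, 1 / sqrt(tr$nu_cl[cc + 1, l]), lower = 0, upper = 1)
      else x
      k <- k + 1
      rows[[k]] <- data.frame(orf = orfs[l], condition = cc, `repeat` = m,
                              time_days = tt, density = y,
                              check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  tr$design <- list(L = L, M = M, N = N, t_max = t_max, seed = seed)
  tr$orfs <- orfs
  list(tc = do.call(rbind, rows), truth = tr)
}

## truncated normal draws by inverse-CDF (exact, vectorised)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd <= 0)) stop("rtnorm: sd must be positive")
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (any(phi - plo < 1e-12))
    stop("rtnorm: negligible mass inside the truncation interval")
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}
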