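test_that("JHM log posterior matches an independently assembled term sum", {
  tc <- data.frame(orf = rep("a", 4), condition = c(0L, 0L, 1L, 1L),
                   `repeat` = c(1L, 1L, 1L, 1L),
                   time_days = c(1, 2, 1, 2),
                   density = c(0.05, 0.11, 0.04, 0.08),
                   check.names = FALSE)
  pr <- qfa_priors("jhm")
  s <- list(lK = c(-2.0, -2.3), lr = c(0.9, 0.8),
            Klo = -2.1, rlo = 0.95, delta = 1L, gam = -0.25, om = -0.1,
            alpha1 = -0.1, beta1 = -0.2,
            ltK = c(5, 5.1), ltr = c(5.5, 5.6), lnu = c(8, 8.2),
            lP = -9.0, lKp = -2.05, lrp = 0.92, lsKo = 3, lsro = 2,
            nup = 8.5, lsnu = 1,
            tKp_c = c(5.2, 5.3), lstK_c = c(2, 2.1),
            trp_c = c(5.4, 5.5), lstr_c = c(2.2, 2.3),
            lsg = 0.2, lso = 0.3)

  ld_t3e <- function(x, loc, prec)
    kernel_logpdf(qfa_kernel("scaled_t3", loc, prec, lower = 0), exp(x)) + x
  mK <- c(s$Klo, s$alpha1 + s$Klo + s$gam)           # control, query
  mr <- c(s$rlo, s$beta1 + s$rlo + s$om)
  yh0 <- logistic_solution(c(1, 2), exp(s$lK[1]), exp(s$lr[1]), exp(s$lP))
  yh1 <- logistic_solution(c(1, 2), exp(s$lK[2]), exp(s$lr[2]), exp(s$lP))
  expected <-
    sum(dnorm(c(0.05, 0.11), yh0, exp(-s$lnu[1] / 2), log = TRUE)) +
    sum(dnorm(c(0.04, 0.08), yh1, exp(-s$lnu[2] / 2), log = TRUE)) +
    sum(dnorm(s$lK, mK, exp(-s$ltK / 2), log = TRUE)) +
    sum(dnorm(s$lr, mr, exp(-s$ltr / 2), log = TRUE)) +
    sum(dnorm(s$ltK, s$tKp_c, exp(-s$lstK_c / 2), log = TRUE)) +
    sum(dnorm(s$ltr, s$trp_c, exp(-s$lstr_c / 2), log = TRUE)) +
    sum(dnorm(s$lnu, s$nup, exp(-s$lsnu / 2), log = TRUE)) +
    ld_t3e(s$Klo, exp(s$lKp), exp(s$lsKo)) +
    ld_t3e(s$rlo, exp(s$lrp), exp(s$lsro)) +
    ld_t3e(s$gam, 1, exp(s$lsg)) +
    ld_t3e(s$om, 1, exp(s$lso)) +
    log(pr$p) +
    dnorm(s$alpha1, pr$alpha_mu, 1 / sqrt(pr$eta_alpha), log = TRUE) +
    dnorm(s$beta1, pr$beta_mu, 1 / sqrt(pr$eta_beta), log = TRUE) +
    sum(dnorm(s$tKp_c, pr$tau_K_mu, 1 / sqrt(pr$eta_tau_K_p), log = TRUE)) +
    sum(dnorm(s$trp_c, pr$tau_r_mu, 1 / sqrt(pr$eta_tau_r_p), log = TRUE)) +
    sum(dnorm(s$lstK_c, pr$eta_tau_K, 1 / sqrt(pr$psi_tau_K), log = TRUE)) +
    sum(dnorm(s$lstr_c, pr$eta_tau_r, 1 / sqrt(pr$psi_tau_r), log = TRUE)) +
    dnorm(s$lKp, pr$K_mu, 1 / sqrt(pr$eta_K_p), log = TRUE) +
    dnorm(s$lrp, pr$r_mu, 1 / sqrt(pr$eta_r_p), log = TRUE) +
    dnorm(s$lP, pr$P_mu, 1 / sqrt(pr$eta_P), log = TRUE) +
    dnorm(s$nup, pr$nu_mu, 1 / sqrt(pr$eta_nu_p), log = TRUE) +
    dnorm(s$lsKo, pr$eta_K_o, 1 / sqrt(pr$psi_K_o), log = TRUE) +
    dnorm(s$lsro, pr$eta_r_o, 1 / sqrt(pr$psi_r_o), log = TRUE) +
    dnorm(s$lsnu, pr$eta_nu, 1 / sqrt(pr$psi_nu), log = TRUE) +
    dnorm(s$lsg, pr$eta_gamma, 1 / sqrt(pr$psi_gamma), log = TRUE) +
    dnorm(s$lso, pr$eta_omega, 1 / sqrt(pr$psi_omega), log = TRUE)

  expect_equal(jhm_log_posterior(s, tc, pr), expected, tolerance = 1e-10)

  # any truncation violation gives -Inf
  for (fld in c("lK", "lr", "ltK")) {
    s_bad <- s
    s_bad[[fld]][1] <- if (fld == "lr") 3.6 else if (fld == "lK") 0.1 else -0.1
    expect_identical(jhm_log_posterior(s_bad, tc, pr), -Inf)
  }
})

test_that("JHM calls K-only and r-only interactors with few false positives", {
  sim <- simulate_jhm(L = 12, M = 4, N = 10, interactors = 1:2,
                      channel = c("K", "r"), gamma = -0.5, omega = -0.5,
                      seed = 41)
  fit <- fit_jhm(sim$tc, config = chain_config(burnin = 1500, samples = 500,
                                               thin = 2, seed = 1))
  calls <- fit$calls
  dh <- calls$delta_hat[match(sim$truth$orfs, calls$orf)]
  expect_gt(dh[1], 0.5)   # K-only interactor found
  expect_gt(dh[2], 0.5)   # r-only interactor found
  expect_lte(mean(dh[3:12] > 0.5), 0.1)
  # per-channel strengths carry the simulated signs
  sk <- calls$strength_K[match(sim$truth$orfs[1], calls$orf)]
  sr <- calls$strength_r[match(sim$truth$orfs[2], calls$orf)]
  expect_lt(sk, 0)
  expect_lt(sr, 0)

  # expected-no-interaction curves: non-interactor coincides with fit
  cv <- expected_curve_no_interaction(fit, sim$truth$orfs[5])
  expect_equal(cv$fitted, cv$expected, tolerance = 0.05)
  # K-only interactor: plateau differs, t = 0 both at the inoculum
  ck <- expected_curve_no_interaction(fit, sim$truth$orfs[1],
                                      t = c(0, seq(0.5, 6, by = 0.5)))
  expect_equal(ck$fitted[1], ck$expected[1], tolerance = 1e-6)
  expect_lt(max(ck$fitted) / max(ck$expected), 0.75)

  # condition effects recovered within posterior uncertainty
  d <- fit$draws$draws
  expect_lt(abs(mean(d[, "alpha1"]) - sim$truth$alpha1),
            4 * sd(d[, "alpha1"]) + 0.02)
  expect_lt(abs(mean(d[, "beta1"]) - sim$truth$beta1),
            4 * sd(d[, "beta1"]) + 0.02)
})

test_that("JHM fitness plug-ins follow the posterior-mean forms", {
  sim <- simulate_jhm(L = 4, M = 2, N = 8, interactors = 1, channel = "K",
                      gamma = -0.5, seed = 42)
  fit <- fit_jhm(sim$tc, config = quick_config(samples = 100))
  out <- jhm_fitness_and_calls(fit)
  d <- fit$draws$draws
  o <- fit$orfs[1]
  expect_equal(out$fitness$K_query[1],
               mean(exp(d[, "alpha1"]) * d[, paste0("eKo_", o)] *
                      exp(d[, paste0("dg_", o)])))
  # DP-channel fitness is independent of growth-rate interaction draws
  fit2 <- fit
  wcols <- grep("^dw_", colnames(fit2$draws$draws))
  fit2$draws$draws[, wcols] <- 0
  expect_equal(jhm_fitness_and_calls(fit, measure = "DP")$fitness$F_query,
               jhm_fitness_and_calls(fit2, measure = "DP")$fitness$F_query)
})

test_that("with query identical to control the condition effects vanish", {
  sim <- simulate_jhm(L = 8, M = 3, N = 8, interactors = integer(0),
                      alpha1 = 0, beta1 = 0, seed = 43)
  fit <- fit_jhm(sim$tc, config = quick_config(burnin = 800, samples = 300))
  d <- fit$draws$draws
  expect_lt(abs(mean(d[, "alpha1"])), 3 * sd(d[, "alpha1"]) + 0.02)
  expect_lt(abs(mean(d[, "beta1"])), 3 * sd(d[, "beta1"]) + 0.02)
  # at L = 8 allow at most one spurious call (binomial slack on 2p)
  expect_lte(sum(fit$calls$delta_hat > 0.5), 1)
})

test_that("interaction calls are stable across MCMC seeds", {
  sim <- simulate_jhm(L = 6, M = 3, N = 8, interactors = 1, channel = "both",
                      gamma = -0.5, omega = -0.5, seed = 44)
  f1 <- fit_jhm(sim$tc, config = quick_config(burnin = 800, samples = 300,
                                              seed = 1))
  f2 <- fit_jhm(sim$tc, config = quick_config(burnin = 800, samples = 300,
                                              seed = 99))
  d1 <- f1$calls$delta_hat[match(sim$truth$orfs, f1$calls$orf)]
  d2 <- f2$calls$delta_hat[match(sim$truth$orfs, f2$calls$orf)]
  expect_true(all(abs(d1 - d2) < 0.1))
})

test_that("all SHM truncations hold per condition in retained JHM draws", {
  sim <- simulate_jhm(L = 4, M = 2, N = 8, seed = 45)
  fit <- fit_jhm(sim$tc, config = quick_config(samples = 80))
  d <- fit$draws$draws
  expect_true(all(d[, grep("^K_", colnames(d))] <= 1))
  expect_true(all(d[, grep("^r_orf", colnames(d))] <= exp(3.5)))
  expect_true(all(d[, grep("^tauK_", colnames(d))] >= 1))
})
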