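test_that("IHM log posterior matches an independently assembled term sum", {
  fitness <- data.frame(orf = c("a", "a"), condition = c(0L, 1L),
                        `repeat` = c(1L, 1L), fitness = c(30, 14),
                        check.names = FALSE)
  pr <- qfa_priors("ihm")
  s <- list(Zl = log(31), delta = 1L, gam = -0.3, lnu = c(-2, -2.2),
            alpha1 = -0.6, lZp = 3.5, lsZ = -4, nup = -2.1, lsnu = 1,
            lsg = 0.2)
  mu0 <- exp(s$Zl); mu1 <- exp(s$alpha1 + s$Zl + s$gam)
  expected <-
    dnorm(30, mu0, exp(-s$lnu[1] / 2), log = TRUE) +
    dnorm(14, mu1, exp(-s$lnu[2] / 2), log = TRUE) +
    kernel_logpdf(qfa_kernel("scaled_t3", exp(s$lZp), exp(s$lsZ),
                             lower = 0), exp(s$Zl)) + s$Zl +
    kernel_logpdf(qfa_kernel("scaled_t3", 1, exp(s$lsg), lower = 0),
                  exp(s$gam)) + s$gam +
    log(pr$p) +
    sum(dnorm(s$lnu, s$nup, exp(-s$lsnu / 2), log = TRUE)) +
    dnorm(s$alpha1, pr$alpha_mu, 1 / sqrt(pr$eta_alpha), log = TRUE) +
    dnorm(s$lZp, pr$Z_mu, 1 / sqrt(pr$eta_Z_p), log = TRUE) +
    dnorm(s$lsZ, pr$eta_Z, 1 / sqrt(pr$psi_Z), log = TRUE) +
    dnorm(s$nup, pr$nu_mu, 1 / sqrt(pr$eta_nu_p), log = TRUE) +
    dnorm(s$lsnu, pr$eta_nu, 1 / sqrt(pr$psi_nu), log = TRUE) +
    dnorm(s$lsg, pr$eta_gamma, 1 / sqrt(pr$psi_gamma), log = TRUE)
  expect_equal(ihm_log_posterior(s, fitness, pr), expected,
               tolerance = 1e-10)

  # with delta = 0 the indicator term flips and gamma drops from the mean
  s0 <- s; s0$delta <- 0L
  expected0 <- expected - log(pr$p) + log(1 - pr$p) -
    dnorm(14, mu1, exp(-s$lnu[2] / 2), log = TRUE) +
    dnorm(14, exp(s$alpha1 + s$Zl), exp(-s$lnu[2] / 2), log = TRUE)
  expect_equal(ihm_log_posterior(s0, fitness, pr), expected0,
               tolerance = 1e-10)
})

test_that("the indicator full conditional follows the odds arithmetic", {
  expect_equal(delta_posterior_prob(0.05, 0), 0.05)      # prior recovery
  expect_equal(delta_posterior_prob(0.5, log(3)), 0.75)  # odds 1:1 times 3
  expect_equal(delta_posterior_prob(0, 5), 0)            # p = 0: never on
  expect_equal(delta_posterior_prob(1, -5), 1)
})

test_that("IHM detects designated interactors and controls false positives", {
  gam <- c(0.6, -0.6, 0.7, -0.7, 0.6)
  sim <- simulate_ihm(L = 40, M = 8, interactors = 1:5, gamma = gam,
                      seed = 31)
  fit <- fit_ihm(sim$fitness,
                 config = chain_config(burnin = 1500, samples = 500,
                                       thin = 2, seed = 1))
  dh <- fit$calls$delta_hat[match(sim$truth$orfs, fit$calls$orf)]
  expect_gte(mean(dh[1:5] > 0.5), 0.8)
  expect_lte(mean(dh[6:40] > 0.5), 0.1)
  # strengths carry the simulated signs
  st <- fit$calls$strength[match(sim$truth$orfs[1:5], fit$calls$orf)]
  called <- dh[1:5] > 0.5
  expect_true(all(sign(st[called]) == sign(gam[called])))
  # indicator means are probabilities
  expect_true(all(dh >= 0 & dh <= 1))
})

test_that("a proportional null screen yields no calls and recovers alpha1", {
  # query = exp(a) * control exactly (zero observation noise)
  a <- -0.5
  sim <- simulate_ihm(L = 30, M = 6, interactors = integer(0), alpha1 = a,
                      truth = list(nu_p = 8, sigma_nu = 1e4), seed = 32)
  fit <- fit_ihm(sim$fitness,
                 config = chain_config(burnin = 1500, samples = 500,
                                       seed = 2))
  expect_true(all(fit$calls$delta_hat < 0.5))
  d <- fit$draws$draws[, "alpha1"]
  expect_lt(abs(mean(d) - a), 3 * sd(d) + 1e-3)
})

test_that("relabelling gene ids permutes but does not change the calls", {
  sim <- simulate_ihm(L = 10, M = 5, interactors = 2, gamma = 0.8, seed = 33)
  f1 <- sim$fitness
  f2 <- f1
  map <- setNames(sprintf("gene%03d", 1:10), sprintf("orf%03d", 1:10))
  f2$orf <- unname(map[f1$orf])   # monotone relabelling
  fit1 <- fit_ihm(f1, config = quick_config(samples = 100))
  fit2 <- fit_ihm(f2, config = quick_config(samples = 100))
  expect_equal(fit1$calls$delta_hat, fit2$calls$delta_hat)
  expect_equal(unname(map[fit1$calls$orf]), fit2$calls$orf)
})

test_that("a gene with no query data reverts to the prior probability p", {
  sim <- simulate_ihm(L = 12, M = 6, interactors = integer(0), seed = 34)
  f <- sim$fitness
  f <- f[!(f$orf == "orf001" & f$condition == 1), ]   # drop its query arm
  fit <- fit_ihm(f, config = chain_config(burnin = 1000, samples = 2000,
                                          seed = 3))
  dh <- fit$calls$delta_hat[fit$calls$orf == "orf001"]
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(dh - 0.05), 5 * se)
})

test_that("classification follows the strict 0.5 rule and sign convention", {
  orfs <- c("g1", "g2", "g3")
  n <- 100
  delta <- cbind(c(rep(1, 62), rep(0, 38)),          # delta_hat = 0.62
                 rep(c(1, 0), each = 50),            # delta_hat = 0.50
                 c(rep(1, 90), rep(0, 10)))          # delta_hat = 0.90
  gamma <- cbind(rep(0.3 / 0.62, n), rep(0.2, n), rep(-0.4 / 0.9, n))
  fit <- fake_ihm_fit(delta, gamma, orfs)
  calls <- classify_and_rank(fit)
  g1 <- calls[calls$orf == "g1", ]
  expect_true(g1$significant)
  expect_equal(g1$label, "suppressor")
  expect_equal(g1$strength, 0.3, tolerance = 1e-12)
  g2 <- calls[calls$orf == "g2", ]
  expect_false(g2$significant)       # 0.5 exactly is not significant
  expect_equal(g2$label, "none")
  g3 <- calls[calls$orf == "g3", ]
  expect_true(g3$significant)
  expect_equal(g3$label, "enhancer")
  expect_equal(g3$strength, -0.4, tolerance = 1e-12)
  # beneficial-query convention flips the labels
  calls_b <- classify_and_rank(fit, query_effect = "beneficial")
  expect_equal(calls_b[calls_b$orf == "g1", "label"], "enhancer")
  # ranks are 1..n with no gaps, ordered by |strength|
  expect_equal(calls$rank, 1:3)
  expect_equal(calls$orf[1], "g3")
})

test_that("sensitivity increases with simulated effect size", {
  dhs <- sapply(c(0.15, 0.4, 0.8), function(g) {
    sim <- simulate_ihm(L = 20, M = 8, interactors = 1:4,
                        gamma = rep(-g, 4), seed = 35)
    fit <- fit_ihm(sim$fitness, config = quick_config(burnin = 800,
                                                      samples = 300))
    mean(fit$calls$delta_hat[match(sim$truth$orfs[1:4], fit$calls$orf)])
  })
  expect_true(all(diff(dhs) >= -0.02))   # non-decreasing (small MC slack)
})
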