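test_that("SHM log posterior matches an independently assembled term sum", {
  tc <- data.frame(orf = "a", condition = 0L, `repeat` = 1L,
                   time_days = c(1, 2), density = c(0.05, 0.11),
                   check.names = FALSE)
  pr <- qfa_priors("shm")
  s <- list(lK = -2.0, lr = 0.9, Klo = -2.1, rlo = 0.95,
            ltK = 5, ltr = 5.5, lnu = 8, lP = -9.0,
            lKp = -2.05, lrp = 0.92, lsKo = 3, lsro = 2,
            nup = 8.5, lsnu = 1, tKp = 5.2, lstK = 2, trp = 5.4, lstr = 2.1)

  yhat <- logistic_solution(tc$time_days, exp(s$lK), exp(s$lr), exp(s$lP))
  expected <-
    sum(dnorm(tc$density, yhat, exp(-s$lnu / 2), log = TRUE)) +
    dnorm(s$lK, s$Klo, exp(-s$ltK / 2), log = TRUE) +
    dnorm(s$lr, s$rlo, exp(-s$ltr / 2), log = TRUE) +
    dnorm(s$ltK, s$tKp, exp(-s$lstK / 2), log = TRUE) +
    dnorm(s$ltr, s$trp, exp(-s$lstr / 2), log = TRUE) +
    kernel_logpdf(qfa_kernel("scaled_t3", exp(s$lKp), exp(s$lsKo),
                             lower = 0), exp(s$Klo)) + s$Klo +
    kernel_logpdf(qfa_kernel("scaled_t3", exp(s$lrp), exp(s$lsro),
                             lower = 0), exp(s$rlo)) + s$rlo +
    dnorm(s$lnu, s$nup, exp(-s$lsnu / 2), log = TRUE) +
    dnorm(s$lKp, pr$K_mu, 1 / sqrt(pr$eta_K_p), log = TRUE) +
    dnorm(s$lrp, pr$r_mu, 1 / sqrt(pr$eta_r_p), log = TRUE) +
    dnorm(s$lP, pr$P_mu, 1 / sqrt(pr$eta_P), log = TRUE) +
    dnorm(s$nup, pr$nu_mu, 1 / sqrt(pr$eta_nu_p), log = TRUE) +
    dnorm(s$tKp, pr$tau_K_mu, 1 / sqrt(pr$eta_tau_K_p), log = TRUE) +
    dnorm(s$trp, pr$tau_r_mu, 1 / sqrt(pr$eta_tau_r_p), log = TRUE) +
    dnorm(s$lsKo, pr$eta_K_o, 1 / sqrt(pr$psi_K_o), log = TRUE) +
    dnorm(s$lsro, pr$eta_r_o, 1 / sqrt(pr$psi_r_o), log = TRUE) +
    dnorm(s$lsnu, pr$eta_nu, 1 / sqrt(pr$psi_nu), log = TRUE) +
    dnorm(s$lstK, pr$eta_tau_K, 1 / sqrt(pr$psi_tau_K), log = TRUE) +
    dnorm(s$lstr, pr$eta_tau_r, 1 / sqrt(pr$psi_tau_r), log = TRUE)

  expect_equal(shm_log_posterior(s, tc, pr), expected, tolerance = 1e-10)

  # truncation violations give -Inf
  s_bad <- s; s_bad$lK <- 0.2
  expect_identical(shm_log_posterior(s_bad, tc, pr), -Inf)
  s_bad <- s; s_bad$lr <- 3.6
  expect_identical(shm_log_posterior(s_bad, tc, pr), -Inf)
  s_bad <- s; s_bad$ltK <- -0.1
  expect_identical(shm_log_posterior(s_bad, tc, pr), -Inf)
})

test_that("SHM recovers gene-level parameters from zero-noise data", {
  sim <- simulate_shm(L = 2, M = 2, N = 5,
                      truth = list(nu_l = rep(Inf, 2), tau_K_p = 10,
                                   tau_r_p = 10),
                      seed = 21)
  fit <- fit_shm(sim$tc, config = chain_config(burnin = 800, samples = 300,
                                               thin = 1, seed = 1))
  cm <- coef(fit)
  eKo <- cm[paste0("eKo_", sim$truth$orfs)]
  ero <- cm[paste0("ero_", sim$truth$orfs)]
  expect_true(all(abs(eKo - exp(sim$truth$Klo)) / exp(sim$truth$Klo) < 0.02))
  expect_true(all(abs(ero - exp(sim$truth$rlo)) / exp(sim$truth$rlo) < 0.05))
})

test_that("retained SHM draws never violate the truncation supports", {
  sim <- simulate_shm(L = 3, M = 2, N = 8, seed = 22)
  fit <- fit_shm(sim$tc, config = quick_config(samples = 100))
  d <- fit$draws$draws
  expect_true(all(d[, grep("^K_", colnames(d))] <= 1))
  expect_true(all(d[, grep("^r_", colnames(d))] <= exp(3.5)))
  expect_true(all(d[, grep("^tauK_", colnames(d))] >= 1))
  expect_true(all(is.finite(d)))
})

test_that("a dead culture is handled without the chain sticking", {
  sim <- simulate_shm(L = 3, M = 3, N = 10, seed = 23)
  tc <- sim$tc
  # replace one gene's cultures with flat traces at the inoculum level
  set.seed(1)
  flat <- tc$orf == "orf001"
  tc$density[flat] <- pmax(1e-4 + rnorm(sum(flat), 0, 5e-5), 1e-6)
  fit <- fit_shm(tc, config = quick_config(burnin = 500, samples = 150))
  d <- fit$draws$draws
  # truncations respected for the dead gene
  expect_true(all(d[, grep("^r_orf001", colnames(d))] <= exp(3.5)))
  # its carrying capacity shrinks towards small values
  expect_lt(mean(d[, "K_orf001.1"]), 0.02)
  # repeat-level blocks keep moving
  expect_gt(fit$draws$accept["lK"], 0.05)
  expect_gt(fit$draws$accept["lr"], 0.05)
})

test_that("posterior spread contracts from population to repeat level", {
  sim <- simulate_shm(L = 4, M = 4, N = 10, seed = 24)
  fit <- fit_shm(sim$tc, config = quick_config(burnin = 600, samples = 300))
  d <- fit$draws$draws
  set.seed(2)
  # population-level predictive: new gene from the t3 layer
  pop <- d[, "K_p"] + (1 / sqrt(d[, "sigma_K_o"])) * rt(nrow(d), 3)
  # gene-level predictive: new repeat for gene 1
  gene <- exp(rnorm(nrow(d), log(d[, "eKo_orf001"]),
                    1 / sqrt(d[, "tauK_orf001"])))
  rep1 <- d[, "K_orf001.1"]
  expect_gt(sd(pop), sd(gene))
  expect_gte(sd(gene), sd(rep1) * 0.999)
})

test_that("doubling replicates contracts gene-level posterior SDs", {
  sds <- sapply(1:5, function(seed) {
    sapply(c(2, 4), function(M) {
      sim <- simulate_shm(L = 4, M = M, N = 8, seed = 100 + seed)
      fit <- fit_shm(sim$tc, config = quick_config(burnin = 400,
                                                   samples = 150,
                                                   seed = seed))
      mean(apply(fit$draws$draws[, paste0("eKo_", sim$truth$orfs)], 2, sd))
    })
  })
  # monotone in expectation: average over seeds decreases with M
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("fitness summaries are plug-ins of the posterior means", {
  sim <- simulate_shm(L = 2, M = 2, N = 8, seed = 25)
  fit <- fit_shm(sim$tc, config = quick_config(samples = 80))
  # point-mass draws: fitness equals the deterministic score
  fit1 <- fit
  fit1$draws$draws <- fit$draws$draws[rep(1, 60), ]
  ft <- summarize_fitness(fit1, "DRDP")
  d1 <- fit$draws$draws[1, ]
  for (i in seq_len(nrow(ft))) {
    cid <- paste0(ft$orf[i], ".", ft[["repeat"]][i])
    expect_equal(ft$fitness[i],
                 fitness_score(d1[paste0("K_", cid)], d1[paste0("r_", cid)],
                               d1["P"], "DRDP"),
                 ignore_attr = TRUE)
  }
  # DP is unaffected by the growth-rate draws
  fit2 <- fit
  rcols <- grep("^r_", colnames(fit2$draws$draws))
  fit2$draws$draws[, rcols] <- fit2$draws$draws[sample(nrow(fit2$draws$draws)),
                                                rcols]
  expect_equal(summarize_fitness(fit, "DP")$fitness,
               summarize_fitness(fit2, "DP")$fitness)
})
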