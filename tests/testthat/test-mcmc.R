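test_that("kernel log densities match reference forms", {
  expect_equal(kernel_logpdf(qfa_kernel("normal", 0, 1), 0),
               -0.5 * log(2 * pi))
  expect_equal(kernel_logpdf(qfa_kernel("normal", 2, 4), 1.3),
               dnorm(1.3, 2, 0.5, log = TRUE))
  expect_equal(kernel_logpdf(qfa_kernel("lognormal", -1, 9), 0.7),
               dlnorm(0.7, -1, 1 / 3, log = TRUE))
  # any kernel truncated to [0, Inf) is -Inf below 0
  for (fam in c("normal", "lognormal", "scaled_t3"))
    expect_identical(kernel_logpdf(qfa_kernel(fam, 1, 1, lower = 0), -1),
                     -Inf)
})

test_that("scaled t3 kernel matches a quadrature-normalised reference", {
  # unnormalised t3 kernel with location 1, precision 4 (scale 1/2)
  mu <- 1; s <- 0.5
  kern <- function(x) (1 + ((x - mu) / s)^2 / 3)^(-2)
  Z <- integrate(kern, -Inf, Inf, rel.tol = 1e-12)$value
  ref <- log(kern(1.5) / Z)
  expect_equal(kernel_logpdf(qfa_kernel("scaled_t3", 1, 4), 1.5), ref,
               tolerance = 1e-10)
})

test_that("random-walk Metropolis targets the correct distribution", {
  set.seed(1)
  lp <- function(x) dnorm(x, log = TRUE)
  x <- 0; xs <- numeric(50000)
  for (i in seq_along(xs)) {
    st <- rw_metropolis_step(x, lp, 2.4)
    x <- st$value; xs[i] <- x
  }
  ess <- mcmc_diagnostics(matrix(xs, dimnames = list(NULL, "x")))$ess
  se <- 1 / sqrt(ess)
  expect_lt(abs(mean(xs)), 3 * se)
  expect_lt(abs(var(xs) - 1), 0.05)
})

test_that("truncation support is handled by immediate rejection", {
  set.seed(2)
  lp <- function(x) dnorm(x, log = TRUE)
  x <- 0.5; xs <- numeric(5000)
  for (i in seq_along(xs)) {
    st <- rw_metropolis_step(x, lp, 1.5, lower = 0)
    x <- st$value; xs[i] <- x
  }
  expect_true(all(xs >= 0))           # empirical mass outside support is 0
  # a proposal outside the support never moves the chain
  st <- rw_metropolis_step(0.1, lp, 0, lower = 0.2)
  expect_false(st$accepted)
  expect_equal(st$value, 0.1)
  expect_error(rw_metropolis_step(-1, function(x) if (x < 0) -Inf else 0, 1))
})

test_that("step size zero means certain acceptance without movement", {
  set.seed(3)
  accs <- replicate(200, rw_metropolis_step(0.7, function(x)
    dnorm(x, log = TRUE), 0)$accepted)
  expect_true(all(accs))
  vals <- replicate(50, rw_metropolis_step(0.7, function(x)
    dnorm(x, log = TRUE), 0)$value)
  expect_true(all(vals == 0.7))
})

test_that("the engine reproduces a conjugate normal-normal posterior", {
  set.seed(4)
  y <- rnorm(20, 1.5, 1)
  # closed-form posterior: precision 1 + n, mean sum(y)/(1 + n)
  post_mean <- sum(y) / (1 + length(y))
  post_var <- 1 / (1 + length(y))
  model <- toy_normal_model(y)
  dr <- run_chain(model, NULL, NULL,
                  chain_config(burnin = 2000, samples = 4000, seed = 5))
  th <- dr$draws[, "theta"]
  ess <- mcmc_diagnostics(dr)$ess
  se <- sqrt(post_var / ess)
  expect_lt(abs(mean(th) - post_mean), 3 * se)
  expect_lt(abs(var(th) - post_var) / post_var, 0.15)
})

test_that("chains are reproducible and thinning preserves sample count", {
  y <- c(0.3, -0.1, 0.7)
  model <- toy_normal_model(y)
  d1 <- run_chain(model, NULL, NULL,
                  chain_config(burnin = 100, samples = 50, thin = 5,
                               seed = 42))
  d2 <- run_chain(model, NULL, NULL,
                  chain_config(burnin = 100, samples = 50, thin = 5,
                               seed = 42))
  expect_identical(d1$draws, d2$draws)      # bit-identical under equal seeds
  expect_equal(nrow(d1$draws), 50)
  d3 <- run_chain(model, NULL, NULL,
                  chain_config(burnin = 100, samples = 50, thin = 1,
                               seed = 42))
  expect_false(identical(d1$draws, d3$draws))
  expect_equal(nrow(d3$draws), 50)
})

test_that("gibbs_sweep applies the model's block updates", {
  model <- toy_normal_model(c(1, 2))
  set.seed(1)
  out <- gibbs_sweep(model, list(theta = 0), list(theta = 0.5))
  expect_named(out$state, "theta")
  expect_type(out$accepted$theta, "logical")
  # zero step size leaves continuous parameters unchanged
  out0 <- gibbs_sweep(model, list(theta = 0.3), list(theta = 0))
  expect_equal(out0$state$theta, 0.3)
})

test_that("diagnostics report sensible ESS, stationarity and ACF summaries", {
  set.seed(6)
  d <- mcmc_diagnostics(matrix(rnorm(1000), dimnames = list(NULL, "x")))
  expect_gt(d$ess, 800); expect_lt(d$ess, 1200)
  expect_lt(abs(d$acf1), 0.1)

  # constant chain: flagged, not an error
  dc <- mcmc_diagnostics(matrix(1, 100, 1, dimnames = list(NULL, "c")))
  expect_true(dc$flag)
  expect_true(is.na(dc$acf1))

  # AR(1) with rho = 0.9: ESS ~ n (1 - rho) / (1 + rho)
  rho <- 0.9; n <- 20000
  x <- numeric(n); x[1] <- 0
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, 0, sqrt(1 - rho^2))
  da <- mcmc_diagnostics(matrix(x, dimnames = list(NULL, "ar")))
  ess_theory <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(da$ess - ess_theory) / ess_theory, 0.3)
  expect_equal(da$acf1, rho, tolerance = 0.05)
})

test_that("our ESS estimator agrees with an independent implementation", {
  skip_if_not_installed("coda")
  set.seed(8)
  rho <- 0.7; n <- 5000
  x <- as.numeric(arima.sim(list(ar = rho), n))
  ours <- mcmc_diagnostics(matrix(x, dimnames = list(NULL, "x")))$ess
  theirs <- unname(coda::effectiveSize(coda::mcmc(x)))
  expect_lt(abs(ours - theirs) / theirs, 0.35)
})

test_that("run_chain rejects a non-finite initial state", {
  y <- c(1, 2)
  model <- toy_normal_model(y)
  model$init <- function(data, priors) list(theta = Inf)
  model$logpost <- function(s) -Inf
  expect_error(run_chain(model, NULL, NULL, quick_config()), "theta")
})
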