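## shared helpers for the test suite

## short chain settings for functional (non-recovery) tests
quick_config <- function(seed = 1, burnin = 300, samples = 150, thin = 1)
  chain_config(burnin = burnin, samples = samples, thin = thin, seed = seed)

## first-passage time of the logistic curve through 2P by bisection
first_passage_2P <- function(K, r, P, tol = 1e-12) {
  stopifnot(K > 2 * P)
  lo <- 0; hi <- 1
  while (logistic_solution(hi, K, r, P) < 2 * P) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (logistic_solution(mid, K, r, P) < 2 * P) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## build a minimal interaction-fit object for testing call classification
fake_ihm_fit <- function(delta_draws, gamma_draws, orfs) {
  draws <- cbind(delta_draws, delta_draws * gamma_draws,
                 gamma_draws)
  colnames(draws) <- c(paste0("delta_", orfs), paste0("dg_", orfs),
                       paste0("gamma_", orfs))
  structure(list(draws = structure(list(draws = draws),
                                   class = "qfa_draws"),
                 orfs = orfs),
            class = "qfa_ihm")
}

## conjugate normal-normal toy model for the MCMC engine:
## y_i ~ N(theta, 1), theta ~ N(0, 1); posterior is closed form
toy_normal_model <- function(y) {
  list(
    init = function(data, priors) list(theta = 0),
    logpost = function(s) sum(dnorm(y, s$theta, 1, log = TRUE)) +
      dnorm(s$theta, 0, 1, log = TRUE),
    tuning0 = function(s) list(theta = 1),
    sweep = function(s, tun) {
      lp <- function(v) sum(dnorm(y, v, 1, log = TRUE)) +
        dnorm(v, 0, 1, log = TRUE)
      st <- rw_metropolis_step(s$theta, lp, tun$theta)
      list(state = list(theta = st$value),
           accepted = list(theta = st$accepted))
    },
    monitor = function(s) c(theta = s$theta),
    blame = function(s) "theta")
}
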