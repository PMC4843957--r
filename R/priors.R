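## Default hyperparameter values for the three hierarchical models.
##
## Naming: Greek symbols are transliterated (eta_K_p is the prior precision
## of log K^p, eta_K_o the prior mean of log sigma_K_o, and so on). Every
## *_p suffix, eta_P, eta_alpha, eta_beta and every psi_* entry is a
## precision; eta_K_o, eta_r_o, eta_nu, eta_gamma, eta_omega, eta_tau_K,
## eta_tau_r and eta_Z are means of log-scale quantities and may be
## negative.
##
## Grouping: the growth hyperpriors (including the sigma_tau layer
## eta_tau_K, psi_tau_K, eta_tau_r, psi_tau_r) are shared by the SHM and
## the JHM; the JHM adds the condition and interaction hyperpriors; the
## IHM has its own fitness-scale set. Each model requires its full
## explicit set, so nothing is inferred across models silently.
.default_priors <- list(
  shm = list(
    K_mu = -2.01, eta_K_p = 0.03,
    r_mu = 0.97,  eta_r_p = 0.13,
    P_mu = -9.04, eta_P = 0.47,
    nu_mu = 19.82, eta_nu_p = 0.02,
    eta_nu = -0.83, psi_nu = 0.86,
    eta_K_o = -0.79, psi_K_o = 0.61,
    eta_r_o = 0.47,  psi_r_o = 0.10,
    tau_K_mu = 2.20, eta_tau_K_p = 0.02,
    tau_r_mu = 3.65, eta_tau_r_p = 0.02,
    eta_tau_K = 2.20, psi_tau_K = 0.02,
    eta_tau_r = 3.65, psi_tau_r = 0.02
  ),
  ihm = list(
    Z_mu = 3.66, eta_Z_p = 0.70,
    eta_Z = 0.10, psi_Z = 0.42,
    nu_mu = 2.60, eta_nu_p = 0.05,
    eta_nu = 0.10, psi_nu = 2.45,
    alpha_mu = 0.00, eta_alpha = 0.31,
    eta_gamma = 0.10, psi_gamma = 0.42,
    p = 0.05
  ),
  jhm = list(
    K_mu = -2.01, eta_K_p = 0.03,
    r_mu = 0.97,  eta_r_p = 0.13,
    P_mu = -9.04, eta_P = 0.47,
    nu_mu = 19.82, eta_nu_p = 0.02,
    eta_nu = -0.83, psi_nu = 0.86,
    eta_K_o = -0.79, psi_K_o = 0.61,
    eta_r_o = 0.47,  psi_r_o = 0.10,
    tau_K_mu = 2.20, eta_tau_K_p = 0.02,
    tau_r_mu = 3.65, eta_tau_r_p = 0.02,
    eta_tau_K = 2.20, psi_tau_K = 0.02,
    eta_tau_r = 3.65, psi_tau_r = 0.02,
    alpha_mu = 0.00, eta_alpha = 0.25,
    beta_mu = 0.00,  eta_beta = 0.25,
    eta_gamma = -0.79, psi_gamma = 0.61,
    eta_omega = 0.47,  psi_omega = 0.10,
    p = 0.05
  )
)

.precision_keys <- function(model) {
  keys <- names(.default_priors[[model]])
  keys[grepl("_p$", keys) | grepl("^psi_", keys) |
         keys %in% c("eta_P", "eta_alpha", "eta_beta")]
}

#' Hyperprior configuration for the hierarchical QFA models
#'
#' Returns the fixed hyperparameters of the chosen model, starting from the
#' package defaults (which were established from broad historical QFA
#' screens) and applying any overrides. \code{load_priors} reads overrides
#' from a YAML or JSON file instead.
#'
#' Every second parameter in the models is a precision (variance =
#' 1/precision); see \code{\link{qfa_kernel}}. \code{p} is the prior
#' probability that a gene deletion interacts with the query mutation
#' (default 0.05: the experimenter's belief that 5\% of genes interact).
#'
#' @param model \code{"shm"}, \code{"ihm"} or \code{"jhm"}.
#' @param ... named overrides of individual hyperparameters.
#' @return Named list of hyperparameters (class \code{"qfa_priors"}).
#' @examples
#' qfa_priors("ihm", p = 0.1)
#' @export
qfa_priors <- function(model = c("shm", "ihm", "jhm"), ...) {
  model <- match.arg(model)
  pr <- .default_priors[[model]]
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(pr))
    if (length(bad))
      stop("unknown hyperparameter(s) for ", model, ": ",
           paste(bad, collapse = ", "), "; expected: ",
           paste(names(pr), collapse = ", "))
    pr[names(over)] <- over
  }
  validate_priors(pr, model)
  structure(pr, class = "qfa_priors", model = model)
}

#' @rdname qfa_priors
#' @param path path to a YAML (or JSON) file of overrides; \code{NULL} or a
#'   file with no entries gives the full defaults.
#' @export
load_priors <- function(path = NULL, model = c("shm", "ihm", "jhm")) {
  model <- match.arg(model)
  over <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("priors file not found: ", path)
    over <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path) else yaml::read_yaml(path)
    if (is.null(over)) over <- list()
  }
  do.call(qfa_priors, c(list(model = model), over))
}

validate_priors <- function(pr, model) {
  expected <- names(.default_priors[[model]])
  miss <- setdiff(expected, names(pr))
  if (length(miss))
    stop("missing hyperparameter(s) for ", model, ": ",
         paste(miss, collapse = ", "))
  for (k in .precision_keys(model))
    if (!is.numeric(pr[[k]]) || pr[[k]] <= 0)
      stop("hyperparameter ", k, " is a precision and must be > 0")
  if (!is.null(pr$p) && (pr$p < 0 || pr$p > 1))
    stop("interaction prior probability p must be in [0, 1]")
  invisible(pr)
}
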