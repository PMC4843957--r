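## S3 methods for the fitted-model classes.

#' @export
print.qfa_draws <- function(x, ...) {
  cat("MCMC draws:", nrow(x$draws), "retained samples x",
      ncol(x$draws), "parameters\n")
  cat("burn-in", x$config$burnin, "| thin", x$config$thin,
      "| seed", x$config$seed, "\n")
  invisible(x)
}

#' @export
print.qfa_shm <- function(x, ...) {
  cat("Separate hierarchical model (one screen), condition",
      x$condition, "\n")
  cat(x$data$L, "gene deletions,", x$data$C, "cultures,",
      sum(x$data$nobs), "density observations\n")
  cm <- coef(x)
  cat(sprintf("posterior means: P = %.3g, K_p = %.3g, r_p = %.3g\n",
              cm["P"], cm["K_p"], cm["r_p"]))
  invisible(x)
}

#' @export
print.qfa_ihm <- function(x, ...) {
  n <- sum(x$calls$significant)
  cat("Interaction hierarchical model:", length(x$orfs), "genes,",
      n, "called significant (posterior indicator mean > 0.5)\n")
  cat(sprintf("condition effect alpha1 (posterior mean): %.3f\n",
              coef(x)["alpha1"]))
  invisible(x)
}

#' @export
print.qfa_jhm <- function(x, ...) {
  n <- sum(x$calls$significant)
  cat("Joint hierarchical model:", length(x$orfs), "genes,",
      x$data$C, "cultures,", n,
      "called significant (posterior indicator mean > 0.5)\n")
  cm <- coef(x)
  cat(sprintf("condition effects: alpha1 = %.3f (log K), beta1 = %.3f (log r)\n",
              cm["alpha1"], cm["beta1"]))
  invisible(x)
}

#' @export
coef.qfa_shm <- function(object, ...) colMeans(object$draws$draws)

#' @export
coef.qfa_ihm <- function(object, ...) colMeans(object$draws$draws)

#' @export
coef.qfa_jhm <- function(object, ...) colMeans(object$draws$draws)

#' @export
summary.qfa_shm <- function(object, ...) mcmc_diagnostics(object$draws)

#' @export
summary.qfa_ihm <- function(object, ...) {
  list(calls = object$calls, diagnostics = mcmc_diagnostics(object$draws))
}

#' @export
summary.qfa_jhm <- function(object, ...) {
  list(calls = object$calls, diagnostics = mcmc_diagnostics(object$draws))
}

#' Fitness plot for interaction calls
#'
#' The standard QFA visualisation: mean query fitness against mean control
#' fitness per gene, with the genetic-independence line (slope
#' \eqn{e^{\alpha_1}}), the equal-fitness diagonal, and significant
#' suppressors/enhancers highlighted.
#'
#' @param x a \code{qfa_ihm} or \code{qfa_jhm} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.qfa_jhm <- function(x, ...) {
  ft <- jhm_fitness_and_calls(x)$fitness
  calls <- x$calls[match(ft$orf, x$calls$orf), ]
  cols <- ifelse(!calls$significant, "grey60",
                 ifelse(calls$label == "suppressor", "red3", "green4"))
  graphics::plot(ft$F_control, ft$F_query, col = cols, pch = 19,
                 xlab = "control fitness", ylab = "query fitness", ...)
  graphics::abline(0, 1, lty = 2)
  a1 <- mean(x$draws$draws[, "alpha1"])
  b1 <- mean(x$draws$draws[, "beta1"])
  graphics::abline(0, exp(a1 + b1), col = "blue")
  invisible(x)
}

#' @rdname plot.qfa_jhm
#' @export
plot.qfa_ihm <- function(x, ...) {
  d <- x$draws$draws
  eZ <- colMeans(d[, paste0("eZ_", x$orfs), drop = FALSE])
  a1 <- mean(d[, "alpha1"])
  dg <- colMeans(d[, paste0("dg_", x$orfs), drop = FALSE])
  Fq <- exp(a1) * eZ * exp(dg)
  calls <- x$calls[match(x$orfs, x$calls$orf), ]
  cols <- ifelse(!calls$significant, "grey60",
                 ifelse(calls$label == "suppressor", "red3", "green4"))
  graphics::plot(eZ, Fq, col = cols, pch = 19,
                 xlab = "control fitness", ylab = "query fitness", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(0, exp(a1), col = "blue")
  invisible(x)
}

#' Growth-curve panel for one gene
#'
#' Plots the observed density time courses of one gene in one condition
#' with, for a JHM fit, the fitted gene-level curve and the
#' expected-no-interaction curve overlaid.
#'
#' @param x a \code{qfa_shm} or \code{qfa_jhm} fit.
#' @param orf gene identifier.
#' @param condition screen to plot (JHM only; 0 or 1).
#' @param ... passed to \code{plot}.
#' @export
plot.qfa_shm <- function(x, orf = x$data$orfs[1], ...) {
  dat <- x$data
  i <- which(dat$orf_c == orf)
  graphics::matplot(t(dat$tmat[i, , drop = FALSE]),
                    t(dat$ymat[i, , drop = FALSE]), pch = 1, col = "grey40",
                    xlab = "time (days)", ylab = "scaled density", ...)
  cm <- coef(x)
  tt <- seq(0, max(dat$tmat, na.rm = TRUE), length.out = 80)
  graphics::lines(tt, logistic_solution(tt, cm[paste0("eKo_", orf)],
                                        cm[paste0("ero_", orf)], cm["P"]),
                  col = "red3", lwd = 2)
  invisible(x)
}

#' Simulate replicate datasets from a fitted SHM
#'
#' Draws new observation noise around the logistic curves of retained
#' posterior draws (posterior predictive replication).
#'
#' @param object a \code{qfa_shm} fit.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of \code{nsim} time-course data frames.
#' @export
simulate.qfa_shm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dat <- object$data
  d <- object$draws$draws
  idx <- sample(nrow(d), nsim, replace = TRUE)
  cid <- paste(dat$orf_c, dat$rep, sep = ".")
  lapply(idx, function(i) {
    K <- d[i, paste0("K_", cid)]; r <- d[i, paste0("r_", cid)]
    P <- d[i, "P"]; nu <- d[i, paste0("nu_", dat$orf_c)]
    x <- K / (1 + (K / P - 1) * exp(-r * dat$tmat))
    y <- x + stats::rnorm(length(x), 0, rep(1 / sqrt(nu), ncol(dat$tmat)))
    tc <- data.frame(orf = rep(dat$orf_c, ncol(dat$tmat)),
                     condition = rep(dat$cond, ncol(dat$tmat)),
                     `repeat` = rep(dat$rep, ncol(dat$tmat)),
                     time_days = as.vector(dat$tmat),
                     density = pmin(pmax(as.vector(y), 0), 1),
                     check.names = FALSE)
    tc[!is.na(tc$time_days), ]
  })
}

#' Residuals of the posterior-mean SHM fit
#'
#' Observed densities minus the logistic curves evaluated at the
#' posterior-mean repeat-level parameters.
#'
#' @param object a \code{qfa_shm} fit.
#' @param ... unused.
#' @return Numeric vector of residuals (observation order of the culture
#'   index).
#' @export
residuals.qfa_shm <- function(object, ...) {
  dat <- object$data
  cm <- coef(object)
  cid <- paste(dat$orf_c, dat$rep, sep = ".")
  K <- cm[paste0("K_", cid)]; r <- cm[paste0("r_", cid)]; P <- cm["P"]
  x <- K / (1 + (K / P - 1) * exp(-r * dat$tmat))
  as.vector((dat$ymat - x)[dat$obs])
}

#' @export
print.qfa_baseline <- function(x, ...) {
  cat("Per-gene linear-model comparator:", nrow(x), "genes,",
      sum(x$significant), "significant at q < 0.05\n")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
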