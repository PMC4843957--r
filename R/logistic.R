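#' Logistic population growth
#'
#' Analytic solution of the logistic growth equation
#' \eqn{\dot{x} = r x (1 - x/K)} used throughout quantitative fitness
#' analysis (QFA) to describe cell-density time courses of microbial
#' cultures growing on solid agar:
#' \deqn{x(t) = \frac{K P e^{rt}}{K + P(e^{rt} - 1)}.}
#' \code{K} is the carrying capacity (maximum achievable population density,
#' scaled so that the maximum observable density on a plate is 1), \code{P}
#' the inoculum density (initial condition, same scaled units) and \code{r}
#' the intrinsic growth rate per day.
#'
#' The implementation evaluates the algebraically identical form
#' \eqn{K / \{1 + (K/P - 1) e^{-rt}\}}, which cannot overflow for large
#' \code{r*t} and returns the limit \code{K} instead of \code{NaN}.
#'
#' @param t time since inoculation, in days (vector, all \code{>= 0}).
#' @param K carrying capacity, in scaled density units (\code{> 0}).
#' @param r intrinsic growth rate per day (\code{>= 0}).
#' @param P inoculum density, in scaled density units (\code{> 0}).
#' @return Scaled cell density at each time in \code{t}.
#' @examples
#' logistic_solution(0, K = 1, r = 2, P = 0.01)      # == P
#' logistic_solution(c(0, 1, 50), K = 0.5, r = 3, P = 1e-4)
#' @export
logistic_solution <- function(t, K, r, P) {
  stopifnot(is.numeric(t), is.numeric(K), is.numeric(r), is.numeric(P))
  if (!all(is.finite(t)) || !all(is.finite(K)) || !all(is.finite(r)) ||
      !all(is.finite(P)))
    stop("logistic_solution: non-finite inputs")
  if (any(t < 0)) stop("logistic_solution: t must be >= 0")
  if (any(K <= 0) || any(P <= 0) || any(r < 0))
    stop("logistic_solution: require K > 0, P > 0, r >= 0")
  K / (1 + (K / P - 1) * exp(-r * t))
}

#' Fitness measures from logistic growth parameters
#'
#' QFA summarises a fitted logistic curve by two univariate phenotypes and
#' their product:
#' \describe{
#'   \item{maximum doubling rate}{\eqn{DR = r / \log\{2(K-P)/(K-2P)\}}
#'     (doublings per day, natural log): the reciprocal of the time at
#'     which the culture first doubles its inoculum density. It captures
#'     the division rate immediately after inoculation.}
#'   \item{maximum doubling potential}{\eqn{DP = \log(K/P)/\log 2}
#'     (doublings): the number of divisions the culture undergoes before
#'     saturating at the carrying capacity.}
#'   \item{combined fitness}{\eqn{DRDP = DR \cdot DP}, the default overall
#'     fitness score, accounting for both attributes.}
#' }
#'
#' \code{DR} is undefined when \code{K <= 2P} (the culture can never double
#' its inoculum); \code{doubling_rate} then returns \code{NA}, which
#' propagates to \code{DRDP}. Callers implementing the dead-culture rule
#' (see \code{\link{ls_fit_logistic}}) typically set such fitnesses to 0.
#'
#' @param K,r,P logistic parameters; see \code{\link{logistic_solution}}.
#' @return \code{doubling_rate} and \code{doubling_potential} return the
#'   respective measure; \code{fitness_score} returns the requested one.
#' @examples
#' doubling_rate(K = 1, r = 1, P = 1e-9)   # ~ 1/log(2): exponential limit
#' doubling_potential(K = 0.1, P = 1e-4)   # log2(1000)
#' fitness_score(K = 0.1, r = 5, P = 1e-4) # DRDP
#' @export
doubling_rate <- function(K, r, P) {
  stopifnot(all(K > 0), all(P > 0), all(r >= 0))
  out <- rep(NA_real_, length(r + K + P)) # recycled length
  den <- log(2 * (K - P) / (K - 2 * P))
  ok <- K > 2 * P
  out <- ifelse(ok, r / den, NA_real_)
  out
}

#' @rdname doubling_rate
#' @export
doubling_potential <- function(K, P) {
  stopifnot(all(K > 0), all(P > 0))
  if (any(K < P)) stop("doubling_potential: K < P (saturation below inoculum)")
  log(K / P) / log(2)
}

#' @rdname doubling_rate
#' @param measure one of \code{"DRDP"} (default), \code{"DR"}, \code{"DP"}.
#' @export
fitness_score <- function(K, r, P, measure = c("DRDP", "DR", "DP")) {
  measure <- match.arg(measure)
  switch(measure,
    DR   = doubling_rate(K, r, P),
    DP   = doubling_potential(K, P),
    DRDP = doubling_rate(K, r, P) * doubling_potential(K, P)
  )
}

#' Least-squares logistic fit to one culture time course
#'
#' Fits the logistic solution to a single culture's density observations by
#' minimising the residual sum of squares, as in classic (pre-Bayesian) QFA.
#' Optimisation is over \code{(log K, log r)} (and \code{log P} unless
#' \code{P_fixed} is supplied) by Nelder-Mead from a coarse grid of growth
#' rate starting values, which is robust for the sigmoid shapes seen in QFA.
#'
#' Cultures whose fitted curve barely rises above the inoculum cannot
#' identify \code{r} (sick, dead or missing cultures); following standard
#' QFA post-processing these are flagged dead and the growth rate is set to
#' 0 so that downstream fitness is 0. The rule used: fitted
#' \code{K <= 2 * P} or fitted \code{K < 1.05 * min(y)}.
#'
#' @param t,y numeric vectors of times (days) and scaled densities for one
#'   culture; at least 3 points.
#' @param P_fixed optional known inoculum density; if given only
#'   \code{(K, r)} are free.
#' @return A list with elements \code{K}, \code{r}, \code{P}, \code{rss},
#'   \code{dead} (logical), \code{converged} (logical).
#' @examples
#' tt <- seq(0, 4, length.out = 10)
#' yy <- logistic_solution(tt, K = 0.2, r = 3, P = 3e-5)
#' ls_fit_logistic(tt, yy)
#' @export
ls_fit_logistic <- function(t, y, P_fixed = NULL) {
  stopifnot(length(t) == length(y), length(t) >= 3, all(is.finite(t)),
            all(is.finite(y)), all(t >= 0))
  o <- order(t); t <- t[o]; y <- y[o]

  ymax <- max(y)
  ymin <- min(y)
  K0 <- max(ymax, 1e-6)
  P0 <- if (is.null(P_fixed)) max(min(y[y > 0], K0 / 2), 1e-9) else P_fixed

  obj <- function(par) {
    K <- exp(par[1]); r <- exp(par[2])
    P <- if (is.null(P_fixed)) exp(par[3]) else P_fixed
    if (!is.finite(K) || !is.finite(r) || !is.finite(P)) return(1e300)
    sum((y - K / (1 + (K / P - 1) * exp(-r * t)))^2)
  }

  best <- NULL
  for (r0 in c(0.5, 1.5, 3, 6, 12)) {
    par0 <- c(log(K0), log(r0), if (is.null(P_fixed)) log(P0))
    fit <- tryCatch(
      stats::optim(par0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }

  if (is.null(best)) {                       # non-convergence fallback
    K <- ymax; r <- 0
    P <- if (is.null(P_fixed)) max(ymin, 1e-9) else P_fixed
    return(list(K = K, r = r, P = P, rss = sum((y - mean(y))^2),
                dead = TRUE, converged = FALSE))
  }

  K <- exp(best$par[1]); r <- exp(best$par[2])
  P <- if (is.null(P_fixed)) exp(best$par[3]) else P_fixed
  dead <- (K <= 2 * P) || (K < 1.05 * ymin)
  if (dead) r <- 0
  list(K = K, r = r, P = P, rss = best$value, dead = dead,
       converged = best$convergence == 0)
}

#' Per-culture fitness table from least-squares logistic fits
#'
#' Runs \code{\link{ls_fit_logistic}} on every culture of a time-course
#' dataset and attaches the fitness measures. This is the frequentist
#' fitness pipeline used by \code{\link{fit_baseline}} and for initialising
#' the MCMC samplers.
#'
#' @param tc a time-course data frame as returned by
#'   \code{\link{read_timecourses}} or \code{\link{simulate_shm}} (columns
#'   \code{orf}, \code{condition}, \code{repeat}, \code{time_days},
#'   \code{density}).
#' @param P_fixed optional shared inoculum density (classic QFA fixes a
#'   single \code{P} for all cultures).
#' @return Data frame with one row per culture: \code{orf},
#'   \code{condition}, \code{repeat}, \code{K}, \code{r}, \code{P},
#'   \code{DR}, \code{DP}, \code{DRDP}, \code{dead_flag}. Dead cultures get
#'   \code{DR = DRDP = 0}.
#' @export
ls_fitness <- function(tc, P_fixed = NULL) {
  validate_timecourses(tc)
  key <- interaction(tc$orf, tc$condition, tc[["repeat"]], drop = TRUE)
  rows <- lapply(split(seq_len(nrow(tc)), key), function(idx) {
    d <- tc[idx, ]
    f <- ls_fit_logistic(d$time_days, d$density, P_fixed = P_fixed)
    dr <- if (f$dead) 0 else doubling_rate(f$K, f$r, f$P)
    if (is.na(dr)) { dr <- 0; f$dead <- TRUE; f$r <- 0 }
    dp <- doubling_potential(max(f$K, f$P), f$P)
    data.frame(orf = d$orf[1], condition = d$condition[1],
               `repeat` = d[["repeat"]][1],
               K = f$K, r = f$r, P = f$P,
               DR = dr, DP = dp, DRDP = dr * dp,
               dead_flag = f$dead, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$orf, out[["repeat"]]), , drop = FALSE]
}

#' Scale fitnesses so each screen has mean 1
#'
#' Classic QFA compares screens on a common scale by dividing each screen's
#' fitnesses by that screen's mean. To be robust to unequal replicate
#' counts, the screen mean is computed as the mean over per-gene
#' (per-orf-deletion) means, so after scaling the grand mean of gene-level
#' means is exactly 1 within each screen. The operation is idempotent.
#'
#' @param fitness numeric vector of per-culture fitness values.
#' @param orf gene (orf deletion) identifier per culture.
#' @param screen screen (condition) identifier per culture.
#' @return Scaled fitness vector, same order as input.
#' @export
scale_fitness <- function(fitness, orf, screen) {
  stopifnot(length(fitness) == length(orf), length(fitness) == length(screen))
  out <- fitness
  for (s in unique(screen)) {
    i <- screen == s
    gm <- mean(tapply(fitness[i], orf[i], mean, na.rm = TRUE), na.rm = TRUE)
    if (!is.finite(gm) || gm == 0)
      stop("scale_fitness: screen '", s, "' has zero or undefined mean fitness")
    out[i] <- fitness[i] / gm
  }
  out
}
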