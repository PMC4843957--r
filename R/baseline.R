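#' Frequentist per-gene linear-model comparator
#'
#' The pre-Bayesian QFA analysis: scaled fitnesses (each screen's gene-level
#' mean equal to 1, see \code{\link{scale_fitness}}) are modelled per gene
#' as \eqn{\tilde F_{cm} = \mu + \gamma_c + \epsilon_{cm}} with
#' \eqn{\gamma_0 = 0} and i.i.d. normal errors of common variance, so
#' \eqn{\gamma_1} is the interaction strength (query minus control mean).
#' Fitted per gene, this linear model is algebraically the pooled-variance
#' two-sample t test, which is how it is computed here; p values are
#' Benjamini-Hochberg corrected and genes with q < 0.05 are called
#' significant.
#'
#' @param fitness data frame with columns \code{orf}, \code{condition}
#'   (0/1) and \code{fitness} (per-culture fitness). Scaling to screen mean
#'   1 is applied internally unless \code{scaled = TRUE} asserts the input
#'   is already scaled.
#' @param scaled set \code{TRUE} if \code{fitness} is already scaled;
#'   the screen means are then checked.
#' @param alpha significance cut-off on the q values (default 0.05).
#' @return Object of class \code{"qfa_baseline"}: data frame with one row
#'   per gene (\code{orf}, \code{gamma1_hat}, \code{p_value},
#'   \code{q_value}, \code{significant}), sorted by q value. Genes with
#'   fewer than 2 replicates in either condition are dropped with a
#'   warning.
#' @export
fit_baseline <- function(fitness, scaled = FALSE, alpha = 0.05) {
  if (!"fitness" %in% names(fitness) && "DRDP" %in% names(fitness))
    fitness$fitness <- fitness$DRDP
  stopifnot(all(c("orf", "condition", "fitness") %in% names(fitness)),
            all(fitness$condition %in% 0:1))
  if (scaled) {
    for (s in 0:1) {
      i <- fitness$condition == s
      gm <- mean(tapply(fitness$fitness[i], fitness$orf[i], mean))
      if (abs(gm - 1) > 1e-6)
        stop("fitness not scaled: screen ", s, " gene-level grand mean is ",
             format(gm))
    }
    f <- fitness$fitness
  } else {
    f <- scale_fitness(fitness$fitness, fitness$orf, fitness$condition)
  }

  orfs <- sort(unique(fitness$orf))
  rows <- lapply(orfs, function(o) {
    x <- f[fitness$orf == o & fitness$condition == 0]
    y <- f[fitness$orf == o & fitness$condition == 1]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    n1 <- length(x); n2 <- length(y)
    g1 <- mean(y) - mean(x)
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
    if (sp2 <= 0) {
      pv <- if (g1 == 0) 1 else 0
    } else {
      tstat <- g1 / sqrt(sp2 * (1 / n1 + 1 / n2))
      pv <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
    }
    data.frame(orf = o, gamma1_hat = g1, p_value = pv,
               stringsAsFactors = FALSE)
  })
  drop <- vapply(rows, is.null, logical(1))
  if (any(drop))
    warning(sum(drop), " gene(s) dropped: fewer than 2 replicates in a ",
            "condition")
  out <- do.call(rbind, rows[!drop])
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- out$q_value < alpha
  out <- out[order(out$q_value, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qfa_baseline", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up q values: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at
#' 1 and order preserving. \code{NA} p values are excluded from \eqn{m} and
#' returned as \code{NA}.
#'
#' @param p vector of p values in [0, 1] (NAs allowed).
#' @return q values, same order as input.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  o <- order(p[ok])
  ps <- p[ok][o]
  qs <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  q[ok[o]] <- qs
  q
}
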