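## Internal helpers shared by the hierarchical growth-model samplers.

## Index a long time-course table into per-culture matrices. Rows of tmat /
## ymat are cultures; unbalanced numbers of time points are NA-padded.
build_culture_data <- function(tc) {
  validate_timecourses(tc)
  orfs <- sort(unique(tc$orf))
  cult_key <- paste(tc$orf, tc$condition, tc[["repeat"]], sep = "\r")
  cultures <- unique(cult_key)
  C <- length(cultures)
  idx <- split(seq_len(nrow(tc)), factor(cult_key, levels = cultures))
  maxN <- max(vapply(idx, length, integer(1)))
  tmat <- matrix(NA_real_, C, maxN)
  ymat <- matrix(NA_real_, C, maxN)
  for (i in seq_len(C)) {
    rows <- idx[[i]]
    o <- order(tc$time_days[rows])
    tmat[i, seq_along(rows)] <- tc$time_days[rows][o]
    ymat[i, seq_along(rows)] <- tc$density[rows][o]
  }
  parts <- strsplit(cultures, "\r", fixed = TRUE)
  orf_c <- vapply(parts, `[`, "", 1)
  cond_c <- as.integer(vapply(parts, `[`, "", 2))
  rep_c <- as.integer(vapply(parts, `[`, "", 3))
  list(orfs = orfs, L = length(orfs), C = C,
       cl = match(orf_c, orfs), cond = cond_c, rep = rep_c,
       orf_c = orf_c, tmat = tmat, ymat = ymat,
       obs = !is.na(ymat), nobs = rowSums(!is.na(ymat)))
}

## Residual sum of squares per culture for logistic curves K, r (vectors
## over cultures) and shared P.
rss_cultures <- function(dat, K, r, P) {
  x <- K / (1 + (K / P - 1) * exp(-r * dat$tmat))
  rowSums((dat$ymat - x)^2, na.rm = TRUE)
}

## Group sums: sum x over groups f (integers in 1..nlev), zeros for empty.
gsum <- function(x, f, nlev) {
  out <- numeric(nlev)
  s <- rowsum(x, f)
  out[as.integer(rownames(s))] <- s
  out
}

gcount <- function(f, nlev) tabulate(f, nbins = nlev)

## log prior density in x-coordinates when exp(x) has a scaled-t3 prior
## truncated to [0, Inf): includes the Jacobian exp(x).
lp_t3exp <- function(x, loc, prec) ldt3_prec(exp(x), loc, prec) + x

## conjugate normal-normal draw: prior N(m0, prec p0), n children
## N(theta, prec tau) with observed sum s
rnorm_conj <- function(m0, p0, tau, s, n) {
  prec <- p0 + n * tau
  stats::rnorm(1, (p0 * m0 + tau * s) / prec, 1 / sqrt(prec))
}
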