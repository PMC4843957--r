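#' Read and validate culture time courses
#'
#' QFA time courses are long/tidy delimited text with one row per
#' observation and columns \code{orf} (gene deletion id), \code{condition}
#' (0 = control screen, 1 = query screen), \code{repeat} (replicate index,
#' dense 1..M within each orf/condition), \code{time_days} (time since
#' inoculation, days) and \code{density} (scaled cell density in [0, 1]).
#' Wide plate-reader exports must be melted to this layout; the column
#' mapping is one row per (culture, photograph).
#'
#' @param path delimited text file (TSV by default; \code{sep = ","} for
#'   CSV).
#' @param sep field separator.
#' @param rescale if \code{TRUE}, densities are divided by the maximum
#'   observed density so the plate-level maximum is 1.
#' @return Validated data frame of time courses.
#' @export
read_timecourses <- function(path, sep = "\t", rescale = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tc <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (rescale && nrow(tc) && "density" %in% names(tc))
    tc$density <- tc$density / max(tc$density)
  validate_timecourses(tc)
  tc
}

#' @rdname read_timecourses
#' @param tc a candidate time-course data frame.
#' @export
validate_timecourses <- function(tc) {
  req <- c("orf", "condition", "repeat", "time_days", "density")
  miss <- setdiff(req, names(tc))
  if (length(miss))
    stop("time-course table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(tc$condition %in% c(0L, 1L)))
    stop("condition must be coded 0 (control) / 1 (query)")
  bad <- which(!is.finite(tc$density) | tc$density < 0 | tc$density > 1)
  if (length(bad))
    stop("density out of [0, 1] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(tc$time_days) | tc$time_days < 0)
  if (length(bad))
    stop("negative or non-finite time_days at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- interaction(tc$orf, tc$condition, tc[["repeat"]], drop = TRUE)
  for (idx in split(seq_len(nrow(tc)), key)) {
    tt <- tc$time_days[idx]
    if (any(diff(tt) <= 0))
      stop("times not strictly increasing within culture starting at row ",
           idx[1], " (orf ", tc$orf[idx[1]], ")")
  }
  for (oc in split(tc[["repeat"]],
                   interaction(tc$orf, tc$condition, drop = TRUE))) {
    m <- sort(unique(oc))
    if (!identical(as.integer(m), seq_along(m)))
      stop("repeat indices must be dense 1..M within each orf/condition")
  }
  invisible(tc)
}

#' @rdname read_timecourses
#' @export
write_timecourses <- function(tc, path, sep = "\t") {
  validate_timecourses(tc)
  utils::write.table(tc, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ranked interaction calls and posterior summaries
#'
#' Writes the standard result files of an interaction fit: a ranked calls
#' table (\code{calls.tsv}), a per-parameter posterior summary with
#' diagnostics (\code{posterior_summary.tsv}: mean, SD, ESS, stationarity
#' z, lag-1 autocorrelation) and a plain-text run log echoing the chain
#' configuration and seed.
#'
#' @param fit a fitted \code{qfa_ihm} or \code{qfa_jhm} object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, c("qfa_ihm", "qfa_jhm")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  calls_path <- file.path(dir, "calls.tsv")
  utils::write.table(fit$calls, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  diag_path <- file.path(dir, "posterior_summary.tsv")
  utils::write.table(mcmc_diagnostics(fit$draws), diag_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_path <- file.path(dir, "run_log.txt")
  cfg <- fit$draws$config
  writeLines(c(
    paste0("model: ", class(fit)[1]),
    paste0("burnin: ", cfg$burnin),
    paste0("samples: ", cfg$samples),
    paste0("thin: ", cfg$thin),
    paste0("seed: ", cfg$seed),
    paste0("adapt: ", cfg$adapt),
    paste0("target_acceptance: ", cfg$target_acceptance)
  ), log_path)
  invisible(c(calls_path, diag_path, log_path))
}
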