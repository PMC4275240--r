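#' Write a scan report as discoveries TSV plus JSON summary
#'
#' The TSV lists every discovery (level, trait, markerA, markerB, p, h2_AB,
#' h2_total); the JSON sidecar records the testing parameters and counts
#' (q, q*, delta, per-level test and rejection counts, the FDR bound) and
#' the skipped/aliased pairs.
#'
#' @param report a `scan_report` from [run_hierarchical()].
#' @param tsv_path path for the discoveries table.
#' @param json_path path for the JSON summary.
#' @param sep field separator for the TSV.
#' @return Invisibly, a list of the two paths.
#' @export
write_scan_report <- function(report, tsv_path, json_path, sep = "\t") {
  stopifnot(inherits(report, "scan_report"))
  utils::write.table(report$discoveries, tsv_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  skipped <- lapply(report$skipped, function(s) {
    if (is.null(s)) list() else s
  })
  summary <- list(q = report$q, q_star = report$q_star, delta = report$delta,
                  delta_mode = report$delta_mode, pi_hat = report$pi_hat,
                  fdr_bound = report$bound, counts = report$counts,
                  n_framework = length(report$plan$framework),
                  skipped = skipped)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(tsv = tsv_path, json = json_path))
}

#' Quantile-quantile table for scan p-values
#'
#' Under a uniform null, `-log(p)` is standard exponential; the table pairs
#' the sorted observed `-log(p)` with the corresponding exponential
#' theoretical quantiles, ready for plotting. Zero p-values are capped and
#' flagged.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param null_dist theoretical null for `-log(p)`: `"exponential"` (the
#'   uniform-p equivalent; default) — kept as an argument for symmetry with
#'   plots annotated either way.
#' @param cap replacement for `p = 0` before taking logs.
#' @return A data.frame with columns `expected` and `observed` (-log p,
#'   ascending) and an attribute `n_capped`.
#' @export
pvalue_qq_data <- function(pvalues, null_dist = c("exponential", "uniform"),
                           cap = 1e-300) {
  null_dist <- match.arg(null_dist)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p <- pvalues[!is.na(pvalues)]
  n_capped <- sum(p == 0)
  p[p == 0] <- cap
  obs <- sort(-log(p))
  exp_q <- stats::qexp(stats::ppoints(length(p)))
  out <- data.frame(expected = exp_q, observed = obs)
  attr(out, "n_capped") <- n_capped
  out
}

#' Write a simulation summary as JSON plus per-replicate TSV
#'
#' @param summary a `sim_summary`.
#' @param json_path path for the aggregate JSON.
#' @param tsv_path optional path for the per-replicate table.
#' @param sep field separator.
#' @return Invisibly, the paths written.
#' @export
write_sim_summary <- function(summary, json_path, tsv_path = NULL, sep = "\t") {
  stopifnot(inherits(summary, "sim_summary"))
  agg <- summary[c("power", "power_se", "fdr", "fdr_se", "h2_epistasis",
                   "h2_total", "n_reps", "n_failed", "mode", "method")]
  if (summary$n_reps < 2L) {
    agg$power_se <- NA
    agg$fdr_se <- NA
    agg$note <- "standard errors undefined with a single replicate"
  }
  jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(tsv_path)) {
    utils::write.table(summary$per_rep, tsv_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}
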