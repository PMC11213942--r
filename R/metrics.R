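# Forecast evaluation: symmetric mean absolute percentage error and
# per-pair logarithmic deviations.

#' Symmetric mean absolute percentage error
#'
#' `SMAPE = (100 / n) * sum(|y_i - x_i| / (|y_i| + |x_i|))`, reported in
#' percent on a 0-100 scale (the denominator is the plain sum of magnitudes,
#' not its half). Pairs where both values are zero contribute 0.
#'
#' @param predicted,measured Equal-length non-negative numeric vectors.
#' @return SMAPE in percent.
#' @export
smape <- function(predicted, measured) {
  if (length(predicted) != length(measured)) stop("length mismatch")
  if (!length(predicted)) stop("need at least one pair")
  num <- abs(predicted - measured)
  den <- abs(predicted) + abs(measured)
  terms <- ifelse(den == 0, 0, num / den)
  100 * mean(terms)
}

#' Logarithmic deviation
#'
#' Per-pair `ld_i = log(y_i / x_i)` and their sum `L_d`. Positive values
#' flag overestimation, negative underestimation. Natural log by default.
#'
#' @param predicted,measured Equal-length strictly positive numeric vectors.
#' @param base Logarithm base (default `exp(1)`; use 10 for log10 axes).
#' @return A list with `per_pair` and `sum`.
#' @export
log_deviation <- function(predicted, measured, base = exp(1)) {
  if (length(predicted) != length(measured)) stop("length mismatch")
  if (any(predicted <= 0) || any(measured <= 0))
    stop("log deviation requires strictly positive values")
  ld <- log(predicted / measured, base = base)
  list(per_pair = ld, sum = sum(ld))
}

#' Evaluation report for one structural parameter
#'
#' Matches predicted and measured plant records by (`plant_id`,
#' `date_index`) and aggregates SMAPE and the logarithmic deviations for the
#' chosen parameter. Unmatched records are excluded with a message.
#'
#' @param pred,truth Record data frames with `plant_id`, `date_index` and
#'   the parameter column.
#' @param parameter `"height"` or `"crown_area"`.
#' @return An object of class `eval_report`: `n_pairs`, `smape_percent`,
#'   `ld_pairs`, `ld_sum`, `over_count`, `under_count`, `zero_count`.
#' @export
evaluation_report <- function(pred, truth, parameter = c("height", "crown_area")) {
  parameter <- match.arg(parameter)
  key <- function(d) paste(d$plant_id, d$date_index)
  m <- match(key(pred), key(truth))
  if (anyNA(m) || nrow(pred) != nrow(truth))
    message("evaluation_report: ", sum(is.na(m)) + (nrow(truth) - sum(!is.na(m))),
            " unmatched records excluded")
  ok <- !is.na(m)
  if (!any(ok)) stop("no matched (plant_id, date_index) pairs")
  y <- pred[[parameter]][ok]
  x <- truth[[parameter]][m[ok]]
  ld <- log_deviation(y, x)
  structure(list(parameter = parameter,
                 n_pairs = length(y),
                 smape_percent = smape(y, x),
                 ld_pairs = ld$per_pair,
                 ld_sum = ld$sum,
                 over_count = sum(ld$per_pair > 0),
                 under_count = sum(ld$per_pair < 0),
                 zero_count = sum(ld$per_pair == 0)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: n = %d, SMAPE = %.3f%%, L_d sum = %.4f\n",
              x$parameter, x$n_pairs, x$smape_percent, x$ld_sum))
  cat(sprintf("  over/under/zero deviations: %d / %d / %d\n",
              x$over_count, x$under_count, x$zero_count))
  invisible(x)
}

#' Write an evaluation report as JSON (plus optional per-pair CSV)
#' @param report An `eval_report`.
#' @param path JSON output path.
#' @param pairs_csv Optional CSV path for the per-pair deviations.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path, pairs_csv = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(pairs_csv))
    utils::write.csv(data.frame(pair = seq_along(report$ld_pairs),
                                ld = report$ld_pairs),
                     pairs_csv, row.names = FALSE)
  invisible(path)
}
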