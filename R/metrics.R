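#' Three-case step function used by the concordance index
#'
#' Returns 1 when `m > 0`, 0.5 when `m == 0`, and 0 when `m < 0`. This is the
#' scoring kernel applied to differences of predicted affinities when the
#' true affinities are strictly ordered.
#'
#' @param m numeric vector of finite values.
#' @return numeric vector of the same length with values in {0, 0.5, 1}.
#' @export
#' @examples
#' step_h(c(2, 0, -1))  # 1.0 0.5 0.0
step_h <- function(m) {
  if (any(!is.finite(m))) input_error("step_h: argument must be finite")
  ifelse(m > 0, 1, ifelse(m < 0, 0, 0.5))
}

#' Concordance index for affinity ranking
#'
#' Fraction of comparable pairs (pairs whose true affinities differ) for
#' which the predictions are ordered the same way; prediction ties count
#' one half. Pairs with tied true affinities are not comparable and are
#' excluded from the normalisation constant.
#'
#' @param pred numeric vector of predicted affinities.
#' @param true numeric vector of observed affinities, same length.
#' @return a number in \[0, 1\].
#' @export
concordance_index <- function(pred, true) {
  if (length(pred) != length(true))
    input_error("concordance_index: pred and true must have equal length")
  if (length(true) < 2)
    input_error("concordance_index: need at least 2 observations")
  gt <- outer(true, true, ">")          # comparable ordered pairs
  z <- sum(gt)
  if (z == 0)
    undefined_metric_error("concordance_index: all true affinities tied; no comparable pair")
  pd <- outer(pred, pred, "-")
  sum(step_h(pd[gt])) / z
}

#' Pearson correlation between predictions and observations
#'
#' Covariance divided by the product of standard deviations.
#'
#' @inheritParams concordance_index
#' @return a number in \[-1, 1\].
#' @export
pearson_r <- function(pred, true) {
  if (length(pred) != length(true))
    input_error("pearson_r: pred and true must have equal length")
  if (length(true) < 2)
    input_error("pearson_r: need at least 2 observations")
  if (stats::var(pred) == 0 || stats::var(true) == 0)
    undefined_metric_error("pearson_r: zero variance in input")
  stats::cor(pred, true)
}

#' Mean squared error
#'
#' @inheritParams concordance_index
#' @return non-negative number, mean of squared residuals.
#' @export
mse <- function(pred, true) {
  if (length(pred) != length(true))
    input_error("mse: pred and true must have equal length")
  if (length(pred) == 0) input_error("mse: empty input")
  mean((true - pred)^2)
}

#' rm2 external-validation index
#'
#' `rm2 = r2 * (1 - sqrt(r2 - r02))`, where `r2` is the squared Pearson
#' correlation between observed and predicted values and `r02` is the squared
#' correlation corresponding to the least-squares regression of the observed
#' values on the predicted values through the origin (slope
#' `k = sum(true * pred) / sum(pred^2)`). A model is conventionally deemed
#' acceptable when `rm2 >= 0.5`.
#'
#' @inheritParams concordance_index
#' @return a real number (1 for a perfect fit through the origin).
#' @export
rm2 <- function(pred, true) {
  r <- pearson_r(pred, true)
  r2 <- r^2
  k <- sum(true * pred) / sum(pred^2)
  ss_tot <- sum((true - mean(true))^2)
  r02 <- 1 - sum((true - k * pred)^2) / ss_tot
  arg <- r2 - r02
  if (arg < 0) {
    if (arg < -1e-8)
      warning("rm2: r2 < r02 beyond numerical tolerance; clamping sqrt argument at 0")
    arg <- 0
  }
  r2 * (1 - sqrt(arg))
}

#' Full evaluation report
#'
#' Computes CI, MSE, Pearson R and rm2 for one set of predictions. Metrics
#' that are undefined on the given data (e.g. Pearson R under constant
#' predictions) are reported as `NA` with an explanatory flag rather than
#' raising, so a whole evaluation never dies on one degenerate partition.
#'
#' @inheritParams concordance_index
#' @return an object of class `mildta_metrics`: list with `ci`, `mse`,
#'   `pearson_r`, `rm2`, `n`, `acceptable` (rm2 >= 0.5) and a character
#'   vector `flags` naming any undefined metrics.
#' @export
metrics_report <- function(pred, true) {
  flags <- character(0)
  ci_v <- tryCatch(concordance_index(pred, true), mildta_undefined_metric = function(e) {
    flags <<- c(flags, paste0("ci: ", conditionMessage(e))); NA_real_
  })
  r_v <- tryCatch(pearson_r(pred, true), mildta_undefined_metric = function(e) {
    flags <<- c(flags, paste0("pearson_r: ", conditionMessage(e))); NA_real_
  })
  rm2_v <- if (is.na(r_v)) {
    flags <- c(flags, "rm2: undefined because pearson_r is undefined")
    NA_real_
  } else rm2(pred, true)
  out <- list(ci = ci_v, mse = mse(pred, true), pearson_r = r_v, rm2 = rm2_v,
              n = length(pred),
              acceptable = !is.na(rm2_v) && rm2_v >= 0.5,
              flags = flags)
  class(out) <- "mildta_metrics"
  out
}

#' @export
print.mildta_metrics <- function(x, ...) {
  cat(sprintf("Evaluation over n = %d pairs\n", x$n))
  cat(sprintf("  CI        : %s\n", format(x$ci, digits = 4)))
  cat(sprintf("  MSE       : %s\n", format(x$mse, digits = 4)))
  cat(sprintf("  Pearson R : %s\n", format(x$pearson_r, digits = 4)))
  cat(sprintf("  rm2       : %s  (acceptable: %s)\n",
              format(x$rm2, digits = 4), x$acceptable))
  if (length(x$flags)) cat("  flags     :", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
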