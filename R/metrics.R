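# Validation metrics and multivariate detection limits.

#' Root mean squared error
#'
#' `sqrt(mean((predicted - actual)^2))`, in concentration units (ng/ml).
#'
#' @param predicted,actual Numeric vectors of equal, non-zero length.
#' @return RMSE, ng/ml.
#' @export
rmse <- function(predicted, actual) {
  if (!length(predicted)) stop("empty input")
  if (length(predicted) != length(actual)) stop("length mismatch")
  sqrt(mean((predicted - actual)^2))
}

#' Coefficient of determination
#'
#' `1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)`.
#' This is the regression definition, not a squared correlation: it can be
#' negative for models worse than the mean predictor, and is reported as
#' computed.
#'
#' @param predicted,actual Numeric vectors; `actual` must not be constant.
#' @return Dimensionless coefficient (<= 1).
#' @export
r_squared <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(actual) < 2) stop("need at least 2 pairs")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("R^2 undefined: all actual values are equal")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Blank leverages in calibration score space
#'
#' The leverage of a blank is `h0 = t0' (T'T)^-1 t0`, where `T` is the
#' calibration score matrix centered on its column means and `t0` the blank
#' score relative to the same center: the normalized squared distance of
#' the blank from the calibration centroid, which inflates prediction
#' variance in the detection-limit formula.
#'
#' @param cal_scores Calibration score matrix (samples x components).
#' @param blank_scores Blank score matrix (one row per blank spectrum).
#' @return List with the per-blank vector `h0` and the scalars `h0_min`,
#'   `h0_max`.
#' @export
blank_leverage <- function(cal_scores, blank_scores) {
  cal_scores <- as.matrix(cal_scores)
  blank_scores <- matrix(as.matrix(blank_scores), ncol = ncol(cal_scores))
  if (!nrow(blank_scores)) stop("need at least one blank")
  ctr <- colMeans(cal_scores)
  Tc <- sweep(cal_scores, 2, ctr)
  t0 <- sweep(blank_scores, 2, ctr)
  M <- tryCatch(solve(crossprod(Tc)),
                error = function(e) {
    stop("T'T is singular; use more calibration samples than components")
  })
  h0 <- rowSums((t0 %*% M) * t0)
  list(h0 = h0, h0_min = min(h0), h0_max = max(h0))
}

#' Multivariate detection limit from blank leverage
#'
#' `limit = factor * sqrt(sigma_b^2 / S0^2 * (1 + h0) + h0 * sigma_ycal^2)`:
#' the three variance contributions are instrumental blank noise
#' (`sigma_b^2/S0^2`), the blank's position in score space
#' (`h0 * sigma_b^2/S0^2`) and calibration error (`h0 * sigma_ycal^2`).
#' With `factor = 3.3` this is the limit of detection; replacing 3.3 by 10
#' gives the limit of quantification, so LOQ/LOD = 10/3.3 exactly for any
#' input. At `h0 = 0` it reduces to the univariate form
#' `factor * sigma_b / S0`.
#'
#' @param sigma_b Standard deviation of the blank response (signal units;
#'   if `sigma_b` is already a predicted-concentration SD, leave `S0 = 1`).
#' @param S0 Calibration sensitivity at minimum analyte concentration
#'   (signal per ng/ml); must be non-zero.
#' @param sigma_ycal Standard deviation of calibration residuals, ng/ml.
#' @param h0 Blank leverage(s), dimensionless (vectorized).
#' @param factor Expansion factor: 3.3 for LOD, 10 for LOQ.
#' @return Limit(s) in ng/ml, one per leverage value.
#' @export
detection_limits <- function(sigma_b, S0 = 1, sigma_ycal = 0, h0 = 0,
                             factor = 3.3) {
  if (any(c(sigma_b, sigma_ycal, h0) < 0)) {
    stop("sigma_b, sigma_ycal and h0 must be non-negative")
  }
  if (S0 == 0) stop("zero sensitivity: S0 must be non-zero")
  factor * sqrt(sigma_b^2 / S0^2 * (1 + h0) + h0 * sigma_ycal^2)
}

#' Assemble a calibration report
#'
#' Bundles the train/validation metrics, detection and quantification
#' limits and (optionally) fold-level cross-validation metrics into a
#' `calibration_report` that prints like the usual validation tables.
#'
#' @param hormone Hormone label.
#' @param train_pred,train_actual Training-set predictions / known values.
#' @param val_pred,val_actual Validation-set predictions / known values.
#' @param sigma_b Blank-response SD (here: SD of predicted concentration
#'   over replicate blanks, so `S0 = 1`).
#' @param S0 Sensitivity (see [detection_limits()]).
#' @param sigma_ycal Calibration-residual SD, ng/ml.
#' @param h0_min,h0_max Minimum / maximum blank leverages.
#' @param cv Optional result of [kfold_cv()].
#' @return An object of class `calibration_report`.
#' @export
build_report <- function(hormone, train_pred, train_actual, val_pred,
                         val_actual, sigma_b, S0 = 1, sigma_ycal,
                         h0_min, h0_max, cv = NULL) {
  if (h0_min > h0_max) stop("h0_min must be <= h0_max")
  structure(list(
    hormone = hormone,
    rmse_train = rmse(train_pred, train_actual),
    rmse_validation = rmse(val_pred, val_actual),
    r2_train = r_squared(train_pred, train_actual),
    r2_validation = r_squared(val_pred, val_actual),
    lod_min = detection_limits(sigma_b, S0, sigma_ycal, h0_min, 3.3),
    lod_max = detection_limits(sigma_b, S0, sigma_ycal, h0_max, 3.3),
    loq_min = detection_limits(sigma_b, S0, sigma_ycal, h0_min, 10),
    loq_max = detection_limits(sigma_b, S0, sigma_ycal, h0_max, 10),
    sigma_b = sigma_b, S0 = S0, sigma_ycal = sigma_ycal,
    h0_min = h0_min, h0_max = h0_max,
    n_train = length(train_actual), n_validation = length(val_actual),
    cv = cv), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration report —", toupper(x$hormone), "\n")
  cat(sprintf("  RMSE (ng/ml): training %.5f, validation %.5f\n",
              x$rmse_train, x$rmse_validation))
  cat(sprintf("  R^2         : training %.4f, validation %.4f\n",
              x$r2_train, x$r2_validation))
  cat(sprintf("  LOD (ng/ml) : min %.4f, max %.4f\n", x$lod_min, x$lod_max))
  cat(sprintf("  LOQ (ng/ml) : min %.4f, max %.4f\n", x$loq_min, x$loq_max))
  if (!is.null(x$cv)) {
    cat(sprintf("  %d-fold CV  : RMSE %.4f +/- %.4f, R^2 %.4f +/- %.4f\n",
                nrow(x$cv$folds), x$cv$rmse_mean, x$cv$rmse_sd,
                x$cv$r2_mean, x$cv$r2_sd))
  }
  invisible(x)
}

#' Serialize / restore a calibration report as JSON
#'
#' @param x A `calibration_report`.
#' @param file JSON path.
#' @return `write_calibration_report` returns `x` invisibly;
#'   `read_calibration_report` the restored report.
#' @export
write_calibration_report <- function(x, file) {
  y <- unclass(x)
  if (!is.null(y$cv)) y$cv$folds <- as.list(y$cv$folds)
  jsonlite::write_json(y, file, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(x)
}

#' @rdname write_calibration_report
#' @export
read_calibration_report <- function(file) {
  y <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(y$cv)) y$cv$folds <- as.data.frame(y$cv$folds)
  structure(y, class = "calibration_report")
}

#' Summarize a calibration report as a data frame
#'
#' One row per metric block, mirroring the usual RMSE/R^2 and LOD/LOQ
#' table layouts; convenient for CSV export.
#'
#' @param x A `calibration_report`.
#' @return Data frame with columns `hormone, metric, value`.
#' @export
report_table <- function(x) {
  data.frame(
    hormone = x$hormone,
    metric = c("rmse_train", "rmse_validation", "r2_train", "r2_validation",
               "lod_min", "lod_max", "loq_min", "loq_max"),
    value = c(x$rmse_train, x$rmse_validation, x$r2_train, x$r2_validation,
              x$lod_min, x$lod_max, x$loq_min, x$loq_max))
}
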