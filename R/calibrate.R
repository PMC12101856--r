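# End-to-end SERS calibration: simulate/ingest -> normalize -> PCA ->
# stratified split -> Rprop+ network -> metrics and detection limits.

#' Calibrate a SERS hormone-quantification model
#'
#' Fits the full chemometric calibration for one hormone: spectra are
#' vector-normalized, reduced to `n_components` principal-component scores,
#' split into stratified training/validation partitions, standardized with
#' the training partition's [score_scaler()] (common scale, so
#' noise-dominated components stay small) and regressed to concentration
#' by a ReLU multilayer perceptron trained with Rprop+. The number of training epochs of the
#' final network is chosen by k-fold cross-validation within the training
#' partition (the epoch minimizing the mean held-fold error), which guards
#' against overfitting the spectral noise. The report includes
#' training/validation RMSE and R^2, the fold-level CV metrics, and LOD/LOQ
#' computed from
#' simulated blank spectra (zero hormone) passed through the full
#' prediction path, whose leverages in calibration score space enter the
#' multivariate detection-limit formula.
#'
#' If `spectra` is `NULL`, a default calibration set is simulated from
#' `config` (30 log-spaced levels over 0.01-60 ng/ml, 30 replicates each).
#' All randomness (simulation, split, weight initialization, folds, blanks)
#' derives from `seed`.
#'
#' @param hormone `"gh"` or `"te"`; selects the varied hormone and the
#'   network architecture ([mlp_architecture()]).
#' @param spectra Optional [spectrum_set()] with known concentrations in
#'   its metadata; simulated when `NULL`.
#' @param config A [generator_config()] (used for simulation and blanks).
#' @param n_concentrations,conc_min,conc_max,n_replicates Design of the
#'   simulated calibration set (ignored when `spectra` is given).
#' @param n_components Number of PC scores fed to the network.
#' @param normalization Spectral normalization method.
#' @param train_fraction Training fraction of the stratified hold-out split.
#' @param k Folds for cross-validation (`k = 0` skips CV).
#' @param train_config A [train_config()].
#' @param n_blanks Number of simulated blank spectra for the detection
#'   limits.
#' @param n_starts Number of independently initialized networks in the
#'   committee; predictions are averaged over them ([ensemble_forward()]).
#' @param seed Integer seed controlling every stochastic stage.
#' @return An object of class `sers_calibration` with elements `hormone`,
#'   `pca`, `scaler`, `models` (the committee of trained [mlp_init()]
#'   networks), `split`, `report` (a [build_report()]), `scores`,
#'   `targets` and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- generator_config(grid_step = 8)
#' fit <- sers_calibrate("gh", config = cfg, n_concentrations = 8,
#'                       n_replicates = 6, k = 0, n_starts = 1, seed = 1)
#' fit
#' }
sers_calibrate <- function(hormone = c("gh", "te"), spectra = NULL,
                           config = generator_config(),
                           n_concentrations = 30, conc_min = 0.01,
                           conc_max = 60, n_replicates = 30,
                           n_components = 6,
                           normalization = "vector",
                           train_fraction = 0.75, k = 4,
                           train_config = serscal::train_config(),
                           n_blanks = 30, n_starts = 5, seed = 42) {
  hormone <- match.arg(hormone)
  cl <- match.call()
  if (is.null(spectra)) {
    spectra <- simulate_calibration_set(
      config, hormone, n_concentrations = n_concentrations,
      conc_min = conc_min, conc_max = conc_max,
      n_replicates = n_replicates, seed = seed)
  }
  targets <- spectra$metadata[[paste0(hormone, "_ng_ml")]]
  norm <- normalize_spectra(spectra, normalization)
  pca <- fit_spectral_pca(norm, n_components)
  scores <- predict(pca, norm)
  split <- holdout_split(targets, train_fraction, seed = seed + 1L)
  scaler <- score_scaler(scores[split$train, , drop = FALSE])
  tr_scores <- apply_score_scaler(scores[split$train, , drop = FALSE],
                                  scaler)
  tr_y <- targets[split$train]

  # cross-validated early stopping: the k-fold held-out loss chooses the
  # number of Rprop+ epochs for the final network (full-batch training to
  # a training-loss plateau demonstrably overfits spectral noise)
  cv <- NULL
  final_config <- train_config
  if (k >= 2) {
    cv <- kfold_cv(scores[split$train, , drop = FALSE], tr_y,
                   mlp_architecture(hormone), train_config,
                   k = k, seed = seed + 3L, trace = TRUE)
    final_config <- serscal::train_config(
      max_epochs = cv$best_epoch,
      eta_plus = train_config$eta_plus,
      eta_minus = train_config$eta_minus,
      delta0 = train_config$delta0,
      delta_min = train_config$delta_min,
      delta_max = train_config$delta_max,
      early_stop_tolerance = 0,
      patience = cv$best_epoch + 1L)
  }

  # committee of independently initialized networks; predictions are
  # averaged, which tames the initialization-to-initialization variance of
  # a single Rprop+ run
  models <- lapply(seq_len(n_starts), function(s) {
    model <- mlp_init(n_components, mlp_architecture(hormone),
                      seed = seed + 1000L + s)
    mlp_train(model, tr_scores, tr_y, final_config)
  })

  std <- function(sc) scale(sc, center = scaler$center, scale = scaler$scale)
  va_scores <- std(scores[split$test, , drop = FALSE])
  pred_tr <- ensemble_forward(models, tr_scores)
  pred_va <- ensemble_forward(models, va_scores)

  # blanks: zero-analyte blood-matrix spectra (the non-analyte hormone at
  # its endogenous baseline) through the full prediction path
  bg <- c(gh = pk_defaults("gh")$baseline, te = pk_defaults("te")$baseline)
  blank_gh <- if (hormone == "gh") 0 else unname(bg["gh"])
  blank_te <- if (hormone == "te") 0 else unname(bg["te"])
  blanks <- with_seed(seed + 2L, {
    t(replicate(n_blanks, simulate_spectrum(config, blank_gh, blank_te)))
  })
  blank_set <- spectrum_set(
    spectra$wavenumbers, blanks,
    data.frame(spectrum_id = sprintf("blank_%02d", seq_len(n_blanks)),
               group = "blank"))
  blank_scores <- predict(pca, normalize_spectra(blank_set, normalization))
  pred_blank <- ensemble_forward(models, std(blank_scores))
  lev <- blank_leverage(scores[split$train, , drop = FALSE], blank_scores)
  sigma_b <- stats::sd(pred_blank)    # predicted-concentration SD => S0 = 1
  sigma_ycal <- stats::sd(pred_tr - tr_y)

  report <- build_report(hormone, pred_tr, tr_y, pred_va,
                         targets[split$test], sigma_b, 1, sigma_ycal,
                         lev$h0_min, lev$h0_max, cv)
  structure(
    list(hormone = hormone, pca = pca, scaler = scaler, models = models,
         split = split, report = report, scores = scores,
         targets = targets, normalization = normalization,
         config = config, seed = seed, call = cl),
    class = "sers_calibration")
}

#' @export
print.sers_calibration <- function(x, ...) {
  cat("SERS calibration model —", toupper(x$hormone), "\n")
  cat("  committee of ", length(x$models), " network",
      if (length(x$models) > 1) "s" else "", " ",
      paste(x$models[[1]]$sizes, collapse = ":"),
      " (Rprop+, ", length(x$models[[1]]$training_history), " epochs); ",
      nrow(x$pca$loadings), " PC scores capturing ",
      sprintf("%.1f%%", 100 * sum(x$pca$explained_variance_ratio)),
      " of spectral variance\n", sep = "")
  cat(sprintf("  n = %d spectra (%d train / %d validation)\n",
              length(x$targets), length(x$split$train),
              length(x$split$test)))
  cat(sprintf("  validation RMSE %.4f ng/ml, R^2 %.4f\n",
              x$report$rmse_validation, x$report$r2_validation))
  invisible(x)
}

#' @export
summary.sers_calibration <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$report)
  invisible(object$report)
}

#' Predict hormone concentration from spectra
#'
#' Applies the calibration's preprocessing (normalization, PCA projection,
#' score standardization) and network to new spectra. With `newdata`
#' missing, fitted values for the calibration spectra are returned.
#'
#' @param object A [sers_calibrate()] fit.
#' @param newdata A [spectrum_set()] on the calibration grid (optional).
#' @param ... Ignored.
#' @return Numeric vector of predicted concentrations, ng/ml.
#' @export
predict.sers_calibration <- function(object, newdata, ...) {
  scores <- if (missing(newdata) || is.null(newdata)) {
    object$scores
  } else {
    predict(object$pca, normalize_spectra(newdata, object$normalization))
  }
  ensemble_forward(object$models,
                   scale(scores, center = object$scaler$center,
                         scale = object$scaler$scale))
}

#' Residuals of a SERS calibration
#'
#' @param object A [sers_calibrate()] fit.
#' @param which `"validation"`, `"train"` or `"all"` spectra.
#' @param ... Ignored.
#' @return Numeric vector of predicted minus known concentration, ng/ml.
#' @export
residuals.sers_calibration <- function(object,
                                       which = c("validation", "train",
                                                 "all"), ...) {
  which <- match.arg(which)
  idx <- switch(which,
                validation = object$split$test,
                train = object$split$train,
                all = seq_along(object$targets))
  pred <- ensemble_forward(object$models,
                           scale(object$scores[idx, , drop = FALSE],
                                 center = object$scaler$center,
                                 scale = object$scaler$scale))
  pred - object$targets[idx]
}

#' Predicted-versus-known plot of a calibration
#'
#' @param x A [sers_calibrate()] fit.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.sers_calibration <- function(x, ...) {
  pred <- predict(x)
  tr <- x$split$train
  plot(x$targets[tr], pred[tr], pch = 1, col = "grey40",
       xlab = "known concentration (ng/ml)",
       ylab = "predicted concentration (ng/ml)",
       main = paste0(toupper(x$hormone), " calibration"), ...)
  graphics::points(x$targets[x$split$test], pred[x$split$test],
                   pch = 16, col = "firebrick")
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", c("training", "validation"),
                   pch = c(1, 16), col = c("grey40", "firebrick"),
                   bty = "n")
  invisible(x)
}

#' Predict the in-vivo hormone time-course
#'
#' Simulates (or takes) a four-group injection experiment and runs every
#' spectrum through one or two calibration models, then averages predicted
#' concentration per group and sampling time (mean and SD over rats),
#' alongside the generator's true mean concentration.
#'
#' @param calibrations Named list with elements `gh` and/or `te`, each a
#'   [sers_calibrate()] fit.
#' @param experiment Optional [spectrum_set()] from
#'   [simulate_group_experiment()]; simulated from `config` when `NULL`.
#' @param config A [generator_config()]; defaults to the configuration of
#'   the first calibration. Its grid must match the stored PCA.
#' @param n_rats_per_group,seed Passed to [simulate_group_experiment()].
#' @return Data frame with columns `hormone, group, time_h, mean_true,
#'   mean_pred, sd_pred, n_rats`.
#' @export
predict_timecourse <- function(calibrations, experiment = NULL,
                               config = NULL, n_rats_per_group = 6,
                               seed = 7) {
  if (inherits(calibrations, "sers_calibration")) {
    calibrations <- stats::setNames(list(calibrations),
                                    calibrations$hormone)
  }
  if (is.null(config)) config <- calibrations[[1]]$config
  if (is.null(experiment)) {
    experiment <- simulate_group_experiment(config, n_rats_per_group,
                                            seed = seed)
  }
  md <- experiment$metadata
  out <- list()
  for (h in names(calibrations)) {
    cal <- calibrations[[h]]
    if (!isTRUE(all.equal(experiment$wavenumbers, cal$pca$wavenumbers))) {
      stop("experiment grid does not match the ", h, " calibration's PCA")
    }
    pred <- predict(cal, experiment)
    truth <- md[[paste0(h, "_ng_ml")]]
    key <- interaction(md$group, md$time_h, drop = TRUE)
    agg <- do.call(rbind, lapply(split(seq_len(nrow(md)), key),
                                 function(i) {
      data.frame(hormone = h, group = md$group[i[1]],
                 time_h = md$time_h[i[1]],
                 mean_true = mean(truth[i]), mean_pred = mean(pred[i]),
                 sd_pred = stats::sd(pred[i]), n_rats = length(i))
    }))
    out[[h]] <- agg
  }
  out <- do.call(rbind, out)
  out <- out[order(out$hormone, out$group, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Save / load a full calibration model as JSON
#'
#' Serializes the PCA, score scaler, network weights and report so a
#' calibration can be reloaded and used for prediction without refitting.
#'
#' @param object A [sers_calibrate()] fit.
#' @param file JSON path.
#' @return `save_calibration` returns `object` invisibly;
#'   `load_calibration` the restored `sers_calibration` (without the
#'   original spectra/scores).
#' @export
save_calibration <- function(object, file) {
  payload <- list(
    hormone = object$hormone,
    normalization = object$normalization,
    pca = list(wavenumbers = object$pca$wavenumbers,
               mean_spectrum = object$pca$mean_spectrum,
               loadings = object$pca$loadings,
               explained_variance_ratio =
                 object$pca$explained_variance_ratio,
               total_variance = object$pca$total_variance),
    scaler = object$scaler,
    sizes = object$models[[1]]$sizes,
    networks = lapply(object$models, function(m) {
      list(W = m$W, b = m$b)
    }),
    training_history_tail = tail(object$models[[1]]$training_history, 1),
    report = unclass(object$report)[c(
      "hormone", "rmse_train", "rmse_validation", "r2_train",
      "r2_validation", "lod_min", "lod_max", "loq_min", "loq_max",
      "n_train", "n_validation")],
    seed = object$seed)
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE)
  invisible(object)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  pca <- structure(
    list(wavenumbers = as.numeric(x$pca$wavenumbers),
         mean_spectrum = as.numeric(x$pca$mean_spectrum),
         loadings = as.matrix(x$pca$loadings),
         explained_variance_ratio =
           as.numeric(x$pca$explained_variance_ratio),
         total_variance = as.numeric(x$pca$total_variance)),
    class = "spectral_pca")
  rownames(pca$loadings) <- paste0("PC", seq_len(nrow(pca$loadings)))
  models <- lapply(x$networks, function(nw) {
    structure(
      list(sizes = as.integer(x$sizes),
           W = lapply(nw$W, as.matrix),
           b = lapply(nw$b, as.numeric),
           training_history = as.numeric(x$training_history_tail)),
      class = "mlp")
  })
  structure(
    list(hormone = x$hormone, pca = pca,
         scaler = list(center = as.numeric(x$scaler$center),
                       scale = as.numeric(x$scaler$scale)),
         models = models, split = NULL,
         report = structure(x$report, class = "calibration_report"),
         scores = NULL, targets = NULL,
         normalization = x$normalization, config = NULL,
         seed = x$seed, call = NULL),
    class = "sers_calibration")
}
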