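# ELISA standard curves: Boltzmann (GH) and exponential decay (TE),
# nonlinear least-squares fitting and closed-form inverse prediction.

#' Fit an ELISA standard curve
#'
#' Fits optical density against known concentration with nonlinear least
#' squares (Levenberg-Marquardt via [minpack.lm::nlsLM]), using a
#' data-driven start plus two perturbed restarts to avoid local minima.
#' Curve forms: Boltzmann sigmoid
#' `OD(x) = A2 + (A1 - A2) / (1 + exp((x - x0)/dx))` and exponential decay
#' `OD(x) = y0 + A * exp(-x / t)`.
#'
#' @param conc Standard concentrations, ng/ml (distinct; at least one more
#'   point than parameters).
#' @param od Measured optical densities.
#' @param form `"boltzmann"` or `"exp_decay"`.
#' @return An object of class `elisa_curve`: list with `form`, named
#'   `parameters`, `fit_r2`, the standards and the valid OD range for
#'   inversion.
#' @export
#' @examples
#' std <- simulate_elisa_standards("te", od_noise_sd = 0, seed = 1)
#' fit_elisa_curve(std$conc_ng_ml, std$od, "exp_decay")
fit_elisa_curve <- function(conc, od, form = c("boltzmann", "exp_decay")) {
  form <- match.arg(form)
  if (anyDuplicated(conc)) stop("standard concentrations must be distinct")
  n_par <- if (form == "boltzmann") 4L else 3L
  if (length(conc) < n_par + 1) {
    stop("need at least ", n_par + 1, " standards for the ", form, " form")
  }
  dat <- data.frame(x = conc, y = od)
  start0 <- if (form == "boltzmann") {
    mid <- (max(od) + min(od)) / 2
    list(A1 = od[which.min(conc)], A2 = od[which.max(conc)],
         x0 = conc[which.min(abs(od - mid))],
         dx = diff(range(conc)) / 4)
  } else {
    list(y0 = min(od), A = od[which.min(conc)] - min(od) + 1e-3,
         t = diff(range(conc)) / 3)
  }
  formula <- if (form == "boltzmann") {
    y ~ A2 + (A1 - A2) / (1 + exp((x - x0) / dx))
  } else {
    y ~ y0 + A * exp(-x / t)
  }
  perturb <- list(1, 0.5, 1.8)  # multi-start factors on the scale params
  fits <- list()
  for (p in perturb) {
    st <- start0
    if (form == "boltzmann") st$dx <- st$dx * p else st$t <- st$t * p
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) {
    stop("ELISA curve fit failed to converge from all starting points (",
         form, ", ", length(conc), " standards)")
  }
  best <- fits[[which.min(vapply(fits, stats::deviance, 1))]]
  pars <- as.list(stats::coef(best))
  fitted_od <- stats::predict(best)
  r2 <- 1 - sum((od - fitted_od)^2) / sum((od - mean(od))^2)
  if (form == "exp_decay" && pars$t <= 0) {
    stop("exponential-decay fit returned a non-positive time constant")
  }
  structure(list(form = form, parameters = pars, fit_r2 = r2,
                 standards = dat,
                 valid_od_range = range(fitted_od)),
            class = "elisa_curve")
}

#' @export
print.elisa_curve <- function(x, ...) {
  cat("<elisa_curve> ", x$form, " fit of ", nrow(x$standards),
      " standards, R^2 = ", sprintf("%.5f", x$fit_r2), "\n  parameters: ",
      paste(sprintf("%s = %.4g", names(x$parameters),
                    unlist(x$parameters)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Optical density predicted by a standard curve
#'
#' @param object An [fit_elisa_curve()] model.
#' @param newdata Concentrations, ng/ml.
#' @param ... Ignored.
#' @return Predicted optical densities.
#' @export
predict.elisa_curve <- function(object, newdata, ...) {
  p <- object$parameters
  if (object$form == "boltzmann") {
    p$A2 + (p$A1 - p$A2) / (1 + exp((newdata - p$x0) / p$dx))
  } else {
    p$y0 + p$A * exp(-newdata / p$t)
  }
}

#' Invert an ELISA standard curve
#'
#' Closed-form inversion of the fitted curve: concentration is predicted
#' from a sample's optical density. Optical densities outside the range
#' spanned by the fitted standards are refused (no extrapolation — inverse
#' prediction outside the standards is meaningless); results are clipped
#' at zero.
#'
#' @param curve An [fit_elisa_curve()] model.
#' @param od Optical density (vectorized).
#' @return Concentration(s), ng/ml.
#' @export
invert_elisa <- function(curve, od) {
  rng <- curve$valid_od_range
  tol <- 1e-9 * max(1, abs(rng))
  if (any(od < rng[1] - tol | od > rng[2] + tol)) {
    stop("optical density outside the valid range [",
         signif(rng[1], 6), ", ", signif(rng[2], 6),
         "] of the standard curve")
  }
  od <- pmin(pmax(od, rng[1]), rng[2])
  p <- curve$parameters
  x <- if (curve$form == "boltzmann") {
    ratio <- (p$A1 - p$A2) / (od - p$A2) - 1
    p$x0 + p$dx * log(ratio)
  } else {
    -p$t * log((od - p$y0) / p$A)
  }
  pmax(x, 0)
}

#' Compare ANN and ELISA time-course predictions
#'
#' Joins two prediction tables on group and time and reports per-group
#' paired differences (ANN minus ELISA), Pearson correlation and the time
#' of the predicted maximum for each method.
#'
#' @param ann,elisa Data frames with columns `group`, `time_h`, `conc`.
#' @return List with the merged `table`, per-group summary `by_group`
#'   (mean difference, correlation, peak times) and the overall Pearson
#'   correlation.
#' @export
compare_methods <- function(ann, elisa) {
  need <- c("group", "time_h", "conc")
  if (!all(need %in% names(ann)) || !all(need %in% names(elisa))) {
    stop("both tables need columns: ", paste(need, collapse = ", "))
  }
  tab <- merge(ann, elisa, by = c("group", "time_h"),
               suffixes = c("_ann", "_elisa"))
  if (nrow(tab) != nrow(ann) || nrow(tab) != nrow(elisa)) {
    stop("group/time keys of the two tables do not match")
  }
  tab <- tab[order(tab$group, tab$time_h), ]
  tab$diff <- tab$conc_ann - tab$conc_elisa
  by_group <- do.call(rbind, lapply(split(tab, tab$group), function(d) {
    data.frame(
      group = d$group[1],
      mean_diff = mean(d$diff),
      pearson_r = if (stats::sd(d$conc_ann) > 0 &&
                      stats::sd(d$conc_elisa) > 0) {
        stats::cor(d$conc_ann, d$conc_elisa)
      } else NA_real_,
      peak_time_ann = d$time_h[which.max(d$conc_ann)],
      peak_time_elisa = d$time_h[which.max(d$conc_elisa)])
  }))
  rownames(by_group) <- NULL
  overall_r <- if (stats::sd(tab$conc_ann) > 0 &&
                   stats::sd(tab$conc_elisa) > 0) {
    stats::cor(tab$conc_ann, tab$conc_elisa)
  } else NA_real_
  rownames(tab) <- NULL
  list(table = tab, by_group = by_group, overall_r = overall_r)
}
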