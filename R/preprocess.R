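# Spectral preprocessing: normalization, averaging, band statistics.

#' Normalize every spectrum in a set
#'
#' Methods: `"vector"` divides each spectrum by its Euclidean norm (the
#' common default in Raman chemometrics), `"max"` by its maximum intensity,
#' `"area"` by its trapezoidal integral over the wavenumber grid. Metadata
#' are preserved; all methods are idempotent.
#'
#' @param x A [spectrum_set()].
#' @param method Normalization method.
#' @return A normalized `spectrum_set`.
#' @export
normalize_spectra <- function(x, method = c("vector", "max", "area")) {
  method <- match.arg(method)
  m <- x$intensities
  denom <- switch(method,
    vector = sqrt(rowSums(m^2)),
    max = apply(m, 1, max),
    area = {
      dw <- diff(x$wavenumbers)
      as.numeric((m[, -ncol(m), drop = FALSE] +
                  m[, -1, drop = FALSE]) %*% dw) / 2
    })
  bad <- which(denom == 0 | !is.finite(denom))
  if (length(bad)) {
    stop("cannot normalize degenerate (all-zero) spectrum: ",
         paste(x$metadata$spectrum_id[bad], collapse = ", "))
  }
  out <- x
  out$intensities <- m / denom
  out$normalization <- method
  out
}

#' Average spectra over metadata groups
#'
#' Computes the channel-wise arithmetic mean spectrum for every combination
#' of the grouping columns. The number of averaged replicates is recorded in
#' the `n_averaged` metadata column, and numeric metadata (time,
#' concentrations) are averaged alongside.
#'
#' @param x A [spectrum_set()].
#' @param by Character vector of metadata column names to group by.
#' @return A `spectrum_set` with one spectrum per group combination.
#' @export
average_spectra <- function(x, by = "group") {
  if (!all(by %in% names(x$metadata))) {
    stop("grouping columns not found in metadata: ",
         paste(setdiff(by, names(x$metadata)), collapse = ", "))
  }
  key <- interaction(x$metadata[by], drop = TRUE, sep = "|")
  if (any(table(key) == 0)) stop("empty group")
  idx <- split(seq_len(nrow(x$intensities)), key)
  mean_rows <- t(vapply(idx, function(i) {
    colMeans(x$intensities[i, , drop = FALSE])
  }, numeric(ncol(x$intensities))))
  md <- do.call(rbind, lapply(names(idx), function(k) {
    i <- idx[[k]]
    data.frame(
      spectrum_id = k,
      group = if ("group" %in% by) x$metadata$group[i[1]] else NA_character_,
      time_h = mean(x$metadata$time_h[i]),
      gh_ng_ml = mean(x$metadata$gh_ng_ml[i]),
      te_ng_ml = mean(x$metadata$te_ng_ml[i]),
      n_averaged = length(i))
  }))
  spectrum_set(x$wavenumbers, mean_rows, md)
}

#' Band intensity of each spectrum
#'
#' The intensity of a band is taken as the maximum within
#' `center +/- half_window`, which is robust to the few-cm^-1 drift of band
#' maxima between groups.
#'
#' @param x A [spectrum_set()].
#' @param center Band center, cm^-1 (must lie on the grid range).
#' @param half_window Half-width of the search window, cm^-1 (at least one
#'   grid step).
#' @return Named numeric vector, one intensity per spectrum.
#' @export
band_intensity <- function(x, center, half_window = 10) {
  wn <- x$wavenumbers
  step <- min(diff(wn))
  if (center < min(wn) || center > max(wn)) {
    stop("band center ", center, " cm^-1 lies outside the grid")
  }
  if (half_window < step) stop("half_window must be >= the grid step")
  sel <- which(wn >= center - half_window & wn <= center + half_window)
  if (!length(sel)) stop("window contains no grid points")
  out <- apply(x$intensities[, sel, drop = FALSE], 1, max)
  names(out) <- x$metadata$spectrum_id
  out
}

#' Descriptive statistics and one-way ANOVA of band intensities
#'
#' For each band center, extracts [band_intensity()] per spectrum, then
#' reports group means, the pooled (within-group) standard deviation and
#' variance, and the fixed-effects one-way ANOVA F statistic with its
#' p-value across groups.
#'
#' @param x A [spectrum_set()].
#' @param centers Band centers, cm^-1.
#' @param group_key Metadata column defining the groups (>= 2 groups with
#'   >= 2 spectra each).
#' @param half_window Passed to [band_intensity()].
#' @return Long-format data frame with columns
#'   `band_center, group, mean, sd, variance, F, p`; `sd`/`variance` are the
#'   pooled values and `F`/`p` the ANOVA results, repeated across the group
#'   rows of each band.
#' @export
band_statistics <- function(x, centers, group_key = "group",
                            half_window = 10) {
  g <- factor(x$metadata[[group_key]])
  if (nlevels(g) < 2) stop("ANOVA needs at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 spectra")
  out <- lapply(centers, function(ct) {
    y <- band_intensity(x, ct, half_window)
    fit <- stats::lm(y ~ g)
    an <- stats::anova(fit)
    pooled_var <- an["Residuals", "Mean Sq"]
    data.frame(
      band_center = ct,
      group = levels(g),
      mean = as.numeric(tapply(y, g, mean)),
      sd = sqrt(pooled_var),
      variance = pooled_var,
      F = an["g", "F value"],
      p = an["g", "Pr(>F)"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
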