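# Principal-component model of a spectrum set.

#' Fit a principal-component model to spectra
#'
#' Singular-value decomposition of the column-mean-centered intensity matrix
#' (via [stats::prcomp]; no variance scaling, since all channels share
#' intensity units). Explained-variance ratios are the component variances
#' divided by the total variance of the data. A deterministic sign
#' convention is applied: each loading's largest-magnitude element is made
#' positive, so serialized models and tests are reproducible.
#'
#' @param x A [spectrum_set()].
#' @param n_components Number of components to retain
#'   (<= min(n_spectra - 1, n_channels)).
#' @return An object of class `spectral_pca`: list with `wavenumbers`,
#'   `mean_spectrum`, `loadings` (components x channels, orthonormal rows),
#'   `explained_variance_ratio` and `total_variance`.
#' @export
#' @examples
#' cfg <- generator_config(grid_step = 16)
#' cal <- simulate_calibration_set(cfg, "gh", n_concentrations = 5,
#'                                 n_replicates = 4, seed = 1)
#' p <- fit_spectral_pca(normalize_spectra(cal), n_components = 3)
#' p$explained_variance_ratio
fit_spectral_pca <- function(x, n_components = 6) {
  m <- x$intensities
  if (nrow(m) < 2) stop("PCA needs at least 2 spectra")
  kmax <- min(nrow(m) - 1, ncol(m))
  if (n_components < 1 || n_components > kmax) {
    stop("n_components must be between 1 and ", kmax)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  load <- t(pc$rotation[, seq_len(n_components), drop = FALSE])
  # sign convention: largest |element| of each loading is positive
  for (i in seq_len(nrow(load))) {
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) load[i, ] <- -load[i, ]
  }
  rownames(load) <- paste0("PC", seq_len(n_components))
  structure(
    list(wavenumbers = x$wavenumbers,
         mean_spectrum = as.numeric(pc$center),
         loadings = load,
         explained_variance_ratio = ratios[seq_len(n_components)],
         total_variance = sum(pc$sdev^2)),
    class = "spectral_pca"
  )
}

#' @export
print.spectral_pca <- function(x, ...) {
  k <- nrow(x$loadings)
  cat("<spectral_pca> ", k, " components over ", length(x$wavenumbers),
      " channels\n", sep = "")
  cat("  explained variance:",
      paste0(sprintf("%.1f", 100 * x$explained_variance_ratio), "%",
             collapse = ", "),
      sprintf(" (cumulative %.1f%%)\n",
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project spectra onto a fitted principal-component model
#'
#' Scores are `(intensities - mean_spectrum) %*% t(loadings)`.
#'
#' @param object A [fit_spectral_pca()] model.
#' @param newdata A [spectrum_set()] on the model's wavenumber grid, or an
#'   intensity matrix with matching channel count.
#' @param ... Ignored.
#' @return Score matrix (spectra x components).
#' @export
predict.spectral_pca <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "spectrum_set")) {
    if (!isTRUE(all.equal(newdata$wavenumbers, object$wavenumbers))) {
      stop("wavenumber grid of `newdata` does not match the PCA model")
    }
    newdata$intensities
  } else {
    as.matrix(newdata)
  }
  if (ncol(m) != length(object$mean_spectrum)) {
    stop("channel count mismatch: spectra have ", ncol(m),
         " channels, model has ", length(object$mean_spectrum))
  }
  sc <- sweep(m, 2, object$mean_spectrum) %*% t(object$loadings)
  colnames(sc) <- rownames(object$loadings)
  sc
}

#' Band positions driving a principal component
#'
#' Finds local extrema of the absolute loading of one component and ranks
#' them by magnitude; these wavenumbers identify the bands responsible for
#' score-space segregation. Ties are broken toward the lower wavenumber.
#'
#' @param object A [fit_spectral_pca()] model.
#' @param component Component index.
#' @param top_k Number of peaks to return; if fewer extrema exist, all are
#'   returned with a warning and `attr(, "truncated") = TRUE`.
#' @return Data frame `wavenumber`, `loading` ordered by |loading|.
#' @export
loading_peaks <- function(object, component = 1, top_k = 5) {
  if (component < 1 || component > nrow(object$loadings)) {
    stop("component out of range")
  }
  a <- abs(object$loadings[component, ])
  n <- length(a)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1) a[i - 1] else -Inf
    right <- if (i < n) a[i + 1] else -Inf
    is_peak[i] <- a[i] > 0 && a[i] > left && a[i] >= right
  }
  idx <- which(is_peak)
  # rank by magnitude, ties toward lower wavenumber
  idx <- idx[order(-a[idx], object$wavenumbers[idx])]
  truncated <- FALSE
  if (length(idx) < top_k) {
    warning("only ", length(idx), " loading extrema found (top_k = ",
            top_k, "); returning all")
    truncated <- TRUE
  } else {
    idx <- idx[seq_len(top_k)]
  }
  out <- data.frame(wavenumber = object$wavenumbers[idx],
                    loading = object$loadings[component, idx])
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}

#' Serialize / restore a principal-component model as JSON
#'
#' @param object A `spectral_pca` model.
#' @param file Path of the JSON file.
#' @return `write_spectral_pca` returns `object` invisibly;
#'   `read_spectral_pca` returns the restored model.
#' @export
write_spectral_pca <- function(object, file) {
  jsonlite::write_json(
    list(wavenumbers = object$wavenumbers,
         mean_spectrum = object$mean_spectrum,
         loadings = object$loadings,
         explained_variance_ratio = object$explained_variance_ratio,
         total_variance = object$total_variance),
    file, digits = NA, auto_unbox = TRUE)
  invisible(object)
}

#' @rdname write_spectral_pca
#' @export
read_spectral_pca <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  load <- as.matrix(x$loadings)
  rownames(load) <- paste0("PC", seq_len(nrow(load)))
  structure(
    list(wavenumbers = as.numeric(x$wavenumbers),
         mean_spectrum = as.numeric(x$mean_spectrum),
         loadings = load,
         explained_variance_ratio = as.numeric(x$explained_variance_ratio),
         total_variance = as.numeric(x$total_variance)),
    class = "spectral_pca")
}
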