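#' Spectrum set container
#'
#' A `spectrum_set` holds a collection of Raman spectra that share one
#' wavenumber grid, together with per-spectrum metadata (group label,
#' sampling time and the known hormone concentrations, where applicable).
#' Rows of the intensity matrix are spectra, columns are spectral channels.
#'
#' @param wavenumbers Strictly increasing numeric vector, in cm^-1.
#' @param intensities Numeric matrix, one row per spectrum; `ncol` must equal
#'   `length(wavenumbers)`.
#' @param metadata Data frame with one row per spectrum. Must contain a
#'   `spectrum_id` column with unique values; the columns `group`, `time_h`,
#'   `gh_ng_ml` and `te_ng_ml` are added (as `NA`/0) when absent.
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `wavenumbers`, `intensities` and `metadata`.
#' @export
#' @examples
#' wn <- seq(400, 500, by = 2)
#' x <- matrix(rnorm(2 * length(wn), 10), nrow = 2)
#' s <- spectrum_set(wn, x, data.frame(spectrum_id = c("a", "b")))
#' s
spectrum_set <- function(wavenumbers, intensities, metadata) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (any(diff(wavenumbers) <= 0)) {
    stop("`wavenumbers` must be strictly increasing")
  }
  if (ncol(intensities) != length(wavenumbers)) {
    stop("ncol(intensities) [", ncol(intensities),
         "] must equal length(wavenumbers) [", length(wavenumbers), "]")
  }
  metadata <- as.data.frame(metadata)
  if (is.null(metadata$spectrum_id)) {
    stop("metadata must contain a `spectrum_id` column")
  }
  metadata$spectrum_id <- as.character(metadata$spectrum_id)
  if (anyDuplicated(metadata$spectrum_id)) stop("spectrum ids must be unique")
  if (nrow(metadata) != nrow(intensities)) {
    stop("metadata must have one row per spectrum")
  }
  if (is.null(metadata$group)) metadata$group <- NA_character_
  if (is.null(metadata$time_h)) metadata$time_h <- NA_real_
  if (is.null(metadata$gh_ng_ml)) metadata$gh_ng_ml <- 0
  if (is.null(metadata$te_ng_ml)) metadata$te_ng_ml <- 0
  conc <- c(metadata$gh_ng_ml, metadata$te_ng_ml)
  if (any(!is.na(conc) & conc < 0)) stop("concentrations must be non-negative")
  rownames(intensities) <- metadata$spectrum_id
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         metadata = metadata),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$intensities), " spectra x ",
      length(x$wavenumbers), " channels (",
      min(x$wavenumbers), "-", max(x$wavenumbers), " cm^-1)\n", sep = "")
  grp <- table(x$metadata$group, useNA = "ifany")
  if (length(grp)) {
    cat("  groups: ",
        paste(sprintf("%s (%d)", names(grp), as.integer(grp)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Subset a spectrum set by spectrum
#'
#' @param x A [spectrum_set()].
#' @param i Row index (integer, logical or spectrum id character vector).
#' @param ... Ignored.
#' @return A `spectrum_set` containing the selected spectra.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$metadata$spectrum_id)
  md <- x$metadata[i, , drop = FALSE]
  rownames(md) <- NULL
  spectrum_set(x$wavenumbers, x$intensities[i, , drop = FALSE], md)
}

#' Number of spectra in a set
#' @param x A [spectrum_set()].
#' @return Integer count of spectra.
#' @export
n_spectra <- function(x) nrow(x$intensities)

#' Combine spectrum sets that share a wavenumber grid
#' @param ... `spectrum_set` objects on identical grids.
#' @return A single combined `spectrum_set`.
#' @export
rbind_spectra <- function(...) {
  sets <- list(...)
  wn <- sets[[1]]$wavenumbers
  for (s in sets[-1]) {
    if (!isTRUE(all.equal(wn, s$wavenumbers))) {
      stop("all sets must share the same wavenumber grid")
    }
  }
  spectrum_set(
    wn,
    do.call(rbind, lapply(sets, `[[`, "intensities")),
    do.call(rbind, lapply(sets, `[[`, "metadata"))
  )
}

#' Write / read the spectra + metadata CSV dialect
#'
#' Spectra are stored as a wide CSV whose first column is `wavenumber_cm1`
#' and remaining columns are one intensity column per spectrum id; metadata
#' as a CSV with columns `spectrum_id,group,time_h,gh_ng_ml,te_ng_ml`.
#'
#' @param x A [spectrum_set()].
#' @param spectra_file,metadata_file Paths of the two CSV files.
#' @return `write_spectrum_set` returns `x` invisibly; `read_spectrum_set`
#'   returns a `spectrum_set`.
#' @export
write_spectrum_set <- function(x, spectra_file, metadata_file) {
  wide <- data.frame(wavenumber_cm1 = x$wavenumbers,
                     t(x$intensities), check.names = FALSE)
  utils::write.csv(wide, spectra_file, row.names = FALSE)
  utils::write.csv(
    x$metadata[, c("spectrum_id", "group", "time_h", "gh_ng_ml", "te_ng_ml")],
    metadata_file, row.names = FALSE)
  invisible(x)
}

#' @rdname write_spectrum_set
#' @export
read_spectrum_set <- function(spectra_file, metadata_file) {
  wide <- utils::read.csv(spectra_file, check.names = FALSE)
  md <- utils::read.csv(metadata_file, stringsAsFactors = FALSE)
  wn <- wide[[1]]
  mat <- t(as.matrix(wide[, -1, drop = FALSE]))
  ids <- colnames(wide)[-1]
  md <- md[match(ids, md$spectrum_id), , drop = FALSE]
  rownames(md) <- NULL
  spectrum_set(wn, mat, md)
}
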