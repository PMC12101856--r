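# Synthetic blood-SERS spectra and experiment designs.

# Evaluate set.seed-dependent code without clobbering the caller's RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Saturating concentration response
#'
#' f(C) = C / (C + K): the fractional occupancy-style response that links a
#' hormone concentration to the relative intensity gain of its sensitive
#' bands. It is 0 at C = 0, 1/2 at C = K and tends to 1 as C grows, the
#' saturation behaviour expected of adsorption-driven SERS intensities.
#'
#' @param conc Concentration(s), ng/ml.
#' @param K Saturation constant, ng/ml.
#' @return Dimensionless response in [0, 1).
#' @export
saturation_response <- function(conc, K) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  conc / (conc + K)
}

# Unit-height Lorentzian with half-width at half-maximum `width`.
lorentzian <- function(wn, center, width) {
  1 / (1 + ((wn - center) / width)^2)
}

baseline_profile <- function(config, wn = config_grid(config)) {
  xx <- 2 * (wn - (config$grid_min + config$grid_max) / 2) /
    (config$grid_max - config$grid_min)
  co <- config$baseline_coefficients
  out <- numeric(length(wn))
  for (j in seq_along(co)) out <- out + co[j] * xx^(j - 1)
  out
}

#' Noise-free synthetic SERS spectrum
#'
#' Evaluates the deterministic band-sum model: a sum of unit-height
#' Lorentzians scaled by `base_amplitude * (1 + s_gh * f(gh) + s_te * f(te))`
#' plus a smooth polynomial baseline, where f is the saturating response
#' [saturation_response()].
#'
#' @param config A [generator_config()].
#' @param gh_conc,te_conc Hormone concentrations, ng/ml (non-negative).
#' @return Numeric intensity vector over [config_grid()].
#' @export
clean_spectrum <- function(config, gh_conc = 0, te_conc = 0) {
  if (gh_conc < 0 || te_conc < 0) stop("concentration must be non-negative")
  wn <- config_grid(config)
  fg <- saturation_response(gh_conc, config$saturation_K)
  ft <- saturation_response(te_conc, config$saturation_K)
  out <- baseline_profile(config, wn)
  bt <- config$band_table
  for (b in seq_len(nrow(bt))) {
    amp <- bt$base_amplitude[b] *
      (1 + bt$gh_sensitivity[b] * fg + bt$te_sensitivity[b] * ft)
    out <- out + amp * lorentzian(wn, bt$center[b], bt$width[b])
  }
  out
}

#' Simulate one noisy SERS spectrum
#'
#' Applies a per-spectrum multiplicative factor `m ~ N(1, jitter_sd)` to the
#' clean band-plus-baseline profile, then adds per-channel Gaussian noise
#' with standard deviation `additive_noise_sd * max(clean)`. Intensities are
#' clipped at zero. Uses the current RNG stream; seed the caller (or use the
#' higher-level `simulate_*` functions, which take a `seed` argument).
#'
#' @inheritParams clean_spectrum
#' @return Numeric intensity vector over [config_grid()].
#' @export
simulate_spectrum <- function(config, gh_conc = 0, te_conc = 0) {
  clean <- clean_spectrum(config, gh_conc, te_conc)
  m <- max(stats::rnorm(1, 1, config$multiplicative_jitter_sd), 0)
  eps <- stats::rnorm(length(clean), 0, config$additive_noise_sd * max(clean))
  pmax(m * clean + eps, 0)
}

#' Simulate a calibration set of spiked-blood spectra
#'
#' Generates `n_concentrations` log-spaced concentration levels between
#' `conc_min` and `conc_max` (inclusive) for one hormone, with
#' `n_replicates` noisy spectra per level. The non-varied hormone is held
#' at its endogenous blood baseline (`background`), since calibration
#' samples are blood matrix spiked with one analyte. The defaults
#' reproduce a ~900-spectrum calibration design over 0.01-60 ng/ml.
#'
#' @param config A [generator_config()].
#' @param hormone `"gh"` or `"te"` — which hormone is varied.
#' @param n_concentrations Number of levels (>= 2).
#' @param conc_min,conc_max Level range, ng/ml; `conc_min` must be positive
#'   (log spacing) and strictly less than `conc_max`.
#' @param n_replicates Spectra per level.
#' @param seed Integer seed; the result is fully reproducible from it.
#' @param background Named vector `c(gh = , te = )` of endogenous
#'   concentrations (ng/ml) used for the hormone that is not varied.
#' @return A [spectrum_set()] whose metadata records the true
#'   concentrations of every spectrum (`group = "calibration"`).
#' @export
#' @examples
#' cfg <- generator_config(grid_step = 16)  # coarse grid for a quick look
#' cal <- simulate_calibration_set(cfg, "gh", n_concentrations = 4,
#'                                 n_replicates = 2, seed = 1)
#' cal$metadata
simulate_calibration_set <- function(config, hormone = c("gh", "te"),
                                     n_concentrations = 30,
                                     conc_min = 0.01, conc_max = 60,
                                     n_replicates = 30, seed = 42,
                                     background = c(gh = 3, te = 2)) {
  hormone <- match.arg(hormone)
  if (n_concentrations < 2) stop("n_concentrations must be >= 2")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (conc_min <= 0) stop("conc_min must be > 0 (levels are log-spaced)")
  if (conc_min >= conc_max) stop("conc_min must be < conc_max")
  levels <- exp(seq(log(conc_min), log(conc_max),
                    length.out = n_concentrations))
  wn <- config_grid(config)
  n <- n_concentrations * n_replicates
  intens <- matrix(0, nrow = n, ncol = length(wn))
  gh <- te <- numeric(n)
  ids <- character(n)
  with_seed(seed, {
    row <- 0L
    for (l in seq_along(levels)) {
      for (r in seq_len(n_replicates)) {
        row <- row + 1L
        g <- if (hormone == "gh") levels[l] else unname(background["gh"])
        t <- if (hormone == "te") levels[l] else unname(background["te"])
        intens[row, ] <- simulate_spectrum(config, g, t)
        gh[row] <- g; te[row] <- t
        ids[row] <- sprintf("%s_cal_L%02d_R%02d", hormone, l, r)
      }
    }
  })
  spectrum_set(wn, intens, data.frame(
    spectrum_id = ids, group = "calibration", time_h = NA_real_,
    gh_ng_ml = gh, te_ng_ml = te))
}

#' Bateman pharmacokinetic profile
#'
#' One-compartment model with first-order absorption and elimination:
#' `C(t) = baseline + A * (exp(-ke * t) - exp(-ka * t))`.
#'
#' @param t Time(s), hours.
#' @param baseline Endogenous baseline concentration, ng/ml.
#' @param A Amplitude, ng/ml.
#' @param ka,kel Absorption and elimination rate constants, 1/h (`ka > kel`).
#' @return Concentration(s), ng/ml.
#' @export
bateman <- function(t, baseline, A, ka, kel) {
  baseline + A * (exp(-kel * t) - exp(-ka * t))
}

#' @rdname bateman
#' @details `bateman_peak_time` gives the time of the profile maximum,
#'   `log(ka / kel) / (ka - kel)`.
#' @export
bateman_peak_time <- function(ka, kel) log(ka / kel) / (ka - kel)

# Solve (ka, kel, A) so that the Bateman profile peaks at `peak` ng/ml at
# t = t_peak and has returned close to baseline by t_return. The rate ratio
# r = ka/kel is found by root search on the residual concentration at
# t_return (target: return_frac of the baseline excess scale).
solve_bateman <- function(baseline, peak, t_peak, t_return = 24,
                          return_frac = 0.05) {
  target <- return_frac * max(baseline, 0.1 * (peak - baseline))
  resid_at <- function(r) {
    kel <- log(r) / (t_peak * (r - 1))
    ka <- r * kel
    A <- (peak - baseline) / (exp(-kel * t_peak) - exp(-ka * t_peak))
    A * (exp(-kel * t_return) - exp(-ka * t_return)) - target
  }
  lo <- 1.0001; hi <- 1000
  r <- if (resid_at(lo) > 0) lo
       else if (resid_at(hi) < 0) hi
       else stats::uniroot(resid_at, c(lo, hi), tol = 1e-10)$root
  kel <- log(r) / (t_peak * (r - 1))
  ka <- r * kel
  A <- (peak - baseline) / (exp(-kel * t_peak) - exp(-ka * t_peak))
  list(ka = ka, kel = kel, A = A)
}

#' Default pharmacokinetic settings per hormone
#'
#' GH: baseline 3 ng/ml, peak 44 ng/ml at 0.5 h. TE: baseline 2 ng/ml,
#' peak 30 ng/ml at 2 h (the TE peak height is a package default; only its
#' timing window is constrained by the in-vivo narrative).
#'
#' @param hormone `"gh"` or `"te"`.
#' @return List with `baseline`, `peak`, `t_peak`.
#' @export
pk_defaults <- function(hormone = c("gh", "te")) {
  hormone <- match.arg(hormone)
  if (hormone == "gh") list(baseline = 3, peak = 44, t_peak = 0.5)
  else list(baseline = 2, peak = 30, t_peak = 2)
}

#' Simulate a hormone concentration time-course
#'
#' For injected groups the profile is the Bateman form with rates solved so
#' that the maximum equals `peak` at `t_peak` and the concentration has
#' returned to within a few percent of baseline by 24 h; for
#' `group = "non_injected"` the profile is constant at baseline.
#'
#' @param group Group label; `"non_injected"` yields a flat profile.
#' @param times Sampling times, hours (default the in-vivo design
#'   0, 0.5, 2, 4, 8 and 24 h).
#' @param baseline,peak Concentrations, ng/ml (`peak >= baseline`).
#' @param t_peak Time of the maximum, hours (> 0).
#' @return An object of class `pk_profile`: list with `group`, `times`,
#'   `concentrations`, `baseline`, `peak` and the solved rate constants.
#' @export
#' @examples
#' simulate_pk_timecourse("gh")$concentrations
simulate_pk_timecourse <- function(group = "gh",
                                   times = c(0, 0.5, 2, 4, 8, 24),
                                   baseline = NULL, peak = NULL,
                                   t_peak = NULL) {
  defs <- if (group %in% c("gh", "te")) pk_defaults(group) else
    list(baseline = 0, peak = 0, t_peak = 1)
  if (is.null(baseline)) baseline <- defs$baseline
  if (is.null(peak)) peak <- defs$peak
  if (is.null(t_peak)) t_peak <- defs$t_peak
  if (any(times < 0)) stop("times must be non-negative")
  if (group == "non_injected" || peak == baseline) {
    prof <- list(group = group, times = times,
                 concentrations = rep(baseline, length(times)),
                 baseline = baseline, peak = baseline,
                 t_peak = NA_real_, ka = NA_real_, kel = NA_real_,
                 A = 0)
    class(prof) <- "pk_profile"
    return(prof)
  }
  if (peak < baseline) stop("peak must be >= baseline")
  if (t_peak <= 0) stop("t_peak must be > 0")
  p <- solve_bateman(baseline, peak, t_peak)
  prof <- list(group = group, times = times,
               concentrations = bateman(times, baseline, p$A, p$ka, p$kel),
               baseline = baseline, peak = peak, t_peak = t_peak,
               ka = p$ka, kel = p$kel, A = p$A)
  class(prof) <- "pk_profile"
  prof
}

#' @export
print.pk_profile <- function(x, ...) {
  cat("<pk_profile> group ", x$group, ": baseline ", x$baseline,
      " ng/ml", sep = "")
  if (!is.na(x$t_peak)) {
    cat(", peak ", x$peak, " ng/ml at ", x$t_peak, " h (ka = ",
        signif(x$ka, 3), ", kel = ", signif(x$kel, 3), " 1/h)", sep = "")
  }
  cat("\n")
  print(data.frame(time_h = x$times, conc_ng_ml = signif(x$concentrations, 4)))
  invisible(x)
}

#' Simulate the four-group in-vivo experiment
#'
#' Groups `non_injected`, `gh`, `te` and `gh_te` are sampled at the six
#' study times; each rat contributes one spectrum per time. Per rat, the
#' injected-hormone peak is multiplied by a lognormal factor
#' (`sdlog = rat_sdlog`) to emulate between-animal variation; endogenous
#' baselines (GH 3, TE 2 ng/ml) are present in every group. Rat factors are
#' drawn first (two per rat, GH then TE, groups in the order above), then
#' spectra in group/rat/time order, so metadata can be re-derived from the
#' seed.
#'
#' @param config A [generator_config()].
#' @param n_rats_per_group Rats per group (>= 1).
#' @param seed Integer seed.
#' @param times Sampling times, hours.
#' @param rat_sdlog Lognormal sdlog of the per-rat peak factor.
#' @return A [spectrum_set()] with complete metadata (144 spectra under the
#'   defaults: 4 groups x 6 rats x 6 times).
#' @export
simulate_group_experiment <- function(config, n_rats_per_group = 6, seed = 42,
                                      times = c(0, 0.5, 2, 4, 8, 24),
                                      rat_sdlog = 0.1) {
  if (n_rats_per_group < 1) stop("n_rats_per_group must be >= 1")
  groups <- c("non_injected", "gh", "te", "gh_te")
  wn <- config_grid(config)
  n <- length(groups) * n_rats_per_group * length(times)
  intens <- matrix(0, nrow = n, ncol = length(wn))
  md <- data.frame(spectrum_id = character(n), group = character(n),
                   time_h = numeric(n), gh_ng_ml = numeric(n),
                   te_ng_ml = numeric(n))
  gh0 <- pk_defaults("gh"); te0 <- pk_defaults("te")
  with_seed(seed, {
    factors <- array(stats::rlnorm(2 * n_rats_per_group * length(groups),
                                   0, rat_sdlog),
                     dim = c(2, n_rats_per_group, length(groups)))
    row <- 0L
    for (g in seq_along(groups)) {
      grp <- groups[g]
      for (rat in seq_len(n_rats_per_group)) {
        gh_prof <- if (grp %in% c("gh", "gh_te")) {
          simulate_pk_timecourse("gh", times, gh0$baseline,
                                 gh0$baseline +
                                   (gh0$peak - gh0$baseline) *
                                   factors[1, rat, g],
                                 gh0$t_peak)
        } else {
          simulate_pk_timecourse("non_injected", times,
                                 baseline = gh0$baseline)
        }
        te_prof <- if (grp %in% c("te", "gh_te")) {
          simulate_pk_timecourse("te", times, te0$baseline,
                                 te0$baseline +
                                   (te0$peak - te0$baseline) *
                                   factors[2, rat, g],
                                 te0$t_peak)
        } else {
          simulate_pk_timecourse("non_injected", times,
                                 baseline = te0$baseline)
        }
        for (ti in seq_along(times)) {
          row <- row + 1L
          ghc <- gh_prof$concentrations[ti]
          tec <- te_prof$concentrations[ti]
          intens[row, ] <- simulate_spectrum(config, ghc, tec)
          md$spectrum_id[row] <- sprintf("%s_rat%02d_t%g", grp, rat,
                                         times[ti])
          md$group[row] <- grp
          md$time_h[row] <- times[ti]
          md$gh_ng_ml[row] <- ghc
          md$te_ng_ml[row] <- tec
        }
      }
    }
  })
  spectrum_set(wn, intens, md)
}

#' Simulate ELISA standards for a hormone
#'
#' Optical densities are generated from a "true" standard curve — a rising
#' Boltzmann sigmoid for GH (sandwich-assay behaviour) and an exponential
#' decay for TE (competitive-assay behaviour) — plus Gaussian OD noise.
#'
#' @param hormone `"gh"` or `"te"`.
#' @param concentrations Standard concentrations, ng/ml.
#' @param od_noise_sd OD noise standard deviation (absorbance units) as a
#'   fraction of the OD span of the true curve.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Data frame `conc_ng_ml`, `od`, with the generating parameters in
#'   `attr(, "true_params")`.
#' @export
simulate_elisa_standards <- function(hormone = c("gh", "te"),
                                     concentrations = c(0, 0.75, 1.5, 3, 6,
                                                        12.5, 25, 50),
                                     od_noise_sd = 0.01, seed = NULL) {
  hormone <- match.arg(hormone)
  p <- elisa_true_params(hormone)
  od <- elisa_curve_value(hormone, p, concentrations)
  span <- abs(diff(range(elisa_curve_value(hormone, p,
                                           c(0, max(concentrations) * 2)))))
  od <- with_seed(seed,
                  od + stats::rnorm(length(od), 0, od_noise_sd * span))
  out <- data.frame(conc_ng_ml = concentrations, od = od)
  attr(out, "true_params") <- p
  out
}

elisa_true_params <- function(hormone) {
  if (hormone == "gh") {
    list(form = "boltzmann", A1 = 0.1, A2 = 2.2, x0 = 10, dx = 4)
  } else {
    list(form = "exp_decay", y0 = 0.15, A = 1.8, t = 8)
  }
}

elisa_curve_value <- function(hormone, p, conc) {
  if (hormone == "gh") {
    p$A2 + (p$A1 - p$A2) / (1 + exp((conc - p$x0) / p$dx))
  } else {
    p$y0 + p$A * exp(-conc / p$t)
  }
}
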