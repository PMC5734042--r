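#' Specific activity from a spectrophotometric slope
#'
#' Converts an absorbance slope (A/min) into a specific activity using the
#' Beer-Lambert relation: `activity = slope / (epsilon * path * enzyme)`,
#' in umol per minute per mg of enzyme. The NAD(P)H extinction coefficients
#' of the assay are 6.2 mM^-1 cm^-1 at 340 nm and 5.12 mM^-1 cm^-1 at
#' 355 nm; cofactor consumption is reported positive.
#'
#' @param slope_abs_per_min Absorbance change per minute (consumption
#'   positive).
#' @param epsilon_mM_cm Extinction coefficient (mM^-1 cm^-1), > 0.
#' @param path_cm Optical path length (cm), > 0.
#' @param enzyme_mg_per_ml Enzyme concentration in the assay (mg/ml), > 0.
#' @return Specific activity in umol min^-1 mg^-1.
#' @examples
#' specific_activity(0.062, 6.2, 1, 0.01)  # 1.0
#' @export
specific_activity <- function(slope_abs_per_min, epsilon_mM_cm = 6.2,
                              path_cm = 1, enzyme_mg_per_ml = 1) {
  if (epsilon_mM_cm <= 0 || path_cm <= 0) {
    stop("epsilon and path length must be positive", call. = FALSE)
  }
  if (any(enzyme_mg_per_ml <= 0)) {
    stop("enzyme concentration must be positive", call. = FALSE)
  }
  slope_abs_per_min / (epsilon_mM_cm * path_cm * enzyme_mg_per_ml)
}

#' Initial-rate dataset for saturation kinetics
#'
#' @param substrate Substrate name.
#' @param concentrations Substrate concentrations (uM), all > 0.
#' @param rates Initial rates (umol min^-1 mg^-1), same length.
#' @param cofactor Cofactor label (default `"NADPH"`).
#' @return Object of class `rate_dataset`.
#' @export
rate_dataset <- function(substrate, concentrations, rates,
                         cofactor = "NADPH") {
  concentrations <- as.numeric(concentrations)
  rates <- as.numeric(rates)
  if (length(concentrations) != length(rates)) {
    stop("concentrations and rates differ in length", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("substrate concentrations must be positive", call. = FALSE)
  }
  if (length(unique(concentrations)) < 4L) {
    stop("need at least 4 distinct concentrations to fit", call. = FALSE)
  }
  structure(list(substrate = substrate, concentrations = concentrations,
                 rates = rates, cofactor = cofactor),
            class = "rate_dataset")
}

#' Fit Michaelis-Menten parameters
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' \code{minpack.lm::nlsLM}) of `v = Vmax * S / (Km + S)`. Start values
#' follow the saturation geometry: `Vmax0 = max(v)` and `Km0` the
#' concentration whose rate is closest to `Vmax0 / 2`. Standard errors are
#' asymptotic, from the curvature of the least-squares surface at the
#' optimum.
#'
#' @param data A [rate_dataset] (or a data.frame with columns
#'   `concentration` and `rate`).
#' @return Object of class `mm_fit`: `vmax`, `vmax_se`, `km`, `km_se`,
#'   `rss`, `converged`, `iterations`, and the fitted `nls` object.
#' @export
fit_mm <- function(data) {
  if (is.data.frame(data)) {
    data <- rate_dataset("substrate", data$concentration, data$rate)
  }
  stopifnot(inherits(data, "rate_dataset"))
  S <- data$concentrations
  v <- data$rates
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(S)
  fit <- NULL
  converged <- FALSE
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(vmax = vmax0, vmax_se = NA_real_, km = km0, km_se = NA_real_,
                rss = sum((v - vmax0 * S / (km0 + S))^2),
                converged = FALSE, iterations = NA_integer_, fit = NULL,
                substrate = data$substrate)
    class(out) <- "mm_fit"
    return(out)
  }
  converged <- isTRUE(fit$convInfo$isConv)
  co <- summary(fit)$coefficients
  out <- list(vmax = co["Vmax", "Estimate"], vmax_se = co["Vmax", "Std. Error"],
              km = co["Km", "Estimate"], km_se = co["Km", "Std. Error"],
              rss = sum(stats::residuals(fit)^2),
              converged = converged,
              iterations = fit$convInfo$finIter,
              fit = fit, substrate = data$substrate)
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %s: Vmax %.3g +/- %.2g, Km %.3g +/- %.2g (%s, %d iter)\n",
              x$substrate, x$vmax, x$vmax_se, x$km, x$km_se,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Predicted Michaelis-Menten rate
#'
#' @param fit An `mm_fit`.
#' @param S Substrate concentrations.
#' @return Predicted rates `Vmax * S / (Km + S)`.
#' @export
predict_mm <- function(fit, S) {
  stopifnot(inherits(fit, "mm_fit"))
  fit$vmax * S / (fit$km + S)
}

#' Activity profile relative to a reference enzyme
#'
#' Expresses a panel of specific activities as a percentage of a reference
#' activity (the convention used for substrate-spectrum bar charts where the
#' reference substrate is set to 100%).
#'
#' @param activities Named numeric vector or data.frame with columns
#'   `substrate` and `activity` (optionally `sd`).
#' @param reference_activity Positive reference activity.
#' @return data.frame with columns `substrate`, `activity`, `sd`,
#'   `percent_of_reference`.
#' @export
profile_vs_reference <- function(activities, reference_activity) {
  if (reference_activity <= 0) {
    stop("reference activity must be positive", call. = FALSE)
  }
  if (!is.data.frame(activities)) {
    activities <- data.frame(substrate = names(activities),
                             activity = as.numeric(activities),
                             stringsAsFactors = FALSE)
  }
  if (is.null(activities$sd)) activities$sd <- NA_real_
  if (any(activities$activity < 0)) {
    stop("activities must be non-negative", call. = FALSE)
  }
  activities$percent_of_reference <-
    100 * activities$activity / reference_activity
  activities
}

#' Turnover number from Vmax
#'
#' `kcat = Vmax * MW / 1000` converts a specific activity in
#' umol min^-1 mg^-1 into a per-enzyme turnover in min^-1 given the molar
#' mass in g/mol (umol product per umol enzyme per minute).
#'
#' @param vmax Specific activity (umol min^-1 mg^-1), > 0.
#' @param molar_mass_g_per_mol Enzyme molar mass (g/mol), > 0.
#' @return kcat in min^-1.
#' @examples
#' kcat_from_vmax(1, 34000)  # 34, a typical ~34 kDa aldo-keto reductase
#' @export
kcat_from_vmax <- function(vmax, molar_mass_g_per_mol) {
  if (any(vmax <= 0) || any(molar_mass_g_per_mol <= 0)) {
    stop("vmax and molar mass must be positive", call. = FALSE)
  }
  vmax * molar_mass_g_per_mol / 1000
}

#' Inverse of [kcat_from_vmax()]
#' @param kcat Turnover number (min^-1), > 0.
#' @param molar_mass_g_per_mol Enzyme molar mass (g/mol), > 0.
#' @return Vmax in umol min^-1 mg^-1.
#' @export
vmax_from_kcat <- function(kcat, molar_mass_g_per_mol) {
  if (any(kcat <= 0) || any(molar_mass_g_per_mol <= 0)) {
    stop("kcat and molar mass must be positive", call. = FALSE)
  }
  kcat * 1000 / molar_mass_g_per_mol
}

#' Two-sample comparison against a blank control
#'
#' Two-tailed two-sample t test of sample rates against blank (control)
#' rates, equal-variance by default with a Welch option -- the convention
#' used to call activities significantly different from an empty-plasmid
#' control at P < 0.05.
#'
#' @param sample_rates Numeric vector, n >= 2.
#' @param blank_rates Numeric vector, n >= 2.
#' @param welch Use Welch's unequal-variance test.
#' @return List with `t`, `p`, `df`, `flagged` (degenerate variance with
#'   n < 3 in either group).
#' @export
compare_to_blank <- function(sample_rates, blank_rates, welch = FALSE) {
  if (length(sample_rates) < 2L || length(blank_rates) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (stats::var(sample_rates) == 0 && stats::var(blank_rates) == 0) {
    if (identical(mean(sample_rates), mean(blank_rates))) {
      return(list(t = 0, p = 1,
                  df = length(sample_rates) + length(blank_rates) - 2L,
                  flagged = FALSE))
    }
    return(list(t = Inf, p = 0,
                df = length(sample_rates) + length(blank_rates) - 2L,
                flagged = TRUE))
  }
  tt <- stats::t.test(sample_rates, blank_rates, var.equal = !welch,
                      alternative = "two.sided")
  flagged <- (length(sample_rates) < 3L || length(blank_rates) < 3L) &&
    (stats::var(sample_rates) == 0 || stats::var(blank_rates) == 0)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       flagged = flagged)
}
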