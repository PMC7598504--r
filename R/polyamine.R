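#' Polyamine free fractions
#'
#' Most cellular putrescine and spermidine is bound to nucleic acids, ATP and
#' phospholipids; only a fraction is free in solution. Estimates derived from
#' published affinity constants put the free fraction at ~40% for putrescine
#' and ~5% for spermidine; these are configured constants of the analysis,
#' not quantities the package computes. No default exists for spermine.
#'
#' @format Named numeric vector of fractions in `[0, 1]`.
#' @export
default_free_fractions <- c(putrescine = 0.40, spermidine = 0.05)

#' Serial dilution series for a standard mixture
#'
#' The calibration standard is a polyamine mixture (e.g. 20 mM putrescine,
#' 10 mM spermidine, 10 mM spermine) serially diluted in `fold`-fold
#' increments: level `k` holds `top / fold^k`.
#'
#' @param top_concentrations Named numeric vector of top concentrations (mM),
#'   one per species, all `> 0`.
#' @param n_levels Number of dilution levels, `>= 2`.
#' @param fold Dilution factor per level, `> 1` (default 4).
#' @return A data.frame `species`, `level` (0-based), `concentration_mM`.
#' @examples
#' build_dilution_series(c(putrescine = 20), n_levels = 3)
#' @export
build_dilution_series <- function(top_concentrations, n_levels, fold = 4) {
  if (!is.numeric(top_concentrations) || any(top_concentrations <= 0)) {
    stop_tq("topoquant_invalid_parameter", "top concentrations must be > 0")
  }
  if (is.null(names(top_concentrations))) {
    stop_tq("topoquant_invalid_parameter", "top_concentrations must be named by species")
  }
  if (!is_count(n_levels) || n_levels < 2) {
    stop_tq("topoquant_invalid_parameter", "n_levels must be an integer >= 2")
  }
  if (!is_num1(fold) || fold <= 1) {
    stop_tq("topoquant_invalid_parameter", "fold must be > 1")
  }
  lev <- 0:(n_levels - 1)
  do.call(rbind, lapply(names(top_concentrations), function(sp) {
    data.frame(species = sp, level = lev,
               concentration_mM = top_concentrations[[sp]] / fold^lev,
               stringsAsFactors = FALSE)
  }))
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares line `response = slope * concentration + intercept`
#' through the calibration points (UV peak area versus concentration). A
#' nonpositive slope is refused as a calibration failure.
#'
#' @param points Data.frame with columns `concentration_mM` and `response`,
#'   at least 3 distinct concentrations.
#' @param species Species label carried on the curve.
#' @return An object of class `"standard_curve"`: `species`, `slope`,
#'   `intercept`, `r_squared`, `points`.
#' @export
fit_standard_curve <- function(points, species = "polyamine") {
  if (!is.data.frame(points) || !all(c("concentration_mM", "response") %in% names(points))) {
    stop_tq("topoquant_invalid_parameter", "points needs columns concentration_mM and response")
  }
  if (length(unique(points$concentration_mM)) < 3L) {
    stop_tq("topoquant_insufficient_calibration_error",
            "standard curve needs >= 3 distinct concentrations")
  }
  if (any(points$concentration_mM < 0)) {
    stop_tq("topoquant_invalid_parameter", "concentrations must be nonnegative")
  }
  fit <- stats::lm(response ~ concentration_mM, data = points)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop_tq("topoquant_calibration_failure_error",
            sprintf("calibration failure for %s: nonpositive slope", species))
  }
  ss_tot <- sum((points$response - mean(points$response))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  structure(list(species = species, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = points),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve (%s): response = %.4g * mM + %.4g, R^2 = %.4f (%d points)\n",
              x$species, x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Invert a standard curve for a sample response
#'
#' `(response - intercept) / slope`, floored at 0 (with a warning) when the
#' response falls below the intercept.
#'
#' @param response Measured response (vectorized).
#' @param curve A [fit_standard_curve()] object.
#' @return Extract concentration(s) in mM.
#' @export
quantify_sample <- function(response, curve) {
  if (!inherits(curve, "standard_curve")) {
    stop_tq("topoquant_invalid_parameter", "curve must be a standard_curve")
  }
  conc <- (response - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warn_tq("topoquant_censor_warning",
            "response below calibration intercept; concentration floored at 0 mM")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Intracellular concentration from extract amount, CFU and cell volume
#'
#' Converts a measured amount of polyamine to its concentration inside the
#' cells it came from: `amount_mol / (cfu * cell_volume_um3 * 1e-15 L)`,
#' reported in mM. 1 um^3 = 1e-15 L.
#'
#' @param amount_mol Amount in the extract, moles, `> 0`.
#' @param cfu Colony-forming units the extract derives from, `> 0`.
#' @param cell_volume_um3 Mean cell volume in cubic micrometers (default 4,
#'   from phase microscopy of the assayed strains).
#' @return Intracellular concentration in mM.
#' @examples
#' intracellular_concentration(8e-8, cfu = 1e9)  # 20 mM
#' @export
intracellular_concentration <- function(amount_mol, cfu, cell_volume_um3 = 4) {
  if (!is_num1(amount_mol) || amount_mol <= 0) stop_tq("topoquant_invalid_parameter", "amount_mol must be > 0")
  if (!is_num1(cfu) || cfu <= 0) stop_tq("topoquant_invalid_parameter", "cfu must be > 0")
  if (!is_num1(cell_volume_um3) || cell_volume_um3 <= 0) {
    stop_tq("topoquant_invalid_parameter", "cell_volume_um3 must be > 0")
  }
  molar <- amount_mol / (cfu * cell_volume_um3 * 1e-15)
  1000 * molar
}

#' Free polyamine concentration
#'
#' Applies the configured free fraction for a species to its total
#' intracellular concentration.
#'
#' @param total_mM Total concentration in mM, `>= 0` (vectorized).
#' @param species Species name; must have a configured fraction.
#' @param fractions Named fractions; defaults to [default_free_fractions].
#' @return Free concentration in mM.
#' @examples
#' free_concentration(20, "putrescine")   # 8
#' free_concentration(4.5, "spermidine")  # 0.225
#' @export
free_concentration <- function(total_mM, species,
                               fractions = default_free_fractions) {
  if (any(total_mM < 0)) stop_tq("topoquant_invalid_parameter", "total_mM must be >= 0")
  if (!is.character(species) || length(species) != 1L || !(species %in% names(fractions))) {
    stop_tq("topoquant_missing_parameter_error",
            sprintf("no free fraction configured for species '%s'", as.character(species)[1]))
  }
  fractions[[species]] * total_mM
}

#' Apply an assay detection limit
#'
#' Concentrations below the limit of detection are flagged censored and
#' labeled `"<lod"`; values at or above the limit pass through (the boundary
#' is inclusive).
#'
#' @param conc_mM Concentration(s) in mM.
#' @param lod_mM Detection limit in mM, `>= 0` (default 0.2).
#' @return A data.frame `conc_mM`, `censored`, `reported` (character, either
#'   the value or `"<lod"`).
#' @examples
#' apply_detection_limit(c(0.1, 0.2, 5))
#' @export
apply_detection_limit <- function(conc_mM, lod_mM = 0.2) {
  if (!is_num1(lod_mM) || lod_mM < 0) stop_tq("topoquant_invalid_parameter", "lod_mM must be >= 0")
  censored <- conc_mM < lod_mM
  data.frame(conc_mM = conc_mM, censored = censored,
             reported = ifelse(censored, sprintf("<%g mM", lod_mM),
                               sprintf("%.1f", conc_mM)),
             stringsAsFactors = FALSE)
}

#' Quantify polyamine samples against standard curves
#'
#' Table-level wrapper over the calibration steps: fits one standard curve
#' per species from the calibration table, inverts each sample response to
#' an extract concentration, converts to moles in the extract volume, then to
#' intracellular concentration via CFU and cell volume, applies the free
#' fraction where configured, and censors at the detection limit.
#'
#' @param standards Data.frame `species`, `concentration_mM`, `response`.
#' @param samples Data.frame `species`, `response`, `cfu`,
#'   `extract_volume_L`.
#' @param cell_volume_um3 Cell volume in um^3 (default 4).
#' @param lod_mM Detection limit in mM (default 0.2).
#' @param fractions Named free fractions; species without one get `NA` free
#'   concentration.
#' @return The samples data.frame augmented with `extract_mM`,
#'   `intracellular_mM`, `free_mM`, `censored`, `reported`.
#' @export
quantify_polyamines <- function(standards, samples, cell_volume_um3 = 4,
                                lod_mM = 0.2, fractions = default_free_fractions) {
  sp_tabs <- split(standards, standards$species)
  curves <- Map(fit_standard_curve, sp_tabs, names(sp_tabs))
  out <- samples
  out$extract_mM <- NA_real_
  out$intracellular_mM <- NA_real_
  out$free_mM <- NA_real_
  for (i in seq_len(nrow(out))) {
    sp <- out$species[i]
    if (is.null(curves[[sp]])) {
      stop_tq("topoquant_missing_parameter_error",
              sprintf("no standard curve for species '%s'", sp))
    }
    ext <- quantify_sample(out$response[i], curves[[sp]])
    out$extract_mM[i] <- ext
    amount_mol <- ext / 1000 * out$extract_volume_L[i]
    if (amount_mol > 0) {
      out$intracellular_mM[i] <- intracellular_concentration(
        amount_mol, out$cfu[i], cell_volume_um3)
    } else {
      out$intracellular_mM[i] <- 0
    }
    if (sp %in% names(fractions)) {
      out$free_mM[i] <- free_concentration(out$intracellular_mM[i], sp, fractions)
    }
  }
  cens <- apply_detection_limit(out$intracellular_mM, lod_mM)
  out$censored <- cens$censored
  out$reported <- cens$reported
  out
}
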