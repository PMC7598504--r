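#' Lane intensity profiles
#'
#' A lane profile is the digitized 1-D trace of one gel lane: intensity versus
#' migration position, with position 0 at the top of the gel (the wells) and
#' increasing downward.
#'
#' @param positions Strictly increasing numeric positions (pixels).
#' @param intensities Nonnegative intensities (arbitrary units), same length.
#' @param lane_id Lane label.
#' @return An object of class `"lane_profile"`.
#' @export
lane_profile <- function(positions, intensities, lane_id = "lane") {
  if (length(positions) != length(intensities)) {
    stop_tq("topoquant_invalid_parameter", "positions and intensities must have equal length")
  }
  if (length(positions) < 2L) stop_tq("topoquant_invalid_parameter", "profile needs >= 2 points")
  if (any(diff(positions) <= 0)) stop_tq("topoquant_invalid_parameter", "positions must be strictly increasing")
  if (any(intensities < 0)) stop_tq("topoquant_invalid_parameter", "intensities must be nonnegative")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 lane_id = as.character(lane_id)),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("Lane profile '%s': %d points, position %.0f-%.0f px, max intensity %.3g\n",
              x$lane_id, length(x$positions), min(x$positions), max(x$positions),
              max(x$intensities)))
  invisible(x)
}

#' Read and write lane profiles as two-column CSV
#'
#' The on-disk format is a CSV with header `position_px,intensity`.
#'
#' @param profile A [lane_profile()].
#' @param path File path.
#' @param lane_id Lane label for the profile read back.
#' @return `read_lane_profile()` returns a [lane_profile()];
#'   `write_lane_profile()` returns `path` invisibly.
#' @export
write_lane_profile <- function(profile, path) {
  utils::write.csv(data.frame(position_px = profile$positions,
                              intensity = profile$intensities),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lane_profile
#' @export
read_lane_profile <- function(path, lane_id = sub("\\.[^.]*$", "", basename(path))) {
  d <- utils::read.csv(path)
  if (!all(c("position_px", "intensity") %in% names(d))) {
    stop_tq("topoquant_parse_error", "lane profile CSV must have columns position_px, intensity")
  }
  lane_profile(d$position_px, d$intensity, lane_id = lane_id)
}

#' Extract a lane profile from a grayscale gel image
#'
#' Averages intensity across the width of a rectangular lane region. Row 0 is
#' the top of the image (the wells); positions in the returned profile are the
#' 0-based row indices of the region.
#'
#' @param image Numeric matrix of intensities (rows = migration axis).
#' @param cols Two-element integer vector, first and last column (1-based,
#'   inclusive) of the lane region; a single column is allowed.
#' @param rows Optional two-element row range; default all rows.
#' @param lane_id Lane label.
#' @return A [lane_profile()].
#' @export
extract_lane_profile <- function(image, cols, rows = NULL, lane_id = "lane") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_tq("topoquant_invalid_parameter", "image must be a numeric matrix")
  }
  cols <- as.integer(round(range(cols)))
  if (is.null(rows)) rows <- c(1L, nrow(image))
  rows <- as.integer(round(range(rows)))
  if (cols[1] < 1L || cols[2] > ncol(image) || rows[1] < 1L || rows[2] > nrow(image)) {
    stop_tq("topoquant_bounds_error", "region of interest outside image bounds")
  }
  block <- image[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  lane_profile(positions = (rows[1]:rows[2]) - 1L,
               intensities = rowMeans(block), lane_id = lane_id)
}

#' Subtract a smooth background from a lane profile
#'
#' Estimates background as a rolling minimum over `window_px` followed by a
#' rolling mean with the same window (both centered, shrinking at the ends),
#' subtracts it, and clips negative residuals at 0. With a window much wider
#' than a band, Gaussian peaks survive essentially intact while constant and
#' linear backgrounds are removed up to an edge-width offset.
#'
#' A rolling minimum of a noisy trace is biased low by roughly the expected
#' minimum of `window_px` noise draws, which would leave a positive noise
#' floor in the corrected profile (and hand spurious area to the outermost
#' bands). The estimator therefore adds back the expected minimum of
#' `window_px` standard normal draws (two-term extreme-value expansion)
#' times a robust noise-sd estimate (median absolute successive difference /
#' sqrt(2)); the correction vanishes exactly on noise-free profiles.
#'
#' The rolling estimate also wiggles spatially with the noise, which
#' propagates into band areas as a correlated error across the ladder. When
#' the background of the gel is well described by a straight line (constant
#' plus drift, the usual case for a washed lane), `fit = "linear"` replaces
#' the rolling estimate by its least-squares line, which removes that
#' variance while reproducing any linear background exactly.
#'
#' @param profile A [lane_profile()].
#' @param window_px Window width in profile points, `> 0` and smaller than
#'   the profile.
#' @param fit `"none"` (subtract the rolling estimate as is) or `"linear"`
#'   (subtract its least-squares line).
#' @return A background-subtracted [lane_profile()].
#' @export
subtract_background <- function(profile, window_px, fit = c("none", "linear")) {
  fit <- match.arg(fit)
  if (!inherits(profile, "lane_profile")) stop_tq("topoquant_invalid_parameter", "profile must be a lane_profile")
  n <- length(profile$intensities)
  if (!is_count(window_px) || window_px <= 0 || window_px >= n) {
    stop_tq("topoquant_invalid_parameter", "window_px must be a positive integer smaller than the profile")
  }
  y <- profile$intensities
  bg <- zoo::rollapply(y, width = window_px, FUN = min,
                       partial = TRUE, align = "center")
  bg <- zoo::rollapply(bg, width = window_px, FUN = mean,
                       partial = TRUE, align = "center")
  sigma_hat <- stats::mad(diff(y)) / sqrt(2)
  a <- sqrt(2 * log(window_px))
  kappa <- if (window_px > 2) a - (log(log(window_px)) + log(4 * pi)) / (2 * a) else 0
  bg <- bg + kappa * sigma_hat
  if (fit == "linear") {
    bg <- stats::fitted(stats::lm(bg ~ profile$positions))
  }
  lane_profile(profile$positions, pmax(y - bg, 0), lane_id = profile$lane_id)
}

# Ladder spacing from sorted band centers. A missing band doubles its gap
# and a spurious doublet produces a sub-spacing gap, so neither the plain
# median nor the minimum gap is safe. The unit is the smallest gap that is
# still a substantial fraction of the median gap (doublet gaps fall below
# it and are ignored); every gap is then rounded to its nearest multiple of
# the unit and the unit refit by least squares over all gaps. Doublets
# therefore collide onto one index downstream, which is the desired
# ambiguity signal.
estimate_spacing <- function(centers) {
  if (length(centers) < 2L) return(NA_real_)
  gaps <- diff(sort(centers))
  big <- gaps[gaps >= 0.6 * stats::median(gaps)]
  unit <- if (length(big)) min(big) else min(gaps)
  mult <- pmax(1, round(gaps / unit))
  sum(gaps) / sum(mult)
}

# Topographic prominence of a local maximum: height above the higher of the
# two minima separating it from the nearest strictly-higher ground on each
# side (or the profile end).
peak_prominence <- function(y, idx) {
  n <- length(y)
  vapply(idx, function(i) {
    h <- y[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) { if (y[j] < lmin) lmin <- y[j]; j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) { if (y[j] < rmin) rmin <- y[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect topoisomer bands in a background-subtracted profile
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_frac` of the profile maximum, then enforces a minimum
#' separation by keeping taller peaks first (ties keep the topmost peak).
#' Each retained band's integrated intensity is the trapezoidal area of the
#' profile between the midpoints to its neighboring bands; the outermost
#' bands integrate half the median inter-band spacing beyond their centers
#' (a lone band integrates the whole profile), so the ladder's
#' above-background area is partitioned among the bands without sweeping in
#' far-field noise.
#'
#' Peak finding can optionally run on a lightly smoothed copy of the trace
#' (`smooth_px`-point centered moving average): maxima, prominences and the
#' threshold are then evaluated on the smoothed trace, which stabilizes the
#' detected band set against noise near the prominence threshold, while
#' integrated intensities are always taken from the unsmoothed profile. The
#' default (`smooth_px = 1`) applies no smoothing.
#'
#' @param profile A background-subtracted [lane_profile()].
#' @param min_prominence_frac Fraction of the profile maximum a peak's
#'   prominence must reach, in `(0, 1]`.
#' @param min_separation_px Minimum distance between retained peaks, in
#'   position units, `> 0`.
#' @param smooth_px Odd window (profile points) of the moving average used
#'   for peak finding; 1 = none.
#' @return A data.frame with one row per band: `center_px`, `height`,
#'   `prominence`, `integrated_intensity`, ordered top to bottom. A flat or
#'   empty profile yields zero rows.
#' @export
detect_bands <- function(profile, min_prominence_frac = 0.05,
                         min_separation_px = 5, smooth_px = 1L) {
  if (!inherits(profile, "lane_profile")) stop_tq("topoquant_invalid_parameter", "profile must be a lane_profile")
  if (!is_num1(min_prominence_frac) || min_prominence_frac <= 0 || min_prominence_frac > 1) {
    stop_tq("topoquant_invalid_parameter", "min_prominence_frac must be in (0, 1]")
  }
  if (!is_num1(min_separation_px) || min_separation_px <= 0) {
    stop_tq("topoquant_invalid_parameter", "min_separation_px must be > 0")
  }
  if (!is_count(smooth_px) || smooth_px < 1 || smooth_px %% 2 == 0) {
    stop_tq("topoquant_invalid_parameter", "smooth_px must be an odd positive integer")
  }
  x <- profile$positions
  y <- profile$intensities
  n <- length(y)
  empty <- data.frame(center_px = numeric(), height = numeric(),
                      prominence = numeric(), integrated_intensity = numeric())
  if (n < 3L || max(y) <= 0) return(empty)
  ys <- if (smooth_px > 1L && smooth_px < n) {
    zoo::rollapply(y, width = smooth_px, FUN = mean, partial = TRUE, align = "center")
  } else y
  i <- 2:(n - 1L)
  cand <- i[ys[i] > ys[i - 1L] & ys[i] >= ys[i + 1L]]
  if (!length(cand)) return(empty)
  prom <- peak_prominence(ys, cand)
  keep <- prom >= min_prominence_frac * max(ys)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # separation filter: taller first; equal heights keep the topmost
  ord <- order(-ys[cand], cand)
  sel <- integer(0)
  for (k in ord) {
    if (!length(sel) || all(abs(x[cand[k]] - x[cand[sel]]) >= min_separation_px)) {
      sel <- c(sel, k)
    }
  }
  sel <- sel[order(cand[sel])]
  idx <- cand[sel]
  centers <- x[idx]
  # integration windows: midpoints between adjacent centers; the outermost
  # windows reach half the median inter-band spacing beyond their peaks
  # (instead of running to the profile ends, which would sweep far-field
  # noise area into the edge bands)
  if (length(centers) > 1L) {
    reach <- stats::median(diff(centers)) / 2
    bounds <- c(max(x[1], centers[1] - reach),
                (centers[-1] + centers[-length(centers)]) / 2,
                min(x[n], centers[length(centers)] + reach))
  } else {
    bounds <- c(x[1], x[n])
  }
  area <- vapply(seq_along(idx), function(k) {
    inwin <- x >= bounds[k] & x <= bounds[k + 1]
    pracma::trapz(x[inwin], y[inwin])
  }, numeric(1))
  data.frame(center_px = centers, height = y[idx], prominence = prom[sel],
             integrated_intensity = area)
}

#' Assign integer linking-number indices to detected bands
#'
#' The topmost band of a ladder is set to apparent Lk = 0, the band
#' immediately below to 1, and so on; a missing (undetected) band simply
#' skips its integer. Indices are `round((center - origin) / spacing)` where
#' `spacing` (when `"auto"`) is estimated from the inter-peak gaps, treating
#' the smallest gap as one spacing unit so that gaps doubled by a missing
#' band do not distort the estimate. For lanes run
#' on the same gel, supplying a common `reference_center` (e.g. the topmost
#' band of a designated reference lane) puts all lanes on one shared index
#' scale so their weighted means are directly comparable.
#'
#' @param peaks A data.frame from [detect_bands()] (needs `center_px` and
#'   `integrated_intensity`), at least one row.
#' @param expected_spacing_px Inter-band spacing in position units, or
#'   `"auto"` (median of inter-peak distances; requires >= 2 peaks unless a
#'   numeric spacing is given).
#' @param lane_id Lane label stored in the band table.
#' @param reference_center Optional position of the index-0 band; default is
#'   this lane's topmost detected band.
#' @return A band table: data.frame `lane_id`, `lk_index`, `center_px`,
#'   `integrated_intensity`.
#' @export
assign_linking_numbers <- function(peaks, expected_spacing_px = "auto",
                                   lane_id = "lane", reference_center = NULL) {
  if (!is.data.frame(peaks) || nrow(peaks) < 1L) {
    stop_tq("topoquant_no_bands_error", "no peaks to assign linking numbers to")
  }
  centers <- sort(peaks$center_px)
  intens <- peaks$integrated_intensity[order(peaks$center_px)]
  if (identical(expected_spacing_px, "auto")) {
    spacing <- estimate_spacing(centers)
  } else {
    if (!is_num1(expected_spacing_px) || expected_spacing_px <= 0) {
      stop_tq("topoquant_invalid_parameter", "expected_spacing_px must be > 0 or 'auto'")
    }
    spacing <- expected_spacing_px
  }
  origin <- if (is.null(reference_center)) centers[1] else reference_center
  if (is.na(spacing)) {
    lk <- 0L
  } else {
    lk <- as.integer(round((centers - origin) / spacing))
  }
  if (anyDuplicated(lk)) {
    dup <- lk[duplicated(lk)][1]
    stop_tq("topoquant_ambiguous_ladder_error",
            sprintf("bands at positions %s map to the same Lk index %d",
                    paste(signif(centers[lk == dup], 6), collapse = " and "), dup))
  }
  data.frame(lane_id = lane_id, lk_index = lk, center_px = centers,
             integrated_intensity = intens)
}

#' Intensity-weighted mean linking number of a lane
#'
#' The central densitometric statistic: `sum(I_i * Lk_i) / sum(I_i)` over the
#' bands of one lane, with band intensities as weights.
#'
#' @param bands A band table from [assign_linking_numbers()].
#' @return The weighted mean apparent Lk (a single number).
#' @export
weighted_mean_lk <- function(bands) {
  if (!is.data.frame(bands) || nrow(bands) == 0L) {
    stop_tq("topoquant_no_bands_error", "band table is empty")
  }
  if (any(!is.finite(bands$integrated_intensity)) || any(bands$integrated_intensity <= 0)) {
    stop_tq("topoquant_invalid_band_error", "all integrated intensities must be positive")
  }
  sum(bands$integrated_intensity * bands$lk_index) / sum(bands$integrated_intensity)
}

#' Quantify a gel lane end to end
#'
#' The one-call densitometry fit: background subtraction, band detection,
#' linking-number assignment, and the intensity-weighted mean Lk, returned as
#' a classed object with `print()`, `coef()` and `plot()` methods.
#'
#' @param profile A raw [lane_profile()].
#' @param background_window_px Window for [subtract_background()]; a good
#'   default is about 3x the expected band spacing.
#' @param background_fit Background model passed to [subtract_background()].
#' @param min_prominence_frac,min_separation_px,smooth_px Passed to
#'   [detect_bands()].
#' @param expected_spacing_px,reference_center Passed to
#'   [assign_linking_numbers()].
#' @return An object of class `"lane_quant"`: list with `lane_id`, `bands`
#'   (band table), `weighted_lk`, `spacing_px`, plus the raw and corrected
#'   profiles.
#' @examples
#' d <- topoisomer_distribution(2, sd = 1.25, half_support = 5)
#' g <- gel_geometry(150, 30, 2, 480)
#' fit <- quantify_lane(render_lane(d, g), background_window_px = 91)
#' coef(fit)  # close to 2
#' @export
quantify_lane <- function(profile, background_window_px = 91L,
                          background_fit = c("none", "linear"),
                          min_prominence_frac = 0.05, min_separation_px = 10,
                          smooth_px = 1L,
                          expected_spacing_px = "auto", reference_center = NULL) {
  corrected <- subtract_background(profile, background_window_px,
                                   fit = match.arg(background_fit))
  peaks <- detect_bands(corrected, min_prominence_frac, min_separation_px,
                        smooth_px = smooth_px)
  if (nrow(peaks) == 0L) {
    stop_tq("topoquant_no_bands_error",
            sprintf("no bands detected in lane '%s'", profile$lane_id))
  }
  bands <- assign_linking_numbers(peaks, expected_spacing_px,
                                  lane_id = profile$lane_id,
                                  reference_center = reference_center)
  spacing <- estimate_spacing(bands$center_px)
  structure(list(lane_id = profile$lane_id, bands = bands,
                 weighted_lk = weighted_mean_lk(bands),
                 spacing_px = spacing, profile = profile, corrected = corrected),
            class = "lane_quant")
}

#' @export
print.lane_quant <- function(x, ...) {
  cat(sprintf("Lane '%s': %d bands, weighted mean Lk = %.3f\n",
              x$lane_id, nrow(x$bands), x$weighted_lk))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' @export
coef.lane_quant <- function(object, ...) {
  c(weighted_lk = object$weighted_lk)
}

#' @export
plot.lane_quant <- function(x, ...) {
  graphics::plot(x$profile$positions, x$profile$intensities, type = "l",
                 xlab = "position (px, top of gel = 0)", ylab = "intensity",
                 main = sprintf("Lane '%s' (weighted Lk = %.2f)",
                                x$lane_id, x$weighted_lk), ...)
  graphics::lines(x$corrected$positions, x$corrected$intensities, col = "grey50")
  graphics::abline(v = x$bands$center_px, col = "red3", lty = 3)
  graphics::text(x$bands$center_px, max(x$profile$intensities),
                 labels = x$bands$lk_index, col = "red3", pos = 3, xpd = NA)
  invisible(x)
}

#' Read and write band tables as TSV
#'
#' Columns: `lane_id`, `lk_index`, `center_px`, `integrated_intensity`.
#'
#' @param bands A band table (possibly several lanes row-bound).
#' @param path File path.
#' @return `read_band_table()` returns the data.frame;
#'   `write_band_table()` returns `path` invisibly.
#' @export
write_band_table <- function(bands, path) {
  utils::write.table(bands, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_band_table
#' @export
read_band_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "lk_index", "center_px", "integrated_intensity")
  if (!all(need %in% names(d))) {
    stop_tq("topoquant_parse_error",
            sprintf("band table must have columns: %s", paste(need, collapse = ", ")))
  }
  d
}
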