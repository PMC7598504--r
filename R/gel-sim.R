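#' Gel geometry for synthetic lane rendering
#'
#' Maps integer apparent linking numbers to migration positions along a lane.
#' Band centers follow `origin_px + spacing_px * lk - compression * lk^2`;
#' position 0 is the top of the gel (the wells) and larger Lk indices migrate
#' further down, so `spacing_px > 0`. The quadratic `compression` term (default
#' 0) lets tests exercise mildly non-uniform ladders; real chloroquine gels are
#' treated as approximately uniform.
#'
#' @param origin_px Position of the Lk = 0 band center, pixels, `>= 0`.
#' @param spacing_px Inter-topoisomer spacing, pixels, `> 0`.
#' @param band_sigma_px Gaussian band half-width (sd), pixels, `> 0`.
#' @param length_px Profile length in pixels, positive integer.
#' @param compression Quadratic spacing decay per squared index, `>= 0`.
#' @return An object of class `"gel_geometry"`.
#' @export
gel_geometry <- function(origin_px, spacing_px, band_sigma_px, length_px,
                         compression = 0) {
  if (!is_num1(origin_px) || origin_px < 0) stop_tq("topoquant_invalid_parameter", "origin_px must be >= 0")
  if (!is_num1(spacing_px) || spacing_px <= 0) stop_tq("topoquant_invalid_parameter", "spacing_px must be > 0")
  if (!is_num1(band_sigma_px) || band_sigma_px <= 0) stop_tq("topoquant_invalid_parameter", "band_sigma_px must be > 0")
  if (!is_count(length_px) || length_px <= 0) stop_tq("topoquant_invalid_parameter", "length_px must be a positive integer")
  if (!is_num1(compression) || compression < 0) stop_tq("topoquant_invalid_parameter", "compression must be >= 0")
  structure(list(origin_px = origin_px, spacing_px = spacing_px,
                 band_sigma_px = band_sigma_px, length_px = as.integer(length_px),
                 compression = compression),
            class = "gel_geometry")
}

band_center <- function(geom, lk) {
  geom$origin_px + geom$spacing_px * lk - geom$compression * lk^2
}

#' Additive noise model for synthetic lanes
#'
#' Background is linear in position (`background_const + background_slope *
#' position`); noise is additive Gaussian with standard deviation
#' `noise_sd_frac` times the tallest band amplitude. With `noise_sd_frac = 0`
#' rendering is deterministic and the seed is never consumed.
#'
#' @param background_const Constant background intensity, `>= 0`.
#' @param background_slope Background slope, intensity per pixel.
#' @param noise_sd_frac Noise sd as a fraction of the peak band amplitude,
#'   `>= 0`.
#' @param seed Integer seed; one generator per render call, no global state.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(background_const = 0, background_slope = 0,
                        noise_sd_frac = 0, seed = 1L) {
  if (!is_num1(background_const) || background_const < 0) {
    stop_tq("topoquant_invalid_parameter", "background_const must be >= 0")
  }
  if (!is_num1(background_slope)) stop_tq("topoquant_invalid_parameter", "background_slope must be finite")
  if (!is_num1(noise_sd_frac) || noise_sd_frac < 0) {
    stop_tq("topoquant_invalid_parameter", "noise_sd_frac must be >= 0")
  }
  if (!is_count(seed)) stop_tq("topoquant_invalid_parameter", "seed must be an integer")
  structure(list(background_const = background_const,
                 background_slope = background_slope,
                 noise_sd_frac = noise_sd_frac, seed = as.integer(seed)),
            class = "noise_model")
}

#' Render a synthetic gel lane profile
#'
#' Produces a 1-D intensity profile: linear background plus, for each
#' topoisomer, a Gaussian of area `total_intensity * p_i` centered at its
#' migration position, plus optional additive noise (clipped at 0 so
#' intensities stay nonnegative). Band amplitudes are therefore proportional
#' to topoisomer probabilities, matching densitometric quantification of real
#' ladders.
#'
#' @param dist A [topoisomer_distribution()].
#' @param geom A [gel_geometry()]; every support index must map inside the
#'   profile.
#' @param noise A [noise_model()].
#' @param total_intensity Total band area above background, `> 0`.
#' @param lane_id Label carried through to the profile.
#' @return A [lane_profile()] of length `geom$length_px`.
#' @export
render_lane <- function(dist, geom, noise = noise_model(),
                        total_intensity = 1000, lane_id = "lane") {
  if (!inherits(dist, "topo_dist")) stop_tq("topoquant_invalid_parameter", "dist must be a topo_dist")
  if (!inherits(geom, "gel_geometry")) stop_tq("topoquant_invalid_parameter", "geom must be a gel_geometry")
  if (!inherits(noise, "noise_model")) stop_tq("topoquant_invalid_parameter", "noise must be a noise_model")
  if (!is_num1(total_intensity) || total_intensity <= 0) {
    stop_tq("topoquant_invalid_parameter", "total_intensity must be > 0")
  }
  centers <- band_center(geom, dist$lk)
  bad <- which(centers < 0 | centers >= geom$length_px)
  if (length(bad)) {
    stop_tq("topoquant_geometry_error",
            sprintf("band center(s) outside profile for Lk = %s",
                    paste(dist$lk[bad], collapse = ", ")))
  }
  x <- seq.int(0L, geom$length_px - 1L)
  signal <- rep(0, length(x))
  for (i in seq_along(dist$lk)) {
    signal <- signal + total_intensity * dist$p[i] *
      stats::dnorm(x, mean = centers[i], sd = geom$band_sigma_px)
  }
  y <- noise$background_const + noise$background_slope * x + signal
  if (noise$noise_sd_frac > 0) {
    amp <- max(signal)
    eps <- with_local_seed(noise$seed,
                           stats::rnorm(length(x), sd = noise$noise_sd_frac * amp))
    y <- y + eps
  }
  lane_profile(positions = x, intensities = pmax(y, 0), lane_id = lane_id)
}

#' Render a multi-lane synthetic gel image
#'
#' Stacks rendered lanes side by side into a grayscale intensity matrix
#' (row 0 at the top of the gel). Each lane occupies `lane_width_px` columns
#' with its 1-D profile replicated across the width; useful for exercising
#' region-of-interest profile extraction.
#'
#' @param profiles List of [lane_profile()]s of equal length.
#' @param lane_width_px Columns per lane.
#' @return A numeric matrix of dimension `length x (n_lanes * lane_width_px)`,
#'   with attribute `lane_cols`: a named list of column index ranges per lane.
#' @export
render_gel_image <- function(profiles, lane_width_px = 10L) {
  if (!length(profiles)) stop_tq("topoquant_invalid_parameter", "profiles must be non-empty")
  n <- length(profiles[[1]]$positions)
  img <- matrix(0, nrow = n, ncol = length(profiles) * lane_width_px)
  lane_cols <- list()
  for (i in seq_along(profiles)) {
    cols <- ((i - 1L) * lane_width_px + 1L):(i * lane_width_px)
    img[, cols] <- profiles[[i]]$intensities
    lane_cols[[profiles[[i]]$lane_id]] <- range(cols)
  }
  attr(img, "lane_cols") <- lane_cols
  img
}

#' Default synthetic scenario configuration
#'
#' Encodes the study conditions the package is tested against: two reference
#' lanes — `ref0` ("wild type, high Mg") and `ref1` ("wild type, low Mg") —
#' whose true weighted mean Lk differ by 0.5, so that one full linking number
#' of offset from `ref0` corresponds to 2 RSU, plus one sample lane offset by
#' 1.0 Lk from `ref0`. Ladders have sd 1.35 Lk, which puts 7 bands above the
#' default 5% detection prominence — mimicking the 7-8 visible bands of a
#' typical chloroquine gel — while keeping the next band pair well below it,
#' so the detected ladder does not flicker with noise. Band noise defaults
#' to 1% of the peak amplitude.
#'
#' @param ref0_mean_lk True mean Lk of the 0-RSU reference lane.
#' @param ref_separation_lk Weighted-Lk separation between `ref1` and `ref0`.
#' @param sample_offsets_lk Named numeric vector of sample-lane offsets from
#'   `ref0` (names become lane ids).
#' @param sd Ladder standard deviation in Lk.
#' @param half_support Integer support half-width of each ladder.
#' @param geometry A [gel_geometry()] shared by all lanes.
#' @param noise_sd_frac Additive noise level (fraction of peak amplitude).
#' @param background_const,background_slope Background model.
#' @param total_intensity Total band intensity per lane.
#' @return A plain list understood by [generate_scenario()].
#' @export
scenario_config <- function(ref0_mean_lk = 2.0,
                            ref_separation_lk = 0.5,
                            sample_offsets_lk = c(sample_1lk = 1.0),
                            sd = 1.35,
                            half_support = 6L,
                            geometry = gel_geometry(origin_px = 150, spacing_px = 30,
                                                    band_sigma_px = 5, length_px = 480),
                            noise_sd_frac = 0.01,
                            background_const = 2,
                            background_slope = 0.002,
                            total_intensity = 1000) {
  list(ref0_mean_lk = ref0_mean_lk,
       ref_separation_lk = ref_separation_lk,
       sample_offsets_lk = sample_offsets_lk,
       sd = sd, half_support = as.integer(half_support),
       geometry = geometry,
       noise_sd_frac = noise_sd_frac,
       background_const = background_const,
       background_slope = background_slope,
       total_intensity = total_intensity)
}

#' Generate a labeled synthetic scenario with ground truth
#'
#' Builds the topoisomer distributions implied by a [scenario_config()],
#' renders every lane on a shared geometry, and returns the lanes together
#' with a ground-truth manifest (true mean Lk per lane, from the realized
#' discretized distributions). Reference lanes are always labeled `ref0` and
#' `ref1`.
#'
#' @param config A [scenario_config()] list; must define both references and
#'   at least one sample lane.
#' @param seed Integer master seed; each lane's noise seed is derived from it.
#' @return A list with `profiles` (named list of [lane_profile()]s),
#'   `manifest` (data.frame `lane_id`, `role`, `true_mean_lk`), `config`.
#' @export
generate_scenario <- function(config = scenario_config(), seed = 1L) {
  req <- c("ref0_mean_lk", "ref_separation_lk", "sample_offsets_lk")
  miss <- setdiff(req, names(config))
  if (length(miss)) {
    stop_tq("topoquant_config_error",
            sprintf("scenario config missing: %s", paste(miss, collapse = ", ")))
  }
  offs <- config$sample_offsets_lk
  if (!length(offs)) stop_tq("topoquant_config_error", "scenario needs at least one sample lane")
  if (is.null(names(offs)) || any(!nzchar(names(offs)))) {
    stop_tq("topoquant_config_error", "sample_offsets_lk must be a named vector")
  }
  means <- c(ref0 = config$ref0_mean_lk,
             ref1 = config$ref0_mean_lk + config$ref_separation_lk,
             config$ref0_mean_lk + offs)
  roles <- c("ref0", "ref1", rep("sample", length(offs)))
  profiles <- list()
  manifest <- data.frame(lane_id = character(), role = character(),
                         true_mean_lk = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(means)) {
    id <- names(means)[i]
    d <- topoisomer_distribution(means[[i]], sd = config$sd,
                                 half_support = config$half_support)
    nm <- noise_model(background_const = config$background_const,
                      background_slope = config$background_slope,
                      noise_sd_frac = config$noise_sd_frac,
                      seed = (as.integer(seed) * 131L + i) %% .Machine$integer.max)
    profiles[[id]] <- render_lane(d, config$geometry, nm,
                                  total_intensity = config$total_intensity,
                                  lane_id = id)
    manifest <- rbind(manifest,
                      data.frame(lane_id = id, role = roles[i],
                                 true_mean_lk = d$mean_lk,
                                 stringsAsFactors = FALSE))
  }
  list(profiles = profiles, manifest = manifest, config = config)
}
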