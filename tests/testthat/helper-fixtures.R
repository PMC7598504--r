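# Shared fixtures built in code at test time.

# Geometry wide enough for ladders with mean Lk anywhere in [0.5, 5] at
# half-support 6.
wide_geometry <- function(band_sigma_px = 5) {
  gel_geometry(origin_px = 200, spacing_px = 30, band_sigma_px = band_sigma_px,
               length_px = 560)
}

default_ladder <- function(mean_lk, sd = 1.35) {
  topoisomer_distribution(mean_lk, sd = sd, half_support = 6L)
}

# Quantify one rendered lane on an absolute index scale (index 0 at the
# geometry origin), so the result is directly comparable to the simulator's
# true mean.
quantify_absolute <- function(profile, geom, ...) {
  fit <- quantify_lane(profile, reference_center = geom$origin_px, ...)
  fit$weighted_lk
}

table1_path <- function() {
  system.file("extdata", "table1_expression.tsv", package = "topoquant")
}
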