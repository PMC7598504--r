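test_that("profile extraction averages the lane region of an image", {
  img <- matrix(7, nrow = 20, ncol = 10)
  p <- extract_lane_profile(img, cols = c(3, 8))
  expect_equal(p$intensities, rep(7, 20))
  expect_equal(p$positions, 0:19)

  # width-1 region degenerates to that pixel column
  img2 <- matrix(runif(200), nrow = 20)
  p1 <- extract_lane_profile(img2, cols = c(4, 4))
  expect_equal(p1$intensities, img2[, 4])

  expect_error(extract_lane_profile(img, cols = c(9, 12)),
               class = "topoquant_bounds_error")
})

test_that("a rendered multi-lane image yields the same profile as the 1-D render", {
  d <- default_ladder(2)
  g <- wide_geometry()
  p <- render_lane(d, g, noise_model(), 1000, lane_id = "laneA")
  img <- render_gel_image(list(p), lane_width_px = 8L)
  cols <- attr(img, "lane_cols")$laneA
  q <- extract_lane_profile(img, cols = cols, lane_id = "laneA")
  expect_equal(q$intensities, p$intensities, tolerance = 1e-12)
})

test_that("background subtraction flattens ramps and preserves peaks", {
  # pure linear ramp: residual below 1% of the ramp range
  n <- 3000
  ramp <- lane_profile(0:(n - 1), 5 + 0.01 * (0:(n - 1)))
  res <- subtract_background(ramp, 31)
  expect_lt(max(res$intensities), 0.01 * diff(range(ramp$intensities)))

  # single Gaussian on zero background: peak height kept within 2%
  x <- 0:499
  gauss <- lane_profile(x, 50 * exp(-(x - 250)^2 / (2 * 9)))
  out <- subtract_background(gauss, 91)
  expect_equal(max(out$intensities), 50, tolerance = 0.02 * 50)

  # all-zero profile maps to itself
  z <- lane_profile(0:99, rep(0, 100))
  expect_equal(subtract_background(z, 11)$intensities, rep(0, 100))

  expect_error(subtract_background(z, 100), class = "topoquant_invalid_parameter")
})

test_that("the linear background model handles a drifting background cleanly", {
  d <- default_ladder(2.5)
  g <- wide_geometry()
  p <- render_lane(d, g, noise_model(background_const = 4, background_slope = 0.02), 1000)
  w_lin <- quantify_absolute(p, g, background_window_px = 91,
                             background_fit = "linear", min_separation_px = 10)
  expect_equal(w_lin, d$mean_lk, tolerance = 0.02)
  # the raw rolling estimate is coarser against a sloped background but
  # stays in the neighbourhood
  w_roll <- quantify_absolute(p, g, background_window_px = 91,
                              min_separation_px = 10)
  expect_equal(w_roll, d$mean_lk, tolerance = 0.1)
})

test_that("band detection finds exactly the rendered ladder", {
  d <- default_ladder(2)   # 7 bands above the 5% prominence threshold
  g <- wide_geometry()
  p <- render_lane(d, g, noise_model(), 1000)
  pk <- detect_bands(subtract_background(p, 91), 0.05, 10)
  expect_equal(nrow(pk), 7L)
  truth <- g$origin_px + g$spacing_px * (-1:5)
  expect_true(all(abs(pk$center_px - truth) <= 1))

  # flat profile: no bands, not an error
  flat <- lane_profile(0:99, rep(3, 100))
  expect_equal(nrow(detect_bands(flat, 0.05, 5)), 0L)

  # with 1% noise and a fixed seed the same 7 bands are found
  pn <- render_lane(d, g, noise_model(2, 0.002, 0.01, seed = 11L), 1000)
  pkn <- detect_bands(subtract_background(pn, 91, fit = "linear"), 0.05, 10,
                      smooth_px = 5)
  expect_equal(nrow(pkn), 7L)
  expect_true(all(abs(pkn$center_px - truth) <= 2))
})

test_that("detection matches an exhaustive brute-force scan on short profiles", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(16:64, 1)
    y <- pmax(stats::filter(rnorm(n, sd = 1), rep(1, 3) / 3, circular = TRUE) +
                3 * sin(seq(0, sample(2:6, 1) * pi, length.out = n)), 0)
    y <- as.numeric(y) - min(y)
    prof <- lane_profile(0:(n - 1), y)
    for (sep in c(1, 3, 6)) {
      got <- detect_bands(prof, 0.1, sep)
      want_idx <- brute_force_peaks(y, 0.1, sep)
      expect_equal(got$center_px, (0:(n - 1))[want_idx],
                   info = sprintf("rep %d sep %d", rep, sep))
    }
  }
})

test_that("linking numbers index down from the topmost band", {
  pk <- data.frame(center_px = c(100, 130, 160), integrated_intensity = c(1, 2, 3))
  bt <- assign_linking_numbers(pk)
  expect_equal(bt$lk_index, 0:2)

  # a missing band skips its integer
  pk2 <- data.frame(center_px = c(100, 130, 190), integrated_intensity = c(1, 2, 3))
  expect_equal(assign_linking_numbers(pk2)$lk_index, c(0L, 1L, 3L))

  # a lone band is index 0
  pk3 <- data.frame(center_px = 42, integrated_intensity = 5)
  expect_equal(assign_linking_numbers(pk3)$lk_index, 0L)

  # two bands collapsing onto one index is an ambiguity, reported with positions
  pk4 <- data.frame(center_px = c(100, 130, 134), integrated_intensity = c(1, 1, 1))
  err <- expect_error(assign_linking_numbers(pk4),
                      class = "topoquant_ambiguous_ladder_error")
  expect_match(conditionMessage(err), "130")

  # a shared reference center puts lanes on one index scale
  bt5 <- assign_linking_numbers(pk, reference_center = 40)
  expect_equal(bt5$lk_index, 2:4)
})

test_that("the weighted mean linking number is the intensity-weighted average", {
  one <- data.frame(lane_id = "l", lk_index = 2L, center_px = 50,
                    integrated_intensity = 10)
  expect_equal(weighted_mean_lk(one), 2)

  two <- data.frame(lane_id = "l", lk_index = 0:1, center_px = c(10, 40),
                    integrated_intensity = c(5, 5))
  expect_equal(weighted_mean_lk(two), 0.5)

  three <- data.frame(lane_id = "l", lk_index = 0:2, center_px = c(10, 40, 70),
                      integrated_intensity = c(1, 2, 3))
  expect_equal(weighted_mean_lk(three), 8 / 6, tolerance = 1e-12)

  expect_error(weighted_mean_lk(three[0, ]), class = "topoquant_no_bands_error")
  bad <- three; bad$integrated_intensity[2] <- 0
  expect_error(weighted_mean_lk(bad), class = "topoquant_invalid_band_error")
})

test_that("weighted mean Lk is scale-invariant and translation-covariant", {
  set.seed(5)
  for (rep in 1:10) {
    nb <- sample(3:8, 1)
    bt <- data.frame(lane_id = "l", lk_index = sort(sample(0:12, nb)),
                     center_px = seq_len(nb) * 30,
                     integrated_intensity = runif(nb, 0.1, 10))
    w <- weighted_mean_lk(bt)
    sc <- bt; sc$integrated_intensity <- sc$integrated_intensity * runif(1, 0.5, 50)
    expect_equal(weighted_mean_lk(sc), w, tolerance = 1e-12)
    k <- sample(-3:3, 1)
    sh <- bt; sh$lk_index <- sh$lk_index + k
    expect_equal(weighted_mean_lk(sh), w + k, tolerance = 1e-12)
  }
})

test_that("noise-free lanes are re-quantified to the true mean within 0.02 Lk", {
  g <- wide_geometry()
  for (m in seq(0.5, 5, by = 0.5)) {
    d <- default_ladder(m)
    p <- render_lane(d, g, noise_model(), 1000)
    w <- quantify_absolute(p, g, background_window_px = 91, min_separation_px = 10)
    expect_equal(w, d$mean_lk, tolerance = 0.02,
                 info = sprintf("mean_lk = %.1f", m))
  }
})

test_that("rendered band areas are proportional to topoisomer probabilities", {
  d <- topoisomer_distribution(2, sd = 1.35, half_support = 6)
  g <- wide_geometry(band_sigma_px = 4)
  # zero noise, zero background: the rendered profile needs no correction
  p <- render_lane(d, g, noise_model(), 1000)
  pk <- detect_bands(p, 0.05, 10)
  lk <- round((pk$center_px - g$origin_px) / g$spacing_px)
  p_det <- d$p[match(lk, d$lk)]
  ratio <- (pk$integrated_intensity / sum(pk$integrated_intensity)) /
    (p_det / sum(p_det))
  expect_true(all(abs(ratio - 1) < 0.005))
})

test_that("quantify_lane returns a printable model object with coef and plot", {
  p <- render_lane(default_ladder(2), wide_geometry(), noise_model(), 1000,
                   lane_id = "demo")
  fit <- quantify_lane(p, background_window_px = 91, min_separation_px = 10)
  expect_s3_class(fit, "lane_quant")
  expect_named(coef(fit), "weighted_lk")
  expect_output(print(fit), "weighted mean Lk")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))

  flat <- lane_profile(0:199, rep(1, 200))
  expect_error(quantify_lane(flat, background_window_px = 51),
               class = "topoquant_no_bands_error")
})

test_that("band tables survive a TSV round trip", {
  bt <- data.frame(lane_id = "x", lk_index = 0:2, center_px = c(10, 40, 70.5),
                   integrated_intensity = c(1.5, 2.25, 3))
  f <- tempfile(fileext = ".tsv")
  write_band_table(bt, f)
  expect_equal(read_band_table(f), bt)
})
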