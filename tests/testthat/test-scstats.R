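test_that("RSU anchors the references at 0 and 1 and is linear beyond them", {
  expect_equal(rsu(2.0, 2.0, 2.5), 0)
  expect_equal(rsu(2.5, 2.0, 2.5), 1)
  # one full linking number against a 0.5-Lk reference separation is 2 RSU
  expect_equal(rsu(3.0, 2.0, 2.5), 2)
  expect_error(rsu(1, 2, 2 + 1e-12), class = "topoquant_degenerate_reference_error")
})

test_that("RSU is invariant under a common affine transform", {
  set.seed(21)
  for (rep in 1:20) {
    w <- rnorm(1, 3); r0 <- rnorm(1, 2); r1 <- r0 + runif(1, 0.2, 2)
    a <- runif(1, 0.2, 5); b <- rnorm(1, 0, 10)
    expect_equal(rsu(a * w + b, a * r0 + b, a * r1 + b), rsu(w, r0, r1),
                 tolerance = 1e-9)
  }
})

test_that("gyrase activity is the signed Lk change per hour and is additive", {
  expect_equal(gyrase_activity(2.0, 5.0, 1.5), 2.0)
  expect_equal(gyrase_activity(3.2, 3.2, 2), 0)
  expect_lt(gyrase_activity(5, 3, 1), 0)  # relaxation is negative
  expect_error(gyrase_activity(1, 2, 0), class = "topoquant_invalid_duration_error")

  # linear mean drift: rates over [0,t1] and [t1,t2] combine to the overall rate
  w0 <- 1; r <- 1.5; t1 <- 0.8; t2 <- 2.0
  w1 <- w0 + r * t1; w2 <- w0 + r * t2
  a1 <- gyrase_activity(w0, w1, t1)
  a2 <- gyrase_activity(w1, w2, t2 - t1)
  overall <- gyrase_activity(w0, w2, t2)
  expect_equal((a1 * t1 + a2 * (t2 - t1)) / t2, overall, tolerance = 1e-12)
})

test_that("relative activity is percent variation against the baseline", {
  expect_equal(relative_activity(1.7, 1.7), 0)
  expect_equal(relative_activity(2.22, 1), 122, tolerance = 1e-9)
  expect_equal(relative_activity(0, 3), -100)
  expect_error(relative_activity(1, 0), class = "topoquant_degenerate_baseline_error")
})

test_that("the studentized range CDF matches the reference distribution", {
  for (k in c(2L, 3L, 5L, 10L)) {
    for (df in c(2, 5, 10, 40)) {
      q <- c(0.5, 1.5, 3, 5.5)
      expect_equal(ptukey_sr(q, k, df), stats::ptukey(q, k, df),
                   tolerance = 2e-4, info = sprintf("k=%d df=%g", k, df))
    }
  }
  expect_equal(ptukey_sr(0, 3, 5), 0)
  expect_equal(ptukey_sr(-1, 3, 5), 0)
})

test_that("Tukey HSD pairwise p-values match the reference ANOVA implementation", {
  set.seed(7)
  x <- list(a = rnorm(4, 0), b = rnorm(4, 1), c = rnorm(4, 1.2), d = rnorm(5, 3))
  cmp <- compare_groups(x, method = "tukey")
  df <- data.frame(y = unlist(x), g = factor(rep(names(x), lengths(x))))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  for (i in seq_len(nrow(cmp$pairwise))) {
    key1 <- paste0(cmp$pairwise$group2[i], "-", cmp$pairwise$group1[i])
    key2 <- paste0(cmp$pairwise$group1[i], "-", cmp$pairwise$group2[i])
    p_ref <- ref[rownames(ref) %in% c(key1, key2), "p adj"]
    expect_equal(cmp$pairwise$p_adj[i], unname(p_ref), tolerance = 1e-3)
  }
})

test_that("identical groups share one letter; separated groups do not", {
  same <- compare_groups(list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1)),
                         method = "tukey")
  expect_equal(unique(same$groups$letters), "a")

  tt <- compare_groups(list(a = c(1.0, 1.1), b = c(2.0, 2.1)), method = "student_t")
  expect_lt(tt$pairwise$p_adj, 0.05)
  expect_equal(sort(tt$groups$letters), c("a", "b"))
  # the underlying t statistic is ~14.1 on 2 df
  t_stat <- abs(diff(sapply(list(c(1.0, 1.1), c(2.0, 2.1)), mean))) /
    sqrt(0.005 * (1 / 2 + 1 / 2))
  expect_equal(t_stat, 14.14, tolerance = 0.01)
  expect_equal(tt$pairwise$p_adj, 2 * stats::pt(-t_stat, df = 2), tolerance = 1e-9)

  expect_warning(
    tuk <- compare_groups(list(a = c(0.0, 0.1, -0.1, 0.05),
                               b = c(0.1, 0.0, 0.05, -0.05),
                               c = c(10, 10.1, 9.9, 10.05)), method = "tukey",
                          alpha = 0.05),
    NA)
  expect_equal(tuk$groups$letters[tuk$groups$group == "c"], "a")
  expect_equal(sort(tuk$groups$letters), c("a", "b", "b"))
})

test_that("design errors are rejected up front", {
  expect_error(compare_groups(list(a = 1:3)), class = "topoquant_invalid_design_error")
  expect_error(compare_groups(list(a = 1:3, b = 4), method = "tukey"),
               class = "topoquant_insufficient_replicates_error")
  expect_error(compare_groups(list(a = 1:2, b = 3:4, c = 5:6), method = "student_t"),
               class = "topoquant_invalid_design_error")
  expect_warning(compare_groups(list(a = c(1, 1.2), b = c(5, 5.1)), method = "tukey"),
                 class = "topoquant_low_replication_warning")
})

test_that("letters encode exactly the non-significant pairs on fuzzed inputs", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    mus <- rnorm(k, sd = sample(c(0.2, 1, 3), 1))
    x <- lapply(mus, function(m) rnorm(sample(3:5, 1), m, 0.5))
    names(x) <- paste0("g", seq_len(k))
    cmp <- suppressWarnings(compare_groups(x, method = "tukey", alpha = 0.05))
    lets <- strsplit(cmp$groups$letters, "")
    names(lets) <- cmp$groups$group
    for (i in seq_len(nrow(cmp$pairwise))) {
      share <- length(intersect(lets[[cmp$pairwise$group1[i]]],
                                lets[[cmp$pairwise$group2[i]]])) > 0
      expect_identical(share, cmp$pairwise$p_adj[i] >= 0.05,
                       info = sprintf("rep %d pair %s-%s", rep,
                                      cmp$pairwise$group1[i], cmp$pairwise$group2[i]))
    }
  }
})

test_that("rsu_table normalizes a quantified lane set against its references", {
  w <- c(ref0 = 3.0, ref1 = 3.5, mut = 4.2)
  tab <- rsu_table(w)
  expect_equal(tab$rsu, c(0, 1, 2.4), tolerance = 1e-12)
  expect_error(rsu_table(w, ref1 = "nope"), class = "topoquant_config_error")
})
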