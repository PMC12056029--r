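test_that("summarize_univariate matches hand-computed descriptives", {
  a <- cont_cohort(v = c(5, 5, 5), provenance = "real")
  b <- cont_cohort(v = c(5, 5, 5), provenance = "virtual")
  s <- summarize_univariate(a, b, "v")
  expect_equal(s$mean, c(5, 5))
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$min, c(5, 5))
  expect_equal(s$max, c(5, 5))

  a2 <- cont_cohort(v = 1:5)
  s2 <- summarize_univariate(a2, b, "v")
  r <- s2[s2$cohort == "real", ]
  expect_equal(r$mean, 3)
  expect_equal(r$sd, sqrt(10 / 4), tolerance = 1e-12)
  expect_equal(c(r$min, r$max), c(1, 5))

  expect_equal(nrow(summarize_univariate(a, b, character(0))), 0)
  dd <- disc_cohort(c("A", "B", "A"))
  expect_error(summarize_univariate(dd, b, "g"), "continuous")
})

test_that("boxplot_stats follows Tukey conventions", {
  bs <- boxplot_stats(cont_cohort(v = c(1, 2, 3, 4)), "v")
  expect_equal(bs$median, 2.5)
  expect_equal(bs$q1, 1.75)
  expect_equal(bs$q3, 3.25)
  expect_length(bs$outliers, 0)

  bs2 <- boxplot_stats(cont_cohort(v = rep(7, 5)), "v")
  expect_equal(bs2$median, 7)
  expect_equal(bs2$whisker_low, 7)
  expect_equal(bs2$whisker_high, 7)

  bs3 <- boxplot_stats(cont_cohort(v = c(1, 2, 3, 100)), "v")
  expect_equal(bs3$outliers, 100)  # beyond q3 + 1.5 IQR = 65.5
  expect_equal(bs3$whisker_high, 3)
})

test_that("scatter_pairs enumerates unordered pairs with pairwise-complete points", {
  r <- cont_cohort(x = c(1, 2, NA, 4), y = c(1, NA, 3, 4), z = 1:4)
  v <- cont_cohort(x = 1:4, y = 1:4, z = 1:4)
  sp <- scatter_pairs(r, v, c("x", "y", "z"))
  expect_length(sp, 3)  # C(3, 2)
  xy <- sp[[1]]
  expect_equal(xy$x_var, "x")
  expect_equal(nrow(xy$real), 2)      # rows 1 and 4 complete on both
  expect_equal(nrow(xy$virtual), 4)
  xz <- sp[[2]]
  expect_equal(nrow(xz$real), 3)      # only x's NA row drops for x:z
  expect_error(scatter_pairs(r, v, "x"), "at least 2")
})

test_that("spearman_matrices matches closed forms and the stats oracle", {
  r <- cont_cohort(x = c(1, 2, 3), y = c(3, 1, 2))
  v <- cont_cohort(x = c(1, 2, 3), y = exp(c(1, 2, 3)))
  sm <- spearman_matrices(r, v, c("x", "y"))
  expect_equal(sm$real_matrix["x", "y"], -0.5)   # 1 - 6*6/(3*8)
  expect_equal(sm$virtual_matrix["x", "y"], 1)   # monotone invariance
  expect_equal(diag(sm$real_matrix), c(x = 1, y = 1))
  expect_equal(sm$difference_matrix["x", "y"], 1.5)

  set.seed(4)
  df <- data.frame(a = rnorm(30), b = rnorm(30), c = sample(1:5, 30, TRUE))
  ch <- cohort(df)
  sm2 <- spearman_matrices(ch, ch, c("a", "b", "c"))
  oracle <- cor(df, method = "spearman")
  expect_equal(unname(sm2$real_matrix), unname(oracle), tolerance = 1e-12)

  # constant variable: undefined, flagged, not silently zero
  cr <- cont_cohort(x = c(1, 1, 1), y = c(1, 2, 3))
  sm3 <- spearman_matrices(cr, v, c("x", "y"))
  expect_true(is.na(sm3$real_matrix["x", "y"]))
  expect_equal(sm3$undefined_pairs, "x:y")
})

test_that("spearman is invariant under strictly monotone transforms (property)", {
  set.seed(21)
  for (i in 1:8) {
    df <- data.frame(a = rnorm(25), b = runif(25), c = rexp(25))
    ch1 <- cohort(df)
    tf <- list(function(x) exp(x), function(x) x^3, function(x) atan(x) * 5)
    df2 <- data.frame(a = tf[[1]](df$a), b = tf[[2]](df$b), c = tf[[3]](df$c))
    ch2 <- cohort(df2)
    s1 <- spearman_matrices(ch1, ch1, c("a", "b", "c"))
    s2 <- spearman_matrices(ch2, ch2, c("a", "b", "c"))
    expect_equal(s1$real_matrix, s2$real_matrix, tolerance = 1e-12)
  }
})

test_that("quadratic_forms matches hand computation and the mahalanobis oracle", {
  r <- cont_cohort(x = c(-1, 0, 1))
  qf <- quadratic_forms(r, r, "x", df_mode = "classical")
  expect_equal(unname(qf$d_real), c(1, 0, 1))
  expect_equal(sum(qf$d_real), 1 * (3 - 1))
  expect_equal(qf$df, 1)
  expect_equal(quadratic_forms(r, r, "x", df_mode = "paper")$df, 0)

  set.seed(8)
  x <- matrix(rnorm(40 * 3), 40)
  ch <- cohort(as.data.frame(x) |> stats::setNames(c("a", "b", "c")))
  qf2 <- quadratic_forms(ch, ch, c("a", "b", "c"))
  oracle <- stats::mahalanobis(x, colMeans(x), cov(x))
  expect_equal(unname(qf2$d_real), unname(oracle), tolerance = 1e-10)

  # identical datasets: QQ pairs on the diagonal
  expect_equal(qf2$qq_pairs[, "real"], qf2$qq_pairs[, "virtual"])

  # collinear columns reported by name
  bad <- cont_cohort(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = rnorm(4))
  expect_error(quadratic_forms(bad, bad, c("a", "b", "c")), "a ~ b")
  tiny <- cont_cohort(a = c(1, 2), b = c(0, 1), c = c(2, 1))
  expect_error(quadratic_forms(tiny, tiny, c("a", "b", "c")), "n > p")
})

test_that("quadratic-form sum identity and affine invariance (property)", {
  set.seed(14)
  for (i in 1:20) {
    p <- sample(1:5, 1)
    n <- sample((p + 2):200, 1)
    x <- matrix(rnorm(n * p), n)
    colnames(x) <- paste0("v", seq_len(p))
    ch <- cohort(as.data.frame(x))
    qf <- quadratic_forms(ch, ch, colnames(x))
    expect_equal(sum(qf$d_real), p * (n - 1), tolerance = 1e-8)

    # invertible affine map leaves d unchanged
    A <- matrix(rnorm(p * p), p) + diag(p) * 2
    y <- sweep(x %*% A, 2, rnorm(p), `+`)
    colnames(y) <- colnames(x)
    qf2 <- quadratic_forms(cohort(as.data.frame(y)), ch, colnames(x))
    expect_equal(qf$d_real, qf2$d_real, tolerance = 1e-8)
  }
})

test_that("chi2_reference matches closed-form quantiles", {
  expect_equal(chi2_reference(2, 0.5), 2 * log(2), tolerance = 1e-12)
  expect_equal(chi2_reference(1, 0.5), qnorm(0.75)^2, tolerance = 1e-12)
  expect_lt(chi2_reference(3, 1e-12), 1e-3)  # p -> 0+ gives quantile -> 0
  expect_error(chi2_reference(0, 0.5), "df")
  expect_error(chi2_reference(2, c(0.5, 1)), "inside")
})

test_that("bootstrap_density_band is deterministic with ordered bands", {
  set.seed(3)
  r <- cont_cohort(v = rnorm(60))
  v <- cont_cohort(v = rnorm(60))
  b1 <- bootstrap_density_band(r, v, "v", B = 120, seed = 42)
  b2 <- bootstrap_density_band(r, v, "v", B = 120, seed = 42)
  expect_identical(b1, b2)
  expect_true(all(b1$band_lower <= b1$band_upper))
  expect_true(all(b1$band_lower >= 0))
  expect_length(b1$grid, 512)
  expect_equal(b1$p_value, b1$outside_fraction)
  expect_equal(b1$deviation_detected, b1$outside_fraction > 0.05)

  expect_error(bootstrap_density_band(r, v, "v", B = 50), "at least 100")
  small <- cont_cohort(v = rnorm(5))
  expect_error(bootstrap_density_band(small, v, "v", B = 120), "at least 10")
})

test_that("raising the band level never narrows the band (same seed)", {
  set.seed(6)
  r <- cont_cohort(v = rnorm(80))
  v <- cont_cohort(v = rnorm(80, 0.3))
  b90 <- bootstrap_density_band(r, v, "v", B = 150, level = 0.90, seed = 9)
  b99 <- bootstrap_density_band(r, v, "v", B = 150, level = 0.99, seed = 9)
  expect_true(all(b99$band_lower <= b90$band_lower + 1e-12))
  expect_true(all(b99$band_upper >= b90$band_upper - 1e-12))
})
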