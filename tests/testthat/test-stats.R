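# noise-free dispersion table from known coefficients
make_table <- function(k = 10, a_obs = 10, b_obs = -1, a_null = 8,
                       b_null = 0, sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- seq(-2, 2, length.out = k)
  rbind(
    data.frame(seep_id = paste0("s", 1:k), community_type = "observed",
               mean_disparity = a_obs + b_obs * idx + rnorm(k, 0, sigma),
               seep_index = idx),
    data.frame(seep_id = paste0("s", 1:k), community_type = "null",
               mean_disparity = a_null + b_null * idx + rnorm(k, 0, sigma),
               seep_index = idx))
}

test_that("ANCOVA recovers noise-free coefficients exactly", {
  tbl <- make_table(k = 8, a_obs = 10, b_obs = -1, a_null = 8, b_null = 0)
  # noise-free interpolation triggers R's perfect-fit warning by design
  fit <- suppressWarnings(dispersion_ancova(tbl))
  expect_equal(fit$slopes$slope[fit$slopes$community_type == "observed"],
               -1, tolerance = 1e-10)
  expect_equal(fit$slopes$slope[fit$slopes$community_type == "null"],
               0, tolerance = 1e-10)
  am <- fit$adjusted_means
  expect_equal(am$mean[am$community_type == "observed"], 10, tolerance = 1e-10)
  expect_equal(am$mean[am$community_type == "null"], 8, tolerance = 1e-10)
  expect_equal(fit$overall$df1, 3)
  expect_equal(fit$overall$df2, 2 * 8 - 4)
})

test_that("identical groups with zero slope give a flat null fit", {
  tbl <- make_table(k = 6, a_obs = 5, b_obs = 0, a_null = 5, b_null = 0)
  tbl$mean_disparity <- tbl$mean_disparity + rnorm(12, 0, 1e-8)
  fit <- dispersion_ancova(tbl)
  am <- fit$adjusted_means
  expect_equal(am$mean[1], am$mean[2], tolerance = 1e-6)
})

test_that("adjusted means equal group means with a centered covariate", {
  tbl <- make_table(k = 9, a_obs = 12, b_obs = -0.6, a_null = 9,
                    b_null = 0.2, sigma = 0.5, seed = 42)
  tbl$seep_index <- tbl$seep_index - mean(tbl$seep_index)
  fit <- dispersion_ancova(tbl)
  grp <- tapply(tbl$mean_disparity, tbl$community_type, mean)
  am <- fit$adjusted_means
  expect_equal(am$mean[am$community_type == "observed"],
               unname(grp["observed"]), tolerance = 1e-10)
  expect_equal(am$mean[am$community_type == "null"],
               unname(grp["null"]), tolerance = 1e-10)
})

test_that("interaction partial F equals the squared slope-difference t", {
  tbl <- make_table(k = 7, sigma = 0.8, seed = 7)
  fit <- dispersion_ancova(tbl)
  Fint <- fit$terms$F[fit$terms$term == "community_type:seep_index"]
  expect_equal(Fint, fit$slope_difference$t^2, tolerance = 1e-10)
  expect_equal(fit$terms$p[fit$terms$term == "community_type:seep_index"],
               fit$slope_difference$p, tolerance = 1e-10)
})

test_that("ANCOVA rejects degenerate designs", {
  tbl <- make_table(k = 5)
  tbl$seep_index <- 1
  expect_error(dispersion_ancova(tbl), "constant")
  one <- make_table(k = 5)
  one <- one[one$community_type == "observed", ]
  expect_error(dispersion_ancova(one), "both community types")
})

test_that("interaction detection approaches the nominal power of the t test", {
  # observed slope -1, null slope 0, known sigma: the slope-difference
  # contrast has se = sigma * sqrt(2 / Sxx); compare empirical detection
  # to the closed-form power of that t test.
  k <- 10; sigma <- 1
  idx <- seq(-2, 2, length.out = k)
  Sxx <- sum((idx - mean(idx))^2)
  ncp <- 1 / (sigma * sqrt(2 / Sxx))
  df <- 2 * k - 4
  tcrit <- qt(0.975, df)
  power <- 1 - pt(tcrit, df, ncp) + pt(-tcrit, df, ncp)
  set.seed(123)
  hits <- mean(vapply(1:400, function(i) {
    tbl <- make_table(k = k, sigma = sigma)
    fit <- dispersion_ancova(tbl)
    fit$terms$p[fit$terms$term == "community_type:seep_index"] < 0.05
  }, logical(1)))
  expect_lt(abs(hits - power), 3 * sqrt(power * (1 - power) / 400) + 0.01)
})

test_that("Moran's I has the analytic expectation and detects gradients", {
  set.seed(77)
  coords <- cbind(runif(14, 0, 10), runif(14, 0, 10))
  m <- morans_i(rnorm(14), coords)
  expect_equal(m$expected, -1 / 13, tolerance = 1e-12)
  expect_equal(round(m$expected, 4), -0.0769)

  # a strong smooth spatial gradient is positively autocorrelated
  grad <- coords[, 1] + coords[, 2]
  mg <- morans_i(grad, coords)
  expect_gt(mg$I, mg$expected)
  expect_lt(mg$p, 0.01)

  expect_error(morans_i(rnorm(4), coords[c(1, 1, 2, 3), ]), "oincident")
  expect_error(morans_i(rnorm(3), coords[1:3, ]), "at least 4")

  # permutation p agrees in direction with the normal approximation
  mp <- morans_i(grad, coords, method = "permutation", nperm = 199, seed = 1)
  expect_lt(mp$p, 0.05)
})

test_that("normal-approximation p is calibrated under permutation", {
  set.seed(31)
  n <- 30
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  x <- rnorm(n)
  ps <- vapply(1:500, function(i) morans_i(sample(x), coords)$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
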