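test_that("receptor noise follows the abundance-scaled Weber rule", {
  bee <- synth_bee_system()
  # hand-derived: 0.05 * sqrt(9.375 / c(2.125, 1, 9.375))
  expect_equal(unname(receptor_noise(bee)),
               c(0.1050210, 0.1530931, 0.0500000), tolerance = 1e-5)
  expect_identical(unname(receptor_noise(bee)[["G"]]), 0.05)

  fly <- synth_fly_system()
  # hand-derived: 0.05 * sqrt(2.33 / c(1, 2.33, 1, 2.33))
  expect_equal(unname(receptor_noise(fly)),
               c(0.0763217, 0.05, 0.0763217, 0.05), tolerance = 1e-5)

  eq <- synth_visual_system(c(a = 350, b = 450, c = 550), weber = 0.1,
                            abundances = c(a = 2, b = 2, c = 2))
  expect_equal(unname(receptor_noise(eq)), rep(0.1, 3))

  expect_error(visual_system(synth_bee_system()$sensitivities, 0.05,
                             c(UV = -1, B = 1, G = 2)), "onpositive")
})

test_that("von Kries adaptation anchors signals to the background", {
  bee <- synth_bee_system()
  bkg <- flat_spectrum(0.1)
  irr <- flat_spectrum(1, kind = "irradiance")

  self <- receptor_signals(bkg, bkg, irr, bee)
  expect_equal(unname(self$q), rep(1, 3))
  expect_equal(unname(self$f), rep(0, 3))

  dbl <- receptor_signals(flat_spectrum(0.2), bkg, irr, bee)
  expect_equal(unname(dbl$f), rep(log(2), 3))

  # illuminant intensity cancels out
  set.seed(11)
  wl <- seq(300, 700, by = 1)
  refl <- spectrum(wl, runif(401, 0.05, 0.9))
  a <- receptor_signals(refl, bkg, irr, bee)
  b <- receptor_signals(refl, bkg,
                        spectrum(wl, 2 * irr$value, kind = "irradiance"), bee)
  expect_equal(a$f, b$f)

  zero_bkg <- flat_spectrum(0)
  expect_error(receptor_signals(refl, zero_bkg, irr, bee),
               "zero background quantum catch")
})

test_that("delta_s closed forms match the projection oracle", {
  set.seed(101)
  for (case in seq_len(250)) {
    n <- sample(2:4, 1)
    df <- rnorm(n, 0, 1)
    omega <- runif(n, 0.02, 0.3)
    expect_equal(delta_s(df, rep(0, n), omega), proj_delta_s(df, omega),
                 tolerance = 1e-10)
  }
})

test_that("delta_s is a symmetric, achromatic-invariant metric", {
  omega <- c(0.1050210, 0.1530931, 0.05)
  expect_identical(delta_s(c(1, 2, 3), c(1, 2, 3), omega), 0)
  expect_equal(delta_s(c(0.2, 0), c(0, 0), c(0.05, 0.05)), 2.8284271,
               tolerance = 1e-6)
  fA <- c(0.3, -0.2, 0.5); fB <- c(0.1, 0.4, -0.3)
  expect_equal(delta_s(fA, fB, omega), delta_s(fB, fA, omega))
  # adding a constant to every signal difference changes nothing
  expect_equal(delta_s(fA + 0.7, fB, omega), delta_s(fA, fB, omega))
  expect_error(delta_s(c(1, 2), c(1, 2, 3), c(0.1, 0.1, 0.1)), "length")

  # triangle inequality on random signal triples
  set.seed(55)
  for (i in 1:100) {
    f1 <- rnorm(3); f2 <- rnorm(3); f3 <- rnorm(3)
    expect_lte(delta_s(f1, f3, omega),
               delta_s(f1, f2, omega) + delta_s(f2, f3, omega) + 1e-12)
  }
})

test_that("delta_s is invariant to brightness and sensitivity scaling", {
  set.seed(21)
  bee <- synth_bee_system()
  wl <- seq(300, 700, by = 1)
  bkg <- spectrum(wl, 0.04 + 0.08 * exp(-((wl - 550) / 35)^2))
  irr <- flat_spectrum(1, kind = "irradiance")
  r1 <- spectrum(wl, runif(401, 0.05, 0.9))
  r2 <- spectrum(wl, runif(401, 0.05, 0.9))
  omega <- receptor_noise(bee)
  ds <- function(a, b, vs, ill = irr)
    delta_s(receptor_signals(a, bkg, ill, vs)$f,
            receptor_signals(b, bkg, ill, vs)$f, receptor_noise(vs))
  base <- ds(r1, r2, bee)
  half <- spectrum(wl, r1$value * 0.5)
  expect_equal(ds(half, r2, bee), base, tolerance = 1e-12)
  bright <- spectrum(wl, 3 * irr$value, kind = "irradiance")
  expect_equal(ds(r1, r2, bee, bright), base, tolerance = 1e-12)

  # per-receptor sensitivity rescaling cancels under von Kries
  sens <- bee$sensitivities
  sens$UV <- spectrum(sens$UV$wl, sens$UV$value * 5, kind = "sensitivity")
  bee2 <- visual_system(sens, bee$weber, bee$abundances, bee$reference)
  expect_equal(ds(r1, r2, bee2), base, tolerance = 1e-12)
})

test_that("color_distance_matrix is symmetric with zero diagonal", {
  set.seed(8)
  wl <- seq(300, 700, by = 1)
  spl <- lapply(1:5, function(i) spectrum(wl, runif(401, 0.05, 0.9)))
  names(spl) <- paste0("sp", 1:5)
  bkg <- flat_spectrum(0.1)
  irr <- flat_spectrum(1, kind = "irradiance")
  d <- color_distance_matrix(spl, bkg, irr, synth_fly_system())
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0))
  expect_equal(rownames(d), names(spl))
})

test_that("chromaticity maps catches into the simplex projectively", {
  c3 <- chromaticity(c(1, 1, 1))
  expect_equal(unname(c3$relative), rep(1 / 3, 3))
  expect_equal(unname(c3$coords), c(0.5, sqrt(3) / 6), tolerance = 1e-12)

  near <- chromaticity(c(2, 1e-4, 1e-4))
  expect_lt(sqrt(sum((near$coords - c(0, 0))^2)), 0.01)

  q <- c(0.3, 1.2, 0.5, 2)
  expect_equal(chromaticity(q)$coords, chromaticity(5 * q)$coords)
  expect_equal(sum(chromaticity(q)$relative), 1)
  expect_error(chromaticity(c(1, 0, 1)), "nonpositive")
})
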