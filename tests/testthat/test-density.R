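test_that("baseline density reduces to the z prefactor on the shell", {
  p <- confinement_params(beta_k = 5, L = 11.5)
  d <- free_end_density(data.frame(x = 0, y = 0, z = 11.5), "baseline", p)
  expect_equal(d$density, 11.5)
  ## off the shell the harmonic factor kicks in
  d2 <- free_end_density(data.frame(x = 0, y = 0, z = 12.5), "baseline", p)
  expect_equal(d2$density, 12.5 * exp(-5 / 2 * 1^2))
})

test_that("densities vanish on and beyond their confinement boundaries", {
  p <- paper_params()
  peak <- free_end_density(data.frame(x = 9, y = 0, z = 6), "combined", p)$density
  ## slit boundaries (tail / combined)
  for (scn in c("tail", "combined")) {
    at_bounds <- free_end_density(
      data.frame(x = c(3, 3), y = c(1, 1), z = c(0, 12.5)), scn, p)$density
    expect_lt(max(abs(at_bounds)), 1e-12 * peak)
    beyond <- free_end_density(
      data.frame(x = c(3, 3), y = c(1, 1), z = c(-0.1, 12.6)), scn, p)$density
    expect_identical(beyond, c(0, 0))
  }
  ## trench walls
  for (scn in c("trench", "combined")) {
    at_walls <- free_end_density(
      data.frame(x = c(5, 5), y = c(-4.5, 4.5), z = c(3, 3)), scn, p)$density
    expect_lt(max(abs(at_walls)), 1e-12 * peak)
    outside <- free_end_density(
      data.frame(x = 5, y = 4.6, z = 3), scn, p)$density
    expect_identical(outside, 0)
  }
  ## below the substrate everything is zero
  below <- free_end_density(data.frame(x = 1, y = 1, z = -2), "baseline", p)
  expect_identical(below$density, 0)
})

test_that("density evaluation is non-negative and rejects bad input", {
  p <- paper_params()
  withr::with_seed(42, {
    pts <- data.frame(x = runif(500, -15, 15), y = runif(500, -15, 15),
                      z = runif(500, -2, 15))
  })
  for (scn in c("baseline", "tail", "trench", "combined"))
    expect_true(all(free_end_density(pts, scn, p)$density >= 0))
  expect_error(free_end_density(data.frame(x = NA, y = 0, z = 1),
                                "baseline", p), "non-finite")
  expect_error(confinement_params(beta_k = -5, L = 11.5), "positive")
  expect_error(validate_scenario("tail", confinement_params(beta_k = 5, L = 11.5)),
               "z_max|beta_k_prime")
  expect_error(validate_scenario("trench_series", paper_params()),
               "beta_k_dprime")
})

test_that("combined density factorizes into tail times the trench cosine", {
  p <- paper_params()
  withr::with_seed(7, {
    pts <- data.frame(x = runif(300, -14, 14), y = runif(300, -4.5, 4.5),
                      z = runif(300, 0, 12.5))
  })
  comb <- free_end_density(pts, "combined", p)$density
  tail_d <- free_end_density(pts, "tail", p)$density
  expect_equal(comb, tail_d * cos(pi * pts$y / p$h_max), tolerance = 1e-12)
})

test_that("trench and combined converge pointwise to baseline and tail as the trench widens", {
  p_wide <- paper_params(h_max = 1000)
  p <- paper_params()
  withr::with_seed(11, {
    pts <- data.frame(x = runif(300, -14, 14), y = runif(300, -12, 12),
                      z = runif(300, 0.2, 12))
  })
  tr <- free_end_density(pts, "trench", p_wide)$density
  ba <- free_end_density(pts, "baseline", p)$density
  expect_equal(tr, ba, tolerance = 1e-3)
  co <- free_end_density(pts, "combined", p_wide)$density
  ta <- free_end_density(pts, "tail", p)$density
  expect_equal(co, ta, tolerance = 1e-3)
})

test_that("normalization constant matches a Monte-Carlo estimate", {
  p <- confinement_params(beta_k = 5, L = 11.5)
  Z <- normalization_constant("baseline", p)
  box <- bounding_box(p, "baseline")
  vol <- diff(box$xlim) * diff(box$ylim) * diff(box$zlim)
  withr::with_seed(99, {
    n <- 1e6
    f <- free_end_density(
      data.frame(x = runif(n, box$xlim[1], box$xlim[2]),
                 y = runif(n, box$ylim[1], box$ylim[2]),
                 z = runif(n, box$zlim[1], box$zlim[2])),
      "baseline", p)$density
  })
  expect_equal(Z, vol * mean(f), tolerance = 0.01)
})

test_that("wide-trench normalization constant recovers the baseline constant", {
  p <- confinement_params(beta_k = 5, L = 11.5, h_max = 1000)
  Z_tr <- normalization_constant("trench", p)
  Z_ba <- normalization_constant("baseline", p)
  expect_equal(Z_tr / Z_ba, 1, tolerance = 2e-3)
})

test_that("series truncation clips a negligible mass fraction at canonical parameters", {
  d <- series_clip_diagnostic("tail", paper_params())
  expect_equal(nrow(d), 1L)
  expect_lt(d$clipped_fraction, 1e-3)
  ## a softer tail stiffness keeps more high modes: clipping still tiny
  d2 <- series_clip_diagnostic("combined", paper_params(beta_k_prime = 1.5))
  expect_lt(d2$clipped_fraction, 5e-3)
})

test_that("parameter configs round-trip through yaml and json", {
  p <- paper_params()
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params_config(p, f)
    q <- read_params_config(f)
    expect_equal(unclass(q), unclass(p))
  }
})
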