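test_that("annulus of a pure circle collapses onto its radius", {
  th <- seq(0, 2 * pi, length.out = 1001)[-1]
  ring <- fit_annulus(data.frame(x = 5 * cos(th), y = 5 * sin(th)),
                      coverage = 0.9)
  expect_lt(abs(ring$R_min - 5), 0.05 + 1e-12)
  expect_lt(abs(ring$R_max - 5), 0.05 + 1e-12)
  expect_gte(ring$coverage, 0.9)
})

test_that("annulus of a uniform disk encloses the target area fraction", {
  withr::with_seed(4, {
    r <- sqrt(runif(1e4)); th <- runif(1e4, 0, 2 * pi)
  })
  ring <- fit_annulus(data.frame(x = r * cos(th), y = r * sin(th)),
                      coverage = 0.9)
  expect_equal(pi * (ring$R_max^2 - ring$R_min^2) / pi, 0.9,
               tolerance = 0.025)
})

test_that("annulus coverage preconditions and order statistics hold", {
  withr::with_seed(5, {
    pts <- data.frame(x = rnorm(2000), y = rnorm(2000))
  })
  expect_error(fit_annulus(pts, coverage = 1), "strictly between")
  ring <- fit_annulus(pts, coverage = 0.999)
  r <- sort(sqrt(pts$x^2 + pts$y^2), decreasing = TRUE)
  expect_gte(ring$R_max, r[floor(0.001 * 2000) + 1] - 0.05)
  expect_error(fit_annulus(data.frame(x = rep(1, 50), y = rep(2, 50))),
               "degenerate")
})

test_that("annulus search equals an independent exhaustive scan", {
  brute <- function(pts, coverage, step) {
    r <- sqrt(pts$x^2 + pts$y^2)
    grid <- seq(0, ceiling(max(r) / step) * step, by = step)
    best <- NULL
    for (i in seq_along(grid)) for (j in i:length(grid)) {
      enc <- sum(r >= grid[i] & r <= grid[j])
      if (enc >= ceiling(coverage * length(r))) {
        area <- grid[j]^2 - grid[i]^2
        if (is.null(best) || area < best$area - 1e-12 ||
            (abs(area - best$area) <= 1e-12 &&
             (grid[j] < best$R_max - 1e-12 ||
              (abs(grid[j] - best$R_max) <= 1e-12 &&
               grid[i] > best$R_min + 1e-12))))
          best <- list(R_min = grid[i], R_max = grid[j], area = area)
      }
    }
    best
  }
  for (seed in 1:3) {
    withr::with_seed(seed, {
      pts <- data.frame(x = rnorm(400, sd = 2), y = rnorm(400, sd = 2))
    })
    got <- fit_annulus(pts, coverage = 0.85, grid_step = 0.25)
    want <- brute(pts, coverage = 0.85, step = 0.25)
    expect_equal(got$R_min, want$R_min)
    expect_equal(got$R_max, want$R_max)
  }
})

test_that("baseline parameters are recovered from a synthetic cloud", {
  truth <- confinement_params(beta_k = 5, L = 11.5)
  cloud <- sample_free_end("baseline", truth, 1e5, seed = 43)
  fit <- fit_parameters(cloud, "baseline", free = c("beta_k", "L"),
                        init = confinement_params(beta_k = 3, L = 9))
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "L"], truth$L, tolerance = 0.05)
  expect_equal(est$estimate[est$term == "beta_k"], truth$beta_k,
               tolerance = 0.05)
  expect_equal(glance(fit)$convergence, 0L)
})

test_that("an empty free set evaluates the objective without optimizing", {
  truth <- confinement_params(beta_k = 5, L = 11.5)
  cloud <- sample_free_end("baseline", truth, 5000, seed = 42)
  fit <- fit_parameters(cloud, "baseline", free = character(0), init = truth)
  expect_equal(unclass(fit$params), unclass(truth))
  expect_true(is.finite(fit$objective))
  ## the truth should fit better than a clearly wrong parameter set
  wrong <- fit_parameters(cloud, "baseline", free = character(0),
                          init = confinement_params(beta_k = 5, L = 8))
  expect_lt(fit$objective, wrong$objective)
})

test_that("mode detection resolves constructed mixtures and is scale invariant", {
  g <- seq(-10, 10, length.out = 401)
  dens <- 0.5 * stats::dnorm(g, -3, 0.5) + 0.5 * stats::dnorm(g, 3, 0.5)
  m <- data.frame(value = g, density = dens)
  modes <- detect_modes(m)
  expect_equal(nrow(modes), 2L)
  expect_lt(max(abs(abs(modes$location) - 3)), diff(g[1:2]) + 1e-9)
  ## rescaling the density changes nothing
  m2 <- data.frame(value = g, density = 17 * dens)
  expect_equal(detect_modes(m2)$location, modes$location)
  ## refining the grid twofold keeps both modes in place
  g2 <- seq(-10, 10, length.out = 801)
  dens2 <- 0.5 * stats::dnorm(g2, -3, 0.5) + 0.5 * stats::dnorm(g2, 3, 0.5)
  modes2 <- detect_modes(data.frame(value = g2, density = dens2))
  expect_equal(nrow(modes2), 2L)
  expect_lt(max(abs(modes2$location - modes$location)), diff(g[1:2]) + 1e-9)
  ## a flat density has no modes
  expect_equal(nrow(detect_modes(data.frame(value = g, density = rep(1, 401)))),
               0L)
})
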