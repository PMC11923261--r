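test_that("with the target at the tether the radial mode sits on the shell", {
  p <- confinement_params(beta_k = 5, L = 11.5)
  rp <- radial_equilibrium_density("baseline", p, target_geometry(0, 2))
  w <- rp$rho^2 * rp$p_eq
  mode <- rp$rho[which.max(w)]
  step <- max(diff(rp$rho[which.max(w) + c(-1, 0, 1)]))
  expect_lt(abs(mode - p$L), step + 1e-9)
  expect_equal(pracma::trapz(rp$rho, w), 1, tolerance = 1e-4)
})

test_that("radial density matches a sampled distance-to-target histogram", {
  p <- confinement_params(beta_k = 5, L = 11.5)
  geom <- target_geometry(11.5, 2)
  rp <- radial_potential("baseline", p, geom)
  n <- 2e5
  cloud <- sample_free_end("baseline", p, n, seed = 31)
  rho_s <- sqrt((cloud$x - geom$a)^2 + cloud$y^2 + cloud$z^2)
  inside <- rho_s >= geom$epsilon          # model conditions on rho >= eps
  breaks <- seq(geom$epsilon, attr(rp, "rho_max"), length.out = 41)
  counts <- graphics::hist(rho_s[inside], breaks = breaks, plot = FALSE)$counts
  n_in <- sum(inside)
  w_fun <- approxfun(rp$rho, rp$rho^2 * rp$p_eq)
  expected <- vapply(seq_len(40), function(i) {
    g <- seq(breaks[i], breaks[i + 1], length.out = 20)
    pracma::trapz(g, w_fun(g))
  }, numeric(1))
  expected <- expected / sum(expected) * n_in
  se <- sqrt(pmax(expected * (1 - expected / n_in), 1))
  expect_true(all(abs(counts - expected) < 3 * se + 3))
})

test_that("angular reduction agrees with brute-force Cartesian shell binning", {
  cases <- list(
    list(scn = "baseline", p = confinement_params(beta_k = 4, L = 10), a = 9),
    list(scn = "tail", p = confinement_params(beta_k = 5, L = 11.5,
                                              beta_k_prime = 0.9, z_max = 11),
         a = 12),
    list(scn = "combined", p = paper_params(), a = 10))
  for (cs in cases) {
    geom <- target_geometry(cs$a, 2)
    rho_max <- cs$a + cs$p$L + 6 / sqrt(cs$p$beta_k)
    edges <- seq(2, rho_max, length.out = 201)
    ## per-shell masses integrated on a radial grid of 5 points per shell
    ## (the radial density has kinks where confinement limits activate)
    fine <- seq(2, rho_max, length.out = 1001)
    rp <- radial_equilibrium_density(cs$scn, cs$p, geom, rho_grid = fine)
    w <- rp$rho^2 * rp$p_eq
    mass_quad <- vapply(seq_len(200), function(i) {
      sel <- (5 * (i - 1) + 1):(5 * (i - 1) + 6)   # 5 sub-intervals per shell
      pracma::trapz(fine[sel], w[sel])
    }, numeric(1))
    mass_quad <- mass_quad / sum(mass_quad)
    ## brute force: Cartesian cell decomposition of the box with one
    ## uniformly jittered evaluation point per cell (stratified sampling,
    ## which avoids aliasing the thin shell against the cell grid), binned
    ## into spherical shells about the target (full phi range, y < 0 too)
    box <- bounding_box(cs$p, cs$scn, a_max = cs$a)
    ng <- 200
    hx <- diff(box$xlim) / ng; hy <- diff(box$ylim) / ng
    hz <- diff(box$zlim) / ng
    cx <- box$xlim[1] + (seq_len(ng) - 1) * hx
    cy <- box$ylim[1] + (seq_len(ng) - 1) * hy
    cz <- box$zlim[1] + (seq_len(ng) - 1) * hz
    mass_bin <- numeric(200)
    withr::with_seed(1000 + cs$a, {
      for (zz in cz) for (pair in 1:2) {
        ux <- runif(ng^2); uy <- runif(ng^2); uz <- runif(ng^2)
        for (anti in c(FALSE, TRUE)) {       # antithetic pair per cell
          if (anti) { ux <- 1 - ux; uy <- 1 - uy; uz <- 1 - uz }
          X <- rep(cx, times = ng) + ux * hx
          Y <- rep(cy, each = ng) + uy * hy
          Z <- zz + uz * hz
          f <- free_end_density(cbind(X, Y, Z), cs$scn, cs$p)$density
          r <- sqrt((X - cs$a)^2 + Y^2 + Z^2)
          sel <- r >= edges[1] & r < edges[201] & f > 0
          if (any(sel)) {
            idx <- findInterval(r[sel], edges, rightmost.closed = TRUE)
            mass_bin <- mass_bin + tapply(f[sel], factor(idx, levels = 1:200),
                                          sum, default = 0)
          }
        }
      }
    })
    mass_bin <- mass_bin / sum(mass_bin)
    expect_lt(sum(abs(mass_bin - mass_quad)), 1e-2)
  }
})

test_that("degenerate landscapes surface as errors, not as numbers", {
  ## a vanishing tail stiffness damps every slit mode to zero: the density
  ## carries no mass anywhere on the radial grid
  p_dead <- confinement_params(beta_k = 5, L = 11.5, beta_k_prime = 0.01,
                               z_max = 12.5)
  expect_error(
    radial_equilibrium_density("tail", p_dead, target_geometry(11.5, 2)),
    "empty radial support")
  ## a far-away target keeps the shell inside the radial domain but the
  ## contact distance itself is never visited
  p <- confinement_params(beta_k = 5, L = 11.5)
  rp_far <- radial_potential("baseline", p, target_geometry(500, 2))
  expect_false(rp_far$reachable[1])
  expect_error(szabo_mfpt(rp_far, paper_kinetics()), "unreachable")
})

test_that("effective potential obeys the log rules", {
  ## flat radial density: constant potential log(b - eps)
  rp <- flat_potential(eps = 2, b = 12)
  expect_equal(rp$beta_u, rep(log(10), nrow(rp)), tolerance = 1e-9)
  ## doubling p_eq lowers beta_u by log(2) everywhere
  doubled <- walkerkinetics:::new_radial_potential(
    tibble::tibble(rho = rp$rho, p_eq = 2 * rp$p_eq, beta_u = NA_real_,
                   reachable = NA),
    scenario = "manual", params = NULL, geom = attr(rp, "geom"),
    rho_max = attr(rp, "rho_max"))
  doubled <- effective_potential(doubled)
  expect_equal(doubled$beta_u, rp$beta_u - log(2), tolerance = 1e-12)
  ## the potential minimum coincides with the radial-density mode
  p <- confinement_params(beta_k = 5, L = 11.5)
  rpb <- radial_potential("baseline", p, target_geometry(11.5, 2))
  expect_equal(which.min(rpb$beta_u), which.max(rpb$rho^2 * rpb$p_eq))
})

test_that("radial potentials round-trip through CSV", {
  rp <- radial_potential("tail", paper_params(), target_geometry(10, 2),
                         n_rho = 50)
  f <- tempfile(fileext = ".csv")
  write_radial_potential(rp, f)
  back <- read_radial_potential(f)
  expect_equal(back$rho, rp$rho, tolerance = 1e-9)
  expect_equal(back$p_eq, rp$p_eq, tolerance = 1e-9)
  expect_equal(attr(back, "scenario"), "tail")
  expect_equal(attr(back, "geom")$a, 10)
})
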