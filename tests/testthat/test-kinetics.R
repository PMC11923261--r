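test_that("Szabo time on a flat potential matches the closed form", {
  eps <- 2; b <- 12; D <- 5e7; kappa <- 1
  rp <- flat_potential(eps, b, n = 400)
  res <- szabo_mfpt(rp, kinetic_params(D = D, kappa = kappa))
  closed_diff <- (b - eps)^2 / (3 * D)
  closed_react <- (b - eps) / kappa
  expect_equal(res$tau_diffusion, closed_diff, tolerance = 1e-3)
  expect_equal(res$tau_reaction, closed_react, tolerance = 1e-3)
  expect_equal(res$tau, res$tau_diffusion + res$tau_reaction)
})

test_that("infinite reactivity removes the rebound term", {
  rp <- flat_potential()
  res <- szabo_mfpt(rp, kinetic_params(D = 5e7, kappa = 1e15))
  expect_lt(res$tau_reaction / res$tau_diffusion, 1e-6)
  expect_equal(res$tau, res$tau_diffusion, tolerance = 1e-6)
})

test_that("stepping is reaction-limited at canonical parameters", {
  rp <- radial_potential("baseline", confinement_params(beta_k = 5, L = 11.5),
                         target_geometry(11.5, 2))
  res <- szabo_mfpt(rp, paper_kinetics())
  expect_gt(res$tau_reaction / res$tau_diffusion, 1e3)
})

test_that("stepping time decreases with reactivity and diffusivity", {
  rp <- radial_potential("baseline", confinement_params(beta_k = 5, L = 11.5),
                         target_geometry(11.5, 2))
  taus_k <- vapply(c(1, 10, 100, 1e4),
                   function(k) szabo_mfpt(rp, kinetic_params(D = 5e7,
                                                             kappa = k))$tau,
                   numeric(1))
  expect_true(all(diff(taus_k) < 0))
  taus_D <- vapply(c(1e6, 1e7, 1e8),
                   function(D) szabo_mfpt(rp, kinetic_params(D = D,
                                                             kappa = 1e6))$tau,
                   numeric(1))
  expect_true(all(diff(taus_D) < 0))
})

test_that("regime ratio follows its defining arithmetic", {
  p <- confinement_params(beta_k = 5, L = 11.5)
  expect_equal(regime_ratio(p, kinetic_params(D = 5e7, kappa = 10)),
               5e7 * sqrt(5) / 10)
  expect_equal(regime_ratio(p, kinetic_params(D = 5e7, kappa = 20)),
               regime_ratio(p, kinetic_params(D = 5e7, kappa = 10)) / 2)
  p4 <- confinement_params(beta_k = 20, L = 11.5)
  expect_equal(regime_ratio(p4, kinetic_params(D = 5e7, kappa = 10)),
               2 * regime_ratio(p, kinetic_params(D = 5e7, kappa = 10)))
})

test_that("normalized rate is unity for the baseline and in the wide-trench limit", {
  p <- paper_params()
  kin <- paper_kinetics()
  geom <- target_geometry(11.5, 2)
  expect_identical(normalized_rate("baseline", p, kin, geom), 1)
  p_wide <- paper_params(h_max = 1000)
  expect_equal(normalized_rate("trench", p_wide, kin, geom), 1,
               tolerance = 1e-2)
})

test_that("full Szabo ratio agrees with the contact-density ratio when reaction-limited", {
  p <- paper_params()
  kin <- paper_kinetics()
  geom <- target_geometry(11.5, 2)
  expect_gt(regime_ratio(p, kin), 1e4)
  full <- normalized_rate("tail", p, kin, geom, method = "szabo")
  contact <- normalized_rate("tail", p, kin, geom, method = "contact")
  expect_equal(full / contact, 1, tolerance = 0.01)
})

test_that("rate sweeps produce a complete flagged table", {
  p <- confinement_params(beta_k = 5, L = 11.5)
  kin <- paper_kinetics()
  tab <- sweep_rates("baseline", p, kin, a_grid = 11.5, epsilon = 2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$normalized_rate, 1)
  expect_true(tab$ok)
  expect_equal(tab$tau, tab$tau_diffusion + tab$tau_reaction)
  ## a target far outside the reachable shell is flagged, not dropped
  tab2 <- sweep_rates("baseline", p, kin, a_grid = c(11.5, 500), epsilon = 2)
  expect_equal(nrow(tab2), 2L)
  expect_false(tab2$ok[tab2$a == 500])
  f <- tempfile(fileext = ".csv")
  write_rate_table(tab2, f)
  expect_equal(names(readr::read_csv(f, show_col_types = FALSE)),
               c("scenario", "a", "epsilon", "tau", "tau_diffusion",
                 "tau_reaction", "normalized_rate", "ok"))
})
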