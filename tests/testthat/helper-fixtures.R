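## Shared fixtures: the canonical parameter set of the 36-bp walker-foothold
## complex (12-bp tail, 9-nm trench) and small construction helpers.

paper_params <- function(...) {
  base <- list(beta_k = 5, L = 11.5, beta_k_prime = 0.75,
               z_max = 12.5, h_max = 9, n_terms = 20)
  do.call(confinement_params, utils::modifyList(base, list(...)))
}

paper_kinetics <- function() kinetic_params(D = 5e7, kappa = 1)

## flat effective potential on [eps, b]: p_eq proportional to 1/rho^2
flat_potential <- function(eps = 2, b = 12, n = 400) {
  rho <- seq(eps, b, length.out = n)
  manual_radial_potential(rho, 1 / rho^2)
}

## coarse linear radial grid so the BD step respects the resolution guard
bd_radial_potential <- function(scenario, params, geom, n = 150) {
  rho_max <- geom$a + params$L + 6 / sqrt(params$beta_k)
  radial_potential(scenario, params, geom,
                   rho_grid = seq(geom$epsilon, rho_max, length.out = n))
}

## independent expectation of a function f(x, y, z) under a scenario density
## by tensor Gauss-Legendre quadrature over the bounding box
box_expectation <- function(f, scenario, params, n_nodes = 64) {
  box <- bounding_box(params, scenario)
  g <- function(lim) pracma::gaussLegendre(n_nodes, lim[1], lim[2])
  gx <- g(box$xlim); gy <- g(box$ylim); gz <- g(box$zlim)
  X <- rep(gx$x, times = n_nodes); Y <- rep(gy$x, each = n_nodes)
  W <- rep(gx$w, times = n_nodes) * rep(gy$w, each = n_nodes)
  num <- 0; den <- 0
  for (k in seq_len(n_nodes)) {
    zz <- rep(gz$x[k], length(X))
    d <- free_end_density(cbind(X, Y, zz), scenario, params)$density
    num <- num + gz$w[k] * sum(W * d * f(X, Y, zz))
    den <- den + gz$w[k] * sum(W * d)
  }
  num / den
}

## minimal oxDNA configuration/topology fixture writer; positions is a list
## of n_frames matrices (n_nt x 3) in oxDNA length units
write_oxdna_fixture <- function(positions, n_nt, dir = tempdir()) {
  conf <- file.path(dir, "fixture.conf")
  top <- file.path(dir, "fixture.top")
  writeLines(c(paste(n_nt, 1), paste("1 A", -1, 1)), top)
  lines <- character(0)
  for (fr in seq_along(positions)) {
    m <- positions[[fr]]
    lines <- c(lines,
               paste0("t = ", fr * 100),
               "b = 50 50 50",
               "E = 0 0 0",
               apply(m, 1, function(r)
                 paste(c(r, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
                       collapse = " ")))
  }
  writeLines(lines, conf)
  list(conf = conf, top = top)
}
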