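# Compact constructors for two-species parameter sets used across tests.
exp_cpl <- function(mu, xi = 1, alpha = 0)
  interaction(mu, xi, alpha, kernel_spec("exponential", xi))
top_cpl <- function(mu, xi = 1, alpha = 0)
  interaction(mu, xi, alpha, kernel_spec("tophat", xi))

make_params <- function(mucc = 1, mucr = 0.5, murc = -0.5, murr = 1,
                        acc = 0, acr = 0, arc = 0, arr = 0,
                        xi = 1, D = 1, C = 0.2, P = 0.2, L = 8,
                        sensing = "direct", fam = "exponential",
                        volume_filling = "linear", xiv = NULL) {
  if (is.null(xiv)) xiv <- rep(xi, 4)
  cpl <- if (fam == "exponential") {
    function(mu, x, a) interaction(mu, x, a, kernel_spec("exponential", x))
  } else {
    function(mu, x, a) interaction(mu, x, a, kernel_spec("tophat", x))
  }
  two_species_params(D = D,
                     cc = cpl(mucc, xiv[1], acc), cr = cpl(mucr, xiv[2], acr),
                     rc = cpl(murc, xiv[3], arc), rr = cpl(murr, xiv[4], arr),
                     C = C, P = P, L = L, sensing = sensing,
                     volume_filling = volume_filling)
}

# Build a chiral_trajectory by hand from a list of (c, rho) matrices, for
# diagnostics tests that do not need the solver.
make_synthetic_trajectory <- function(c_list, rho_list, times, grid) {
  nt <- length(times)
  N <- grid$N
  carr <- array(0, dim = c(nt, N, N))
  rarr <- array(0, dim = c(nt, N, N))
  for (i in seq_len(nt)) {
    carr[i, , ] <- c_list[[i]]
    rarr[i, , ] <- rho_list[[i]]
  }
  mass_c <- apply(carr, 1, sum) * grid$h^2
  mass_r <- apply(rarr, 1, sum) * grid$h^2
  structure(list(times = times, c = carr, rho = rarr,
                 mass = tibble::tibble(t = times, mass_c = mass_c,
                                       mass_rho = mass_r,
                                       drift_c = abs(mass_c / mass_c[1] - 1),
                                       drift_rho = abs(mass_r / mass_r[1] - 1)),
                 params = NULL, grid = grid, seed = NA, sigma = NA,
                 rtol = 1e-6, atol = 1e-8, method = "synthetic",
                 flags = list()),
            class = "chiral_trajectory")
}

# Periodic Gaussian bump of width w centred at (x0, y0) on the grid.
periodic_bump <- function(grid, x0, y0, w = 0.8, height = 1) {
  d2 <- function(a, b) {
    d <- abs(a - b)
    pmin(d, grid$L - d)^2
  }
  X <- matrix(grid$x, grid$N, grid$N)
  Y <- t(X)
  height * exp(-(d2(X, x0) + d2(Y, y0)) / (2 * w^2))
}
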