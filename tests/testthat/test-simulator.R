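test_that("seeded initial conditions are reproducible with the stated noise", {
  g <- sim_grid(100, 10)
  # sigma = 0 gives the exact homogeneous state
  ic0 <- initial_condition(g, C = 0.3, P = 0.1, sigma = 0)
  expect_identical(ic0$c, matrix(0.3, 100, 100))
  expect_identical(ic0$rho, matrix(0.1, 100, 100))
  # identical seeds give bit-identical states, different seeds differ
  a <- initial_condition(g, 0.2, 0.2, seed = 42)
  b <- initial_condition(g, 0.2, 0.2, seed = 42)
  expect_identical(a$c, b$c)
  expect_identical(a$rho, b$rho)
  expect_false(identical(a$c, initial_condition(g, 0.2, 0.2, seed = 43)$c))
  # the c and rho noise draws are independent
  expect_false(identical(a$c - 0.2, a$rho - 0.2))
  # sample mean within 5 standard errors of the homogeneous state
  expect_lt(abs(mean(a$c) - 0.2), 5 * 1e-3 / 100)
  expect_lt(abs(mean(a$rho) - 0.2), 5 * 1e-3 / 100)
  expect_error(initial_condition(g, 0.2, 0.2, sigma = -1), "non-negative")
})

test_that("the rhs vanishes identically at the homogeneous state", {
  g <- sim_grid(32, 8)
  for (sensing in c("direct", "gradient")) {
    p <- make_params(acr = -20, arc = 70, sensing = sensing)
    st <- initial_condition(g, p$C, p$P, sigma = 0)
    d <- rhs(st, p)
    expect_lt(max(abs(d$dc)), 1e-12)
    expect_lt(max(abs(d$drho)), 1e-12)
  }
})

test_that("the transport rhs conserves mass pointwise in time", {
  g <- sim_grid(32, 8)
  set.seed(19)
  for (sensing in c("direct", "gradient")) {
    p <- make_params(mucc = 5, mucr = 3, murc = -2, murr = 4, acr = -20,
                     arc = 70, sensing = sensing)
    st <- initial_condition(g, p$C, p$P, sigma = 0.05, seed = 19)
    d <- rhs(st, p)
    expect_lt(abs(sum(d$dc)), 1e-12)
    expect_lt(abs(sum(d$drho)), 1e-12)
  }
})

test_that("two-species rhs with zero cross-coupling reduces to the single-species model", {
  # independent single-species oracle: brute-force nonlocal sum and naive
  # periodic differences of density * (1 - density) * mu/xi^2 * sum shat W
  N <- 16
  L <- 8
  g <- sim_grid(N, L)
  xi <- 1
  mu <- 2.5
  set.seed(8)
  f <- matrix(runif(N * N, 0.1, 0.3), N, N)
  spec <- kernel_spec("exponential", xi)
  sx <- matrix(g$s, N, N)
  sy <- t(sx)
  r <- sqrt(sx^2 + sy^2)
  w <- kernel_value(spec, r) / xi^2 * g$h^2
  w[r >= L / 2] <- 0 # truncation disc, Nyquist ring excluded
  kx <- ifelse(r > 0, sx / r, 0) * w
  ky <- ifelse(r > 0, sy / r, 0) * w
  vx <- vy <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    acc_x <- 0
    acc_y <- 0
    for (a in 1:N) for (b in 1:N) {
      fs <- f[((i - 1 + a - 1) %% N) + 1, ((j - 1 + b - 1) %% N) + 1]
      acc_x <- acc_x + kx[a, b] * fs
      acc_y <- acc_y + ky[a, b] * fs
    }
    vx[i, j] <- mu * acc_x
    vy[i, j] <- mu * acc_y
  }
  shift <- function(m, di, dj) {
    m[((seq_len(N) - 1 + di) %% N) + 1, ((seq_len(N) - 1 + dj) %% N) + 1]
  }
  phi <- 1 - f
  fx <- f * phi * vx
  fy <- f * phi * vy
  lap <- (shift(f, 1, 0) + shift(f, -1, 0) + shift(f, 0, 1) +
            shift(f, 0, -1) - 4 * f) / g$h^2
  div <- (shift(fx, 1, 0) - shift(fx, -1, 0)) / (2 * g$h) +
    (shift(fy, 0, 1) - shift(fy, 0, -1)) / (2 * g$h)
  oracle <- lap - div

  p <- two_species_params(D = 1, cc = interaction(mu, xi),
                          cr = interaction(0, xi), rc = interaction(0, xi),
                          rr = interaction(0, xi), C = 0.2, P = 0, L = L)
  st <- field_state(f, matrix(0, N, N), 0, g)
  d <- rhs(st, p)
  expect_equal(d$dc, oracle, tolerance = 1e-10)
  expect_equal(d$drho, matrix(0, N, N))
})

test_that("pure diffusion decays each mode at the discrete heat-equation rate", {
  N <- 32
  L <- 8
  g <- sim_grid(N, L)
  p <- make_params(mucc = 0, mucr = 0, murc = 0, murr = 0, D = 1, L = L)
  X <- matrix(g$x, N, N)
  eps <- 1e-4
  modes <- list(c(1, 0), c(2, 1))
  st <- initial_condition(g, p$C, p$P, sigma = 0)
  for (nm in modes) {
    st$c <- st$c + eps * cos(2 * pi * (nm[1] * X + nm[2] * t(X)) / L)
  }
  tr <- simulate_two_species(p, g, state0 = st, output_times = c(0, 1),
                             rtol = 1e-12, atol = 1e-15)
  for (nm in modes) {
    kd2 <- sum((2 - 2 * cos(2 * pi * nm / N)) / g$h^2)
    z0 <- fft(tr$c[1, , ])[nm[1] + 1, nm[2] + 1]
    z1 <- fft(tr$c[2, , ])[nm[1] + 1, nm[2] + 1]
    expect_equal(Mod(z1 / z0), exp(-kd2), tolerance = 1e-6)
  }
})

test_that("trajectories record strictly increasing times starting at the IC", {
  g <- sim_grid(16, 8)
  p <- make_params(L = 8)
  tr <- simulate_two_species(p, g, output_times = c(0.5, 1), seed = 2)
  expect_equal(tr$times, c(0, 0.5, 1)) # 0 prepended
  ic <- initial_condition(g, p$C, p$P, seed = 2)
  expect_equal(tr$c[1, , ], ic$c)
  expect_equal(tr$rho[1, , ], ic$rho)
  expect_error(simulate_two_species(p, sim_grid(16, 10),
                                    output_times = c(0, 1)), "match")
  # identical seed twice gives bit-identical trajectories
  tr2 <- simulate_two_species(p, g, output_times = c(0.5, 1), seed = 2)
  expect_identical(tr$c, tr2$c)
})

test_that("integration is equivariant under quarter-turn rotations", {
  # rotating the initial condition by 90 degrees about the domain centre and
  # integrating commutes with integrating then rotating (the model is
  # isotropic up to chirality, which is equivariant under proper rotations)
  g <- sim_grid(24, 8)
  rot90 <- function(m) t(m[nrow(m):1, ])
  p <- make_params(mucc = 8, mucr = 4, murc = -4, murr = 6, acr = -20,
                   arc = 70, L = 8)
  st <- initial_condition(g, p$C, p$P, sigma = 0.01, seed = 13)
  st_rot <- field_state(rot90(st$c), rot90(st$rho), 0, g)
  tr <- simulate_two_species(p, g, state0 = st, output_times = c(0, 0.5),
                             rtol = 1e-10, atol = 1e-12)
  tr_rot <- simulate_two_species(p, g, state0 = st_rot,
                                 output_times = c(0, 0.5),
                                 rtol = 1e-10, atol = 1e-12)
  expect_equal(tr_rot$c[2, , ], rot90(tr$c[2, , ]), tolerance = 1e-8)
  expect_equal(tr_rot$rho[2, , ], rot90(tr$rho[2, , ]), tolerance = 1e-8)
})

test_that("flipping every chiral angle mirrors the dynamics", {
  # alpha -> -alpha is equivalent to mirror-reflecting the initial
  # condition, integrating, and reflecting back (parity of the rotation)
  g <- sim_grid(24, 8)
  mirror <- function(m) m[nrow(m):1, ]
  p_plus <- make_params(mucc = 8, mucr = 4, murc = -4, murr = 6,
                        acc = 15, acr = -20, arc = 70, L = 8)
  p_minus <- make_params(mucc = 8, mucr = 4, murc = -4, murr = 6,
                         acc = -15, acr = 20, arc = -70, L = 8)
  st <- initial_condition(g, 0.2, 0.2, sigma = 0.01, seed = 21)
  st_mir <- field_state(mirror(st$c), mirror(st$rho), 0, g)
  tr_plus <- simulate_two_species(p_plus, g, state0 = st,
                                  output_times = c(0, 0.5),
                                  rtol = 1e-10, atol = 1e-12)
  tr_minus <- simulate_two_species(p_minus, g, state0 = st_mir,
                                   output_times = c(0, 0.5),
                                   rtol = 1e-10, atol = 1e-12)
  expect_equal(mirror(tr_minus$c[2, , ]), tr_plus$c[2, , ],
               tolerance = 1e-8)
  expect_equal(mirror(tr_minus$rho[2, , ]), tr_plus$rho[2, , ],
               tolerance = 1e-8)
})

test_that("measure_mode_growth recovers the dispersion relation on a coarse grid", {
  p <- make_params(mucc = 92, mucr = 55.2, murc = -55.2, murr = 0,
                   acr = -20, arc = 70, xi = 1, L = 16)
  g <- sim_grid(32, 16)
  res <- measure_mode_growth(p, g, n = 1, m = 0)
  expect_lt(res$re_rel_err, 0.05)
  expect_lt(res$im_fit, 0.01) # real growth: no phase drift
})
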