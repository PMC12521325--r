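#' Seeded initial condition: homogeneous state plus Gaussian noise
#'
#' The standard starting state for pattern-formation runs: the homogeneous
#' densities `(C, P)` perturbed by independent zero-mean Gaussian noise of
#' standard deviation `sigma` in every cell (default 1e-3), fully
#' reproducible from `seed`.
#'
#' @param grid A [sim_grid()].
#' @param C,P Homogeneous chaser and runner densities (>= 0).
#' @param sigma Noise standard deviation (>= 0; 0 gives the exact
#'   homogeneous state).
#' @param seed Integer seed.
#' @return An object of class `field_state`: matrices `c`, `rho`, time `t =
#'   0`, and the grid.
#' @examples
#' ic <- initial_condition(sim_grid(16, 8), C = 0.2, P = 0.2, seed = 1)
#' @export
initial_condition <- function(grid, C, P, sigma = 1e-3, seed = 1L) {
  stopifnot(inherits(grid, "sim_grid"), C >= 0, P >= 0)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("noise scale `sigma` must be non-negative", call. = FALSE)
  N <- grid$N
  if (sigma == 0) {
    cc <- matrix(C, N, N)
    rr <- matrix(P, N, N)
  } else {
    rng <- .seeded_rng(seed)
    cc <- matrix(C + sigma * rng(N * N), N, N)
    rr <- matrix(P + sigma * rng(N * N), N, N)
  }
  field_state(cc, rr, t = 0, grid = grid)
}

# All randomness in the package flows through one seeded generator.
.seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
}

#' Construct a field state
#'
#' @param c,rho `N x N` density matrices for chasers and runners.
#' @param t Time stamp.
#' @param grid The [sim_grid()] the fields live on.
#' @return An object of class `field_state`.
#' @export
field_state <- function(c, rho, t = 0, grid) {
  stopifnot(is.matrix(c), is.matrix(rho), all(dim(c) == dim(rho)),
            inherits(grid, "sim_grid"), all(dim(c) == c(grid$N, grid$N)),
            all(is.finite(c)), all(is.finite(rho)))
  structure(list(c = c, rho = rho, t = t, grid = grid),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf(
    "<field_state> t = %g on %dx%d grid; c in [%.4g, %.4g], rho in [%.4g, %.4g]\n",
    x$t, x$grid$N, x$grid$N, min(x$c), max(x$c), min(x$rho), max(x$rho)))
  invisible(x)
}

#' Precompute the discrete nonlocal operators for a parameter set
#'
#' Tabulates the four coupling kernels on the grid (rotated vector kernels
#' for direct sensing, scalar kernels for gradient sensing) with their FFT
#' spectra, so the right-hand side can be evaluated repeatedly at FFT cost.
#'
#' @param params A [two_species_params()] object.
#' @param grid A [sim_grid()].
#' @return An opaque list of class `nonlocal_ops` consumed by [rhs()] and
#'   [simulate_two_species()].
#' @export
build_operators <- function(params, grid) {
  stopifnot(inherits(params, "two_species_params"),
            inherits(grid, "sim_grid"))
  ops <- list(params = params, grid = grid)
  for (nm in c("cc", "cr", "rc", "rr")) {
    cp <- params[[nm]]
    ops[[nm]] <- if (params$sensing == "direct") {
      build_direct_kernel(cp$kernel, grid, cp$alpha)
    } else {
      build_gradient_kernel(cp$kernel, grid)
    }
  }
  class(ops) <- "nonlocal_ops"
  ops
}

# Advection velocity induced on species u by coupling `cp` sensing `source`.
.advection <- function(cp, kernel, source, grid, sensing) {
  g_src <- source # identity response
  if (sensing == "direct") {
    v <- convolve_field(g_src, kernel)
    list(x = cp$mu * v$x, y = cp$mu * v$y)
  } else {
    w <- convolve_field(g_src, kernel)
    gr <- fd_gradient(w, grid)
    ca <- cospi(cp$alpha / 180)
    sa <- sinpi(cp$alpha / 180)
    list(x = cp$mu * (ca * gr$x - sa * gr$y),
         y = cp$mu * (sa * gr$x + ca * gr$y))
  }
}

#' Right-hand side of the two-species chiral model
#'
#' Method-of-lines spatial discretisation of the governing equations:
#' \deqn{\partial_t c = \nabla^2 c - \nabla\cdot\big(c\,\phi_c\,[v_{cc} +
#'   v_{c\rho}]\big), \quad \partial_t \rho = D \nabla^2 \rho -
#'   \nabla\cdot\big(\rho\,\phi_\rho\,[v_{\rho\rho} + v_{\rho c}]\big),}
#' where each \eqn{v_{uv}} is the nonlocal advection velocity of coupling
#' `uv` (rotated vector-kernel convolution for direct sensing; rotated
#' gradient of a scalar-kernel convolution for gradient sensing). Transport
#' only: both species' grid sums are conserved to machine precision.
#'
#' @param state A [field_state()].
#' @param params A [two_species_params()] object.
#' @param ops Precomputed [build_operators()] for the same `params` and grid
#'   (built on the fly when omitted).
#' @return A list of matrices `dc`, `drho`.
#' @export
rhs <- function(state, params, ops = NULL) {
  stopifnot(inherits(state, "field_state"),
            inherits(params, "two_species_params"))
  if (is.null(ops)) ops <- build_operators(params, state$grid)
  grid <- state$grid
  cc <- state$c
  rr <- state$rho
  phi <- volume_filling_factor(params$volume_filling, cc, rr)
  v_cc <- .advection(params$cc, ops$cc, cc, grid, params$sensing)
  v_cr <- .advection(params$cr, ops$cr, rr, grid, params$sensing)
  v_rr <- .advection(params$rr, ops$rr, rr, grid, params$sensing)
  v_rc <- .advection(params$rc, ops$rc, cc, grid, params$sensing)
  wc <- cc * phi
  wr <- rr * phi
  flux_c <- list(x = wc * (v_cc$x + v_cr$x), y = wc * (v_cc$y + v_cr$y))
  flux_r <- list(x = wr * (v_rr$x + v_rc$x), y = wr * (v_rr$y + v_rc$y))
  list(dc = fd_laplacian(cc, grid) - fd_divergence(flux_c, grid),
       drho = params$D * fd_laplacian(rr, grid) -
         fd_divergence(flux_r, grid))
}

#' Integrate the two-species chiral model in time
#'
#' Method-of-lines integration of [rhs()] with an adaptive variable-order
#' multistep scheme from \pkg{deSolve}. The default `"adams"`
#' (Jacobian-free functional iteration) suits these transport systems, whose
#' step size is limited by advective/diffusive accuracy rather than strong
#' stiffness; the nonlocal coupling makes the Jacobian fully dense, so
#' implicit methods requiring it do not scale to the grid sizes used here.
#'
#' @param params A [two_species_params()] object.
#' @param grid A [sim_grid()]; defaults to 100x100 on the params' domain.
#' @param state0 Initial [field_state()]; defaults to
#'   [initial_condition()] with the params' `(C, P)` and `sigma`, `seed`.
#' @param output_times Strictly increasing times at which to store
#'   snapshots; the first snapshot is the initial condition (a leading 0 is
#'   prepended when missing).
#' @param sigma,seed Initial-condition noise scale and seed (used only when
#'   `state0` is missing).
#' @param rtol,atol Solver tolerances (defaults 1e-6, 1e-8, well below the
#'   1e-3 noise scale).
#' @param method A \pkg{deSolve} method name.
#' @return An object of class `chiral_trajectory`: `times`, arrays `c` and
#'   `rho` (time x N x N), a `mass` tibble with per-species grid mass and
#'   relative drift from t = 0, the `params`, `grid`, `seed`, solver
#'   settings, and diagnostic `flags` (negative densities beyond
#'   `-10 * atol`; total density above carrying capacity).
#' @examples
#' \donttest{
#' p <- two_species_params(cc = interaction(1), cr = interaction(0),
#'                         rc = interaction(0), rr = interaction(1),
#'                         C = 0.2, P = 0.2, L = 8)
#' tr <- simulate_two_species(p, sim_grid(32, 8), output_times = c(0, 1),
#'                            seed = 1)
#' glance(tr)
#' }
#' @export
simulate_two_species <- function(params, grid = NULL, state0 = NULL,
                                 output_times, sigma = 1e-3, seed = 1L,
                                 rtol = 1e-6, atol = 1e-8,
                                 method = "adams") {
  stopifnot(inherits(params, "two_species_params"))
  if (is.null(grid)) grid <- sim_grid(100, params$L)
  if (!isTRUE(all.equal(grid$L, params$L)))
    stop("grid domain length (", grid$L, ") must match params$L (",
         params$L, ")", call. = FALSE)
  if (is.null(state0))
    state0 <- initial_condition(grid, params$C, params$P, sigma, seed)
  stopifnot(inherits(state0, "field_state"))
  output_times <- sort(unique(as.numeric(output_times)))
  if (length(output_times) == 0L || any(output_times < 0))
    stop("`output_times` must be non-negative", call. = FALSE)
  if (output_times[1] > 0) output_times <- c(0, output_times)

  ops <- build_operators(params, grid)
  N <- grid$N
  n2 <- N * N
  y0 <- c(as.vector(state0$c), as.vector(state0$rho))
  deriv <- function(t, y, parms) {
    st <- field_state(matrix(y[1:n2], N, N), matrix(y[(n2 + 1):(2 * n2)], N, N),
                      t = t, grid = grid)
    d <- rhs(st, params, ops)
    list(c(as.vector(d$dc), as.vector(d$drho)))
  }
  sol <- deSolve::ode(y = y0, times = output_times, func = deriv,
                      parms = NULL, method = method, rtol = rtol,
                      atol = atol, maxsteps = 1e6)
  if (attr(sol, "istate")[1] < 0)
    stop("time integration failed: ", paste(
      utils::capture.output(deSolve::diagnostics(sol)), collapse = "\n"),
      call. = FALSE)
  nt <- nrow(sol)
  carr <- array(sol[, 2:(n2 + 1)], dim = c(nt, N, N))
  rarr <- array(sol[, (n2 + 2):(2 * n2 + 1)], dim = c(nt, N, N))
  mass_c <- apply(carr, 1, sum) * grid$h^2
  mass_r <- apply(rarr, 1, sum) * grid$h^2
  mass <- tibble::tibble(
    t = sol[, 1], mass_c = mass_c, mass_rho = mass_r,
    drift_c = abs(mass_c / mass_c[1] - 1),
    drift_rho = abs(mass_r / mass_r[1] - 1))
  min_dens <- min(min(carr), min(rarr))
  max_tot <- max(carr + rarr)
  flags <- list(negative_density = min_dens < -10 * atol,
                above_capacity = params$volume_filling == "linear" &&
                  max_tot > 1,
                min_density = min_dens, max_total_density = max_tot)
  if (flags$negative_density)
    warning("densities fell below -10*atol (min = ", signif(min_dens, 3),
            "); reported as a diagnostic, not corrected", call. = FALSE)
  structure(list(times = sol[, 1], c = carr, rho = rarr, mass = mass,
                 params = params, grid = grid, seed = seed, sigma = sigma,
                 rtol = rtol, atol = atol, method = method, flags = flags),
            class = "chiral_trajectory")
}

#' @export
print.chiral_trajectory <- function(x, ...) {
  cat(sprintf(
    "<chiral_trajectory> %d snapshots on [0, %g], %dx%d grid, %s sensing\n",
    length(x$times), max(x$times), x$grid$N, x$grid$N, x$params$sensing))
  cat(sprintf("  max relative mass drift: c %.2e, rho %.2e\n",
              max(x$mass$drift_c), max(x$mass$drift_rho)))
  invisible(x)
}

#' Extract one snapshot of a trajectory as a field state
#'
#' @param trajectory A `chiral_trajectory`.
#' @param i Snapshot index (default: the last).
#' @return A [field_state()].
#' @export
snapshot <- function(trajectory, i = length(trajectory$times)) {
  stopifnot(inherits(trajectory, "chiral_trajectory"),
            i >= 1, i <= length(trajectory$times))
  field_state(trajectory$c[i, , ], trajectory$rho[i, , ],
              t = trajectory$times[i], grid = trajectory$grid)
}

#' Measure the growth rate of a single linear mode by simulation
#'
#' The central consistency check between the nonlinear simulator and the
#' linear theory: seeds the homogeneous state with a small perturbation
#' along the leading eigenvector of the stability matrix at one admissible
#' wavenumber, integrates the full nonlinear system through the linear
#' regime, and fits the complex growth rate of that Fourier mode. The mode's
#' complex coefficient evolves as \eqn{\hat c(t) = a_c e^{\lambda_+ t}}, so
#' the slope of \eqn{\log|\hat c|} estimates \eqn{\mathrm{Re}\,\lambda_+}
#' and the unwrapped phase drift estimates \eqn{|\mathrm{Im}\,\lambda_+|}.
#'
#' @param params A [two_species_params()] object.
#' @param grid A [sim_grid()] on the params' domain.
#' @param n,m Integer mode indices: wavevector \eqn{2\pi(n, m)/L}.
#' @param eps Seed amplitude (default 1e-6, deep in the linear regime).
#' @param t_fit Fit-window length; defaults to `2 / max(|Re lambda+|, 0.5)`.
#' @param n_snap Snapshots across the window.
#' @param ... Passed to [simulate_two_species()] (tolerances default to
#'   `rtol = 1e-9`, `atol = 1e-12` here: the signal is tiny).
#' @return A one-row tibble: `k`, predicted `re_pred`, `im_pred` (from
#'   [dispersion()]), fitted `re_fit`, `im_fit` (absolute value), and the
#'   relative errors `re_rel_err`, `im_rel_err` (`NA` when the predicted
#'   imaginary part is zero).
#' @export
measure_mode_growth <- function(params, grid, n, m = 0, eps = 1e-6,
                                t_fit = NULL, n_snap = 9, ...) {
  stopifnot(inherits(params, "two_species_params"),
            inherits(grid, "sim_grid"), n == round(n), m == round(m))
  N <- grid$N
  k <- 2 * pi * sqrt(n^2 + m^2) / grid$L
  d <- dispersion(params, k)
  lam <- complex(real = d$re_lambda_plus, imaginary = d$im_lambda_plus)
  ratio <- complex(real = d$amp_ratio_re, imaginary = d$amp_ratio_im)
  if (is.na(ratio)) ratio <- 0 + 0i # decoupled c-equation: pure c mode
  X <- matrix(grid$x, N, N)
  phase <- exp(1i * 2 * pi * (n * X + m * t(X)) / grid$L)
  c0 <- matrix(params$C, N, N) + eps * Re(phase)
  r0 <- matrix(params$P, N, N) + eps * Re(ratio * phase)
  st <- field_state(c0, r0, 0, grid)
  if (is.null(t_fit)) t_fit <- 2 / max(abs(Re(lam)), 0.5)
  tt <- seq(0, t_fit, length.out = n_snap)
  dots <- list(...)
  args <- list(params = params, grid = grid, state0 = st,
               output_times = tt, rtol = 1e-9, atol = 1e-12)
  args[names(dots)] <- dots
  tr <- do.call(simulate_two_species, args)
  z <- vapply(seq_along(tr$times),
              function(i) stats::fft(tr$c[i, , ])[n + 1, m + 1] / N^2,
              complex(1))
  re_fit <- unname(stats::coef(stats::lm(log(Mod(z)) ~ tt))[2])
  dph <- diff(Arg(z))
  dph <- dph - 2 * pi * round(dph / (2 * pi))
  im_fit <- abs(sum(dph) / (max(tt) - min(tt)))
  tibble::tibble(
    k = k, n = n, m = m,
    re_pred = Re(lam), re_fit = re_fit,
    re_rel_err = abs(re_fit / Re(lam) - 1),
    im_pred = abs(Im(lam)), im_fit = im_fit,
    im_rel_err = if (abs(Im(lam)) > 1e-12) abs(im_fit / abs(Im(lam)) - 1)
                 else NA_real_)
}
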