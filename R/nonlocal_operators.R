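#' Periodic simulation grid
#'
#' A cell-centred square grid on the periodic domain \eqn{[0, L]^2} with `N`
#' points per side, spacing `h = L/N`, coordinates `(i - 1/2) h`.
#'
#' @param N Points per side (even, >= 8).
#' @param L Domain length (> 0).
#' @return An object of class `sim_grid` with fields `N`, `L`, `h`, the
#'   coordinate vector `x`, and the signed periodic offset vector `s`
#'   (lattice offsets in FFT order: `0, h, ..., L/2, -(L/2 - h), ..., -h`).
#' @examples
#' g <- sim_grid(64, 16)
#' g$h
#' @export
sim_grid <- function(N, L) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 8, N %% 2 == 0,
            is.numeric(L), length(L) == 1L, L > 0)
  N <- as.integer(N)
  h <- L / N
  idx <- 0:(N - 1L)
  s <- ifelse(idx <= N / 2, idx, idx - N) * h
  structure(list(N = N, L = L, h = h, x = (idx + 0.5) * h, s = s),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d, L = %g, h = %g\n", x$N, x$N, x$L, x$h))
  invisible(x)
}

# Default truncation radius for grid tabulation: half the domain length for
# the exponential family (so two points interact at most once), the kernel's
# own support for the tophat.
.grid_cutoff <- function(spec, grid) {
  if (!is.null(spec$cutoff)) return(min(spec$cutoff, grid$L / 2))
  if (spec$family == "tophat") {
    if (spec$xi >= grid$L / 2)
      stop("tophat range xi = ", spec$xi, " must be below half the domain ",
           "length (L/2 = ", grid$L / 2, ") so any two points interact at ",
           "most once", call. = FALSE)
    min(spec$xi, grid$L / 2)
  } else {
    grid$L / 2
  }
}

#' Tabulate a rotated vector kernel for direct sensing
#'
#' Direct-sensing advection is the lattice sum of rotated unit separation
#' vectors weighted by the kernel: this tabulates
#' \eqn{R(\alpha)\,\hat{s}\; \Omega(|s|/\xi)\, h^2 / \xi^2} at every periodic
#' offset `s` (midpoint sampling times cell area), zero at the origin where
#' \eqn{\hat{s}} is undefined and the continuum integrand is odd, and zero
#' beyond the truncation disc (default radius `L/2` for the exponential
#' family; the tophat's own support otherwise). Forward FFT spectra of both
#' components are precomputed.
#'
#' @param spec A [kernel_spec()].
#' @param grid A [sim_grid()].
#' @param alpha Chiral rotation angle in degrees.
#' @return An object of class `discrete_kernel` with `mode =
#'   "vector_direct"`, component matrices `kx`, `ky`, and their spectra.
#' @export
build_direct_kernel <- function(spec, grid, alpha = 0) {
  stopifnot(inherits(spec, "kernel_spec"), inherits(grid, "sim_grid"))
  sx <- matrix(grid$s, grid$N, grid$N)
  sy <- matrix(grid$s, grid$N, grid$N, byrow = TRUE)
  r <- sqrt(sx^2 + sy^2)
  cut <- .grid_cutoff(spec, grid)
  w <- kernel_value(spec, r) / spec$xi^2 * grid$h^2
  w[r > cut] <- 0
  # offsets on the Nyquist ring (|s| = L/2) are their own mirror image and
  # would break the antisymmetric tabulation; exclude them
  w[r >= grid$L / 2] <- 0
  hx <- ifelse(r > 0, sx / r, 0) * w
  hy <- ifelse(r > 0, sy / r, 0) * w
  ca <- cospi(alpha / 180)
  sa <- sinpi(alpha / 180)
  kx <- ca * hx - sa * hy
  ky <- sa * hx + ca * hy
  structure(list(mode = "vector_direct", grid = grid, alpha = alpha,
                 kx = kx, ky = ky,
                 spec_kx = stats::fft(kx), spec_ky = stats::fft(ky)),
            class = "discrete_kernel")
}

#' Tabulate a scalar kernel for gradient sensing
#'
#' Gradient-sensing advection follows the rotated gradient of a
#' kernel-smoothed density; the rotation is applied after the gradient, so
#' the tabulated kernel itself is the scalar
#' \eqn{\tilde\Omega(|s|/\xi)\, h^2/\xi} on periodic offsets, truncated as in
#' [build_direct_kernel()].
#'
#' @inheritParams build_direct_kernel
#' @return An object of class `discrete_kernel` with `mode =
#'   "scalar_gradient"`, matrix `kw`, and its spectrum.
#' @export
build_gradient_kernel <- function(spec, grid) {
  stopifnot(inherits(spec, "kernel_spec"), inherits(grid, "sim_grid"))
  sx <- matrix(grid$s, grid$N, grid$N)
  sy <- matrix(grid$s, grid$N, grid$N, byrow = TRUE)
  r <- sqrt(sx^2 + sy^2)
  cut <- .grid_cutoff(spec, grid)
  kw <- kernel_value(spec, r) / spec$xi * grid$h^2
  kw[r > cut] <- 0
  structure(list(mode = "scalar_gradient", grid = grid,
                 kw = kw, spec_kw = stats::fft(kw)),
            class = "discrete_kernel")
}

# Periodic cross-correlation sum_s K(s) f(x + s) by spectral multiplication.
.correlate <- function(spec_K, field) {
  N <- nrow(field)
  Re(stats::fft(Conj(spec_K) * stats::fft(field), inverse = TRUE)) / N^2
}

#' Nonlocal convolution of a field with a discrete kernel
#'
#' Evaluates the nonlocal sum \eqn{\sum_s K(s)\, f(x + s)} over all periodic
#' offsets by FFT spectral multiplication. For a `vector_direct` kernel the
#' result is the two-component advection direction field (before the
#' strength \eqn{\mu} and volume-filling weights are applied); for a
#' `scalar_gradient` kernel it is the smoothed scalar measure whose rotated
#' gradient drives advection.
#'
#' @param field An `N x N` matrix on the kernel's grid.
#' @param kernel A `discrete_kernel`.
#' @return For scalar kernels, an `N x N` matrix; for vector kernels, a list
#'   with components `x` and `y`.
#' @export
convolve_field <- function(field, kernel) {
  stopifnot(inherits(kernel, "discrete_kernel"), is.matrix(field))
  N <- kernel$grid$N
  if (!all(dim(field) == c(N, N)))
    stop("field dimensions ", paste(dim(field), collapse = "x"),
         " do not match the kernel grid (", N, "x", N, ")", call. = FALSE)
  if (kernel$mode == "vector_direct") {
    list(x = .correlate(kernel$spec_kx, field),
         y = .correlate(kernel$spec_ky, field))
  } else {
    .correlate(kernel$spec_kw, field)
  }
}

# Periodic shifts along rows (x, first index) and columns (y, second index).
.shift_x <- function(m, by) {
  N <- nrow(m)
  m[((seq_len(N) - 1L + by) %% N) + 1L, , drop = FALSE]
}
.shift_y <- function(m, by) {
  N <- ncol(m)
  m[, ((seq_len(N) - 1L + by) %% N) + 1L, drop = FALSE]
}

#' Periodic finite-difference operators
#'
#' Second-order central differences on the periodic grid. The divergence of
#' any vector field telescopes to a machine-zero grid sum, which is the
#' discrete conservation law guaranteeing that the transport terms conserve
#' mass exactly.
#'
#' @param field An `N x N` matrix (first index x, second index y).
#' @param vfield A list with `N x N` components `x` and `y`.
#' @param grid A [sim_grid()].
#' @return `fd_gradient`: list of components `x`, `y`; `fd_divergence` and
#'   `fd_laplacian`: an `N x N` matrix.
#' @export
fd_gradient <- function(field, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  list(x = (.shift_x(field, 1L) - .shift_x(field, -1L)) / (2 * grid$h),
       y = (.shift_y(field, 1L) - .shift_y(field, -1L)) / (2 * grid$h))
}

#' @rdname fd_gradient
#' @export
fd_divergence <- function(vfield, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  (.shift_x(vfield$x, 1L) - .shift_x(vfield$x, -1L)) / (2 * grid$h) +
    (.shift_y(vfield$y, 1L) - .shift_y(vfield$y, -1L)) / (2 * grid$h)
}

#' @rdname fd_gradient
#' @export
fd_laplacian <- function(field, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  (.shift_x(field, 1L) + .shift_x(field, -1L) +
     .shift_y(field, 1L) + .shift_y(field, -1L) - 4 * field) / grid$h^2
}
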