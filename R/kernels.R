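#' Interaction kernel specification
#'
#' An interaction kernel is a non-negative, non-increasing radial weight
#' \eqn{\Omega(s/\xi)} giving the strength of a nonlocal interaction as a
#' function of the separation distance \eqn{s}. Two standard families are
#' supported: the exponential kernel \eqn{\Omega(u) = e^{-u}/(2\pi)} and the
#' tophat kernel \eqn{\Omega(u) = 1/\pi} for \eqn{u \le 1}, zero beyond.
#' Both are normalised so that the kernel integrates to one over the plane
#' (in units of the range \eqn{\xi}), leaving the interaction strength
#' parameterised solely by a signed coefficient \eqn{\mu}.
#'
#' @param family Kernel family, `"exponential"` or `"tophat"`.
#' @param xi Interaction range \eqn{\xi > 0} (length units).
#' @param cutoff Optional truncation radius (length units): kernel values at
#'   separations beyond `cutoff` are zero. Used when tabulating kernels on a
#'   periodic simulation grid so that two points interact at most once.
#'   Truncated kernels are deliberately not renormalised.
#'
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("exponential", xi = 2)
#' kernel_spec("tophat", xi = 1)
#' @export
kernel_spec <- function(family = c("exponential", "tophat"), xi = 1,
                        cutoff = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(xi), length(xi) == 1L, is.finite(xi))
  if (xi <= 0) stop("kernel range `xi` must be positive", call. = FALSE)
  if (!is.null(cutoff)) {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
    if (cutoff <= 0) stop("`cutoff` must be positive when set", call. = FALSE)
  }
  structure(list(family = family, xi = xi, cutoff = cutoff),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s, xi = %g%s\n", x$family, x$xi,
              if (is.null(x$cutoff)) "" else sprintf(", cutoff = %g", x$cutoff)))
  invisible(x)
}

#' Evaluate an interaction kernel at a separation distance
#'
#' Returns \eqn{\Omega(s/\xi)}: \eqn{e^{-s/\xi}/(2\pi)} for the exponential
#' family and \eqn{1/\pi \cdot [s \le \xi]} for the tophat family, with
#' values beyond the spec's `cutoff` (when set) equal to zero.
#'
#' @param spec A [kernel_spec()].
#' @param s Non-negative separation distance(s).
#' @return Kernel weight(s), same length as `s`.
#' @examples
#' kernel_value(kernel_spec("tophat", 1), 0.5) # 1/pi
#' @export
kernel_value <- function(spec, s) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (any(s < 0)) stop("separation `s` must be non-negative", call. = FALSE)
  w <- switch(spec$family,
    exponential = exp(-s / spec$xi) / (2 * pi),
    tophat = ifelse(s <= spec$xi, 1 / pi, 0)
  )
  if (!is.null(spec$cutoff)) w[s > spec$cutoff] <- 0
  w
}

#' Total mass of an interaction kernel
#'
#' Computes \eqn{\int_{R^2} \Omega(|u|)\,d^2 u = 2\pi \int_0^\infty
#' \Omega(u)\, u\, du} in range-rescaled coordinates \eqn{u = s/\xi}, by
#' adaptive radial quadrature. Without a cutoff this equals 1 for both
#' families by construction; with a cutoff it is strictly smaller because
#' truncated kernels are not renormalised.
#'
#' @param spec A [kernel_spec()].
#' @return The kernel mass (dimensionless).
#' @examples
#' kernel_mass(kernel_spec("exponential", 1)) # 1
#' @export
kernel_mass <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  upper <- if (is.null(spec$cutoff)) Inf else spec$cutoff / spec$xi
  if (spec$family == "tophat") upper <- min(upper, 1)
  f <- switch(spec$family,
    exponential = function(u) exp(-u) * u / (2 * pi),
    tophat = function(u) u / pi
  )
  2 * pi * stats::integrate(f, 0, upper, rel.tol = 1e-12,
                            abs.tol = 1e-12)$value
}

# Adaptive quadrature of int_0^upper f(s) s J_nu(k s) ds, splitting the
# oscillatory integrand at the Bessel-period scale so stats::integrate
# converges for large k * upper.
.hankel_quad <- function(f, k, nu, upper, tol = 1e-11) {
  integrand <- function(s) f(s) * s * besselJ(k * s, nu)
  if (k * upper < 20) {
    return(stats::integrate(integrand, 0, upper, rel.tol = tol,
                            abs.tol = tol)$value)
  }
  breaks <- seq(0, upper, by = pi / k)
  if (breaks[length(breaks)] < upper) breaks <- c(breaks, upper)
  total <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    total <- total + stats::integrate(integrand, breaks[i], breaks[i + 1L],
                                      rel.tol = tol, abs.tol = tol)$value
  }
  total
}

#' Order-1 Hankel transform of an interaction kernel
#'
#' Computes \eqn{\int_0^\infty \Omega(s/\xi)\, s\, J_1(k s)\, ds}, the radial
#' integral that carries the direct-sensing nonlocal term into the dispersion
#' relation. The exponential family uses the closed form
#' \eqn{(1/2\pi)\, k / ((1/\xi)^2 + k^2)^{3/2}}; the tophat family has no
#' elementary closed form at order 1 and is evaluated by adaptive quadrature
#' on \eqn{[0, \xi]} (tolerance 1e-10). Linear-stability transforms always
#' use the untruncated kernel: any cutoff on `spec` is ignored here, since
#' truncation at half the domain length has negligible effect on stability
#' whenever the domain is suitably larger than the kernel range.
#'
#' @param spec A [kernel_spec()].
#' @param k Non-negative wavenumber(s).
#' @return Transform value(s); exactly 0 at `k = 0`.
#' @examples
#' hankel1(kernel_spec("exponential", 1), 1) # (1/2pi) * 2^(-3/2)
#' @export
hankel1 <- function(spec, k) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (any(k < 0)) stop("wavenumber `k` must be non-negative", call. = FALSE)
  xi <- spec$xi
  if (spec$family == "exponential") {
    return(k / ((1 / xi)^2 + k^2)^1.5 / (2 * pi))
  }
  vapply(k, function(kk) {
    if (kk == 0) return(0)
    .hankel_quad(function(s) rep(1 / pi, length(s)), kk, 1, xi)
  }, numeric(1))
}

#' Order-0 Hankel transform of an interaction kernel
#'
#' Computes \eqn{\int_0^\infty \tilde\Omega(s/\xi)\, s\, J_0(k s)\, ds}, the
#' radial integral for the gradient-sensing nonlocal term. Both families have
#' closed forms: tophat \eqn{\xi J_1(k\xi)/(\pi k)} (limit
#' \eqn{\xi^2/(2\pi)} as \eqn{k \to 0}); exponential
#' \eqn{(1/2\pi)(1/\xi)/((1/\xi)^2 + k^2)^{3/2}}. As with [hankel1()], any
#' cutoff is ignored for stability analysis.
#'
#' @inheritParams hankel1
#' @return Transform value(s).
#' @examples
#' hankel0(kernel_spec("tophat", 1), 0) # 1/(2pi)
#' @export
hankel0 <- function(spec, k) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (any(k < 0)) stop("wavenumber `k` must be non-negative", call. = FALSE)
  xi <- spec$xi
  if (spec$family == "exponential") {
    return((1 / xi) / ((1 / xi)^2 + k^2)^1.5 / (2 * pi))
  }
  out <- numeric(length(k))
  zero <- k == 0
  out[zero] <- xi^2 / (2 * pi)
  out[!zero] <- xi * besselJ(k[!zero] * xi, 1) / (pi * k[!zero])
  out
}
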