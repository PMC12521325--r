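#' One nonlocal movement coupling
#'
#' Describes the effect of species v on the movement of species u: a signed
#' strength `mu` (positive = attraction, negative = repulsion), an
#' interaction range `xi`, a chiral angle `alpha` in degrees measured
#' counter-clockwise from the separation direction (direct sensing) or the
#' sensed gradient (gradient sensing), the interaction kernel, and the
#' response function g applied to the source density (currently the
#' identity, \eqn{g(v) = v}, as an extensible enum).
#'
#' The angle is restricted to \eqn{-90^\circ < \alpha \le 90^\circ} so that
#' attraction versus repulsion remains governed by the sign of `mu`.
#'
#' @param mu Signed interaction strength.
#' @param xi Interaction range (> 0). Also sets the kernel range when
#'   `kernel` is not supplied.
#' @param alpha Chiral advection angle in degrees, in (-90, 90].
#' @param kernel A [kernel_spec()]; defaults to an exponential kernel of
#'   range `xi`.
#' @param g Response function, `"identity"`.
#' @return An object of class `interaction`.
#' @examples
#' interaction(mu = 1, xi = 2, alpha = 70)
#' @export
interaction <- function(mu, xi = 1, alpha = 0, kernel = NULL,
                        g = c("identity")) {
  g <- match.arg(g)
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi) || xi <= 0)
    stop("interaction range `xi` must be a positive number", call. = FALSE)
  if (alpha <= -90 || alpha > 90)
    stop("chiral angle `alpha` must lie in (-90, 90] degrees", call. = FALSE)
  if (is.null(kernel)) kernel <- kernel_spec("exponential", xi = xi)
  stopifnot(inherits(kernel, "kernel_spec"))
  structure(list(mu = mu, xi = xi, alpha = alpha, kernel = kernel, g = g),
            class = "interaction")
}

#' @export
print.interaction <- function(x, ...) {
  cat(sprintf("<interaction> mu = %g, xi = %g, alpha = %g deg, %s kernel\n",
              x$mu, x$xi, x$alpha, x$kernel$family))
  invisible(x)
}

#' Parameters of the two-species chiral chase-and-run model
#'
#' Collects everything that defines a two-species nonlocal
#' advection-diffusion system: the runner/chaser diffusivity ratio `D`, the
#' four movement couplings (chaser-on-chaser `cc`, runner-on-chaser `cr`,
#' chaser-on-runner `rc`, runner-on-runner `rr`, where the first letter
#' names the species that moves and the second the species it senses), the
#' volume-filling choice, the homogeneous state (`C`, `P`) set by the
#' conserved masses, the periodic domain length `L`, and the sensing mode.
#'
#' Chase-and-run dynamics are characterised by `cr$mu > 0` (chasers
#' attracted to runners) together with `rc$mu < 0` (runners repelled from
#' chasers).
#'
#' @param D Diffusivity of runners relative to chasers (> 0).
#' @param cc,cr,rc,rr [interaction()] couplings: effect of chasers on
#'   chasers, runners on chasers, chasers on runners, runners on runners.
#' @param C,P Homogeneous chaser and runner densities in \[0, 1).
#' @param L Periodic domain length (> 0).
#' @param sensing `"direct"` (advection along rotated separation vectors) or
#'   `"gradient"` (advection along the rotated gradient of a kernel-smoothed
#'   density).
#' @param volume_filling `"linear"` for \eqn{\phi_c = \phi_\rho = 1 - c -
#'   \rho} (carrying capacity 1) or `"none"` for \eqn{\phi = 1}.
#' @return An object of class `two_species_params`.
#' @examples
#' p <- two_species_params(
#'   D = 1,
#'   cc = interaction(1, 1), cr = interaction(0.5, 1, alpha = -20),
#'   rc = interaction(-0.5, 1, alpha = 70), rr = interaction(1, 1),
#'   C = 0.2, P = 0.2, L = 8
#' )
#' is_chase_and_run(p)
#' @export
two_species_params <- function(D = 1, cc, cr, rc, rr, C = 0.2, P = 0.2,
                               L = 8, sensing = c("direct", "gradient"),
                               volume_filling = c("linear", "none")) {
  sensing <- match.arg(sensing)
  volume_filling <- match.arg(volume_filling)
  for (cp in list(cc, cr, rc, rr))
    stopifnot(inherits(cp, "interaction"))
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("diffusivity ratio `D` must be positive", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("domain length `L` must be positive", call. = FALSE)
  stopifnot(is.numeric(C), is.numeric(P), C >= 0, P >= 0)
  if (volume_filling == "linear" && C + P >= 1)
    stop("with linear volume filling the homogeneous state must satisfy ",
         "C + P < 1 (carrying capacity 1)", call. = FALSE)
  structure(list(D = D, cc = cc, cr = cr, rc = rc, rr = rr, C = C, P = P,
                 L = L, sensing = sensing, volume_filling = volume_filling),
            class = "two_species_params")
}

#' @export
print.two_species_params <- function(x, ...) {
  cat(sprintf(
    "<two_species_params> %s sensing, D = %g, L = %g, (C, P) = (%g, %g)\n",
    x$sensing, x$D, x$L, x$C, x$P))
  cat(sprintf("  volume filling: %s%s\n", x$volume_filling,
              if (is_chase_and_run(x)) "; chase-and-run regime" else ""))
  for (nm in c("cc", "cr", "rc", "rr")) {
    cp <- x[[nm]]
    cat(sprintf("  %s: mu = %g, xi = %g, alpha = %g deg, %s\n",
                nm, cp$mu, cp$xi, cp$alpha, cp$kernel$family))
  }
  invisible(x)
}

#' Is a parameter set in the chase-and-run regime?
#'
#' @param params A [two_species_params()] object.
#' @return `TRUE` iff chasers are attracted to runners (`cr$mu > 0`) and
#'   runners are repelled from chasers (`rc$mu < 0`).
#' @export
is_chase_and_run <- function(params) {
  stopifnot(inherits(params, "two_species_params"))
  params$cr$mu > 0 && params$rc$mu < 0
}

#' Rotate 2-vectors counter-clockwise
#'
#' Applies the standard rotation matrix
#' \eqn{R(\alpha) = [\cos\alpha, -\sin\alpha; \sin\alpha, \cos\alpha]}
#' used to tilt the induced advection away from the separation direction or
#' sensed gradient. Norm-preserving, determinant 1.
#'
#' @param alpha Angle in degrees.
#' @param v A length-2 vector, or a 2-column matrix of row vectors.
#' @return The rotated vector(s), same shape as `v`.
#' @examples
#' rotate2(90, c(1, 0)) # (0, 1)
#' @export
rotate2 <- function(alpha, v) {
  R <- matrix(c(cospi(alpha / 180), sinpi(alpha / 180),
                -sinpi(alpha / 180), cospi(alpha / 180)), 2, 2)
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 2L)
    v %*% t(R)
  } else {
    stopifnot(length(v) == 2L)
    drop(R %*% v)
  }
}

#' Volume-filling motility factor
#'
#' The saturation factor \eqn{\phi(c, \rho)} multiplying the advective flux:
#' `"linear"` gives \eqn{1 - c - \rho} (zero at carrying capacity, and
#' deliberately not clamped — it may go negative during stiff transients,
#' which the simulator reports rather than corrects); `"none"` gives 1.
#'
#' @param choice `"linear"` or `"none"`.
#' @param c,rho Chaser and runner densities (vectors or matrices).
#' @return The factor, recycled to the common shape of `c` and `rho`.
#' @examples
#' volume_filling_factor("linear", 0.4, 0.6) # 0 at carrying capacity
#' @export
volume_filling_factor <- function(choice = c("linear", "none"), c, rho) {
  choice <- match.arg(choice)
  if (choice == "linear") 1 - c - rho else (c * 0 + rho * 0 + 1)
}
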