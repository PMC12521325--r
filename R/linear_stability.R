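#' Per-coupling contribution to the linear growth rate
#'
#' Each nonlocal coupling of species `v` acting on species `u` enters the
#' linearised dynamics about the homogeneous state through a real
#' contribution \eqn{\Lambda_{uv}(k)}. For direct sensing this is
#' \deqn{\Lambda_{uv}(k) = \cos(\alpha_{uv})\, 2\pi\, U \phi_u(C,P)\,
#'   g'_{uv}(V)\, (\mu_{uv}/\xi_{uv}^2)\, k \int_0^\infty
#'   \Omega_{uv}(s/\xi_{uv})\, s\, J_1(k s)\, ds,}
#' and for gradient sensing the order-1 Hankel transform and \eqn{k/\xi^2}
#' prefactor are replaced by the order-0 transform and \eqn{k^2/\xi}. `U` and
#' `V` are the homogeneous states corresponding to `u` and `v`. Chirality
#' enters only through \eqn{\cos(\alpha_{uv})}: only the component of induced
#' advection parallel to the separation (or sensed gradient) affects linear
#' stability, so a purely perpendicular coupling (\eqn{\alpha = 90^\circ})
#' contributes nothing at any wavenumber.
#'
#' @param params A [two_species_params()] object.
#' @param u,v Species labels, `"c"` (chaser) or `"r"` (runner): `u` is the
#'   species that moves, `v` the species it senses.
#' @param k Non-negative wavenumber(s).
#' @return \eqn{\Lambda_{uv}(k)}, same length as `k`.
#' @examples
#' p <- two_species_params(cc = interaction(1), cr = interaction(0.5),
#'                         rc = interaction(-0.5), rr = interaction(1))
#' lambda_uv(p, "c", "r", k = 1)
#' @export
lambda_uv <- function(params, u, v, k) {
  stopifnot(inherits(params, "two_species_params"))
  u <- match.arg(u, c("c", "r"))
  v <- match.arg(v, c("c", "r"))
  if (any(k < 0)) stop("wavenumber `k` must be non-negative", call. = FALSE)
  cp <- params[[paste0(u, v)]]
  U <- if (u == "c") params$C else params$P
  phi_u <- volume_filling_factor(params$volume_filling, params$C, params$P)
  gprime <- 1 # identity response
  pref <- cospi(cp$alpha / 180) * 2 * pi * U * phi_u * gprime
  if (params$sensing == "direct") {
    pref * (cp$mu / cp$xi^2) * k * hankel1(cp$kernel, k)
  } else {
    pref * (cp$mu / cp$xi) * k^2 * hankel0(cp$kernel, k)
  }
}

# The four Lambda contributions at one wavenumber, as a named list.
.lambdas <- function(params, k) {
  list(cc = lambda_uv(params, "c", "c", k),
       cr = lambda_uv(params, "c", "r", k),
       rc = lambda_uv(params, "r", "c", k),
       rr = lambda_uv(params, "r", "r", k))
}

#' Two-species dispersion relation
#'
#' Growth rates of infinitesimal perturbations \eqn{e^{i k \cdot x}
#' e^{\lambda t}} about the homogeneous state. The growth rates are the
#' eigenvalues of the 2x2 stability matrix
#' \eqn{F(k) = [[-k^2 + \Lambda_{cc}, \Lambda_{c\rho}], [\Lambda_{\rho c},
#' -Dk^2 + \Lambda_{\rho\rho}]]}:
#' \deqn{\lambda_\pm(k) = \tfrac{1}{2}\big(-(1+D)k^2 +
#'   (\Lambda_{cc}+\Lambda_{\rho\rho}) \pm \sqrt{4\Lambda_{c\rho}
#'   \Lambda_{\rho c} + [(1-D)k^2 + (\Lambda_{\rho\rho} -
#'   \Lambda_{cc})]^2}\big),}
#' with the principal square root, so that \eqn{\lambda_+} always has the
#' (weakly) larger real part. Patterns can form when
#' \eqn{\mathrm{Re}(\lambda_+) > 0} at some \eqn{k > 0}; they are expected to
#' be stationary at early times iff the discriminant (the quantity under the
#' root) is non-negative, and to oscillate in time when it is negative.
#'
#' @param params A [two_species_params()] object.
#' @param k Non-negative wavenumber(s).
#' @return A tibble with one row per `k`: the four contributions
#'   `Lambda_cc`..`Lambda_rr`, real and imaginary parts of
#'   `lambda_plus`/`lambda_minus`, the `discriminant`, and the mode
#'   amplitude ratio \eqn{a_\rho/a_c} (`amp_ratio_re`, `amp_ratio_im`; `NA`
#'   when the coupling \eqn{\Lambda_{c\rho}} vanishes so the ratio is
#'   undefined). Classed `chiral_dispersion` for [autoplot()].
#' @examples
#' p <- two_species_params(cc = interaction(1), cr = interaction(0.5),
#'                         rc = interaction(-0.5), rr = interaction(1))
#' dispersion(p, k = seq(0, 4, by = 0.5))
#' @export
dispersion <- function(params, k) {
  stopifnot(inherits(params, "two_species_params"))
  if (any(k < 0)) stop("wavenumber `k` must be non-negative", call. = FALSE)
  L <- .lambdas(params, k)
  D <- params$D
  B <- (1 - D) * k^2 + (L$rr - L$cc)
  disc <- 4 * L$cr * L$rc + B^2
  A <- sqrt(as.complex(disc))
  half_trace <- 0.5 * (-(1 + D) * k^2 + L$cc + L$rr)
  lp <- half_trace + 0.5 * A
  lm <- half_trace - 0.5 * A
  ratio <- ifelse(L$cr == 0, NA_complex_, (B + A) / (2 * L$cr))
  out <- tibble::tibble(
    k = k,
    Lambda_cc = L$cc, Lambda_cr = L$cr, Lambda_rc = L$rc, Lambda_rr = L$rr,
    re_lambda_plus = Re(lp), im_lambda_plus = Im(lp),
    re_lambda_minus = Re(lm), im_lambda_minus = Im(lm),
    discriminant = disc,
    amp_ratio_re = Re(ratio), amp_ratio_im = Im(ratio)
  )
  class(out) <- c("chiral_dispersion", class(out))
  out
}

#' Admissible wavenumbers of a periodic square domain
#'
#' On a periodic domain \eqn{[0, L]^2} only modes with integer numbers of
#' wavelengths fit, restricting the wavenumber to
#' \eqn{k = 2\pi\sqrt{n^2 + m^2}/L} for integers \eqn{0 \le n, m \le
#' n_{max}}, \eqn{(n, m) \ne (0, 0)}.
#'
#' @param L Domain length (> 0).
#' @param n_max Largest per-axis mode index (>= 1).
#' @return Sorted unique admissible wavenumbers; the smallest is always
#'   \eqn{2\pi/L}.
#' @examples
#' admissible_wavenumbers(2 * pi, 1) # 1, sqrt(2)
#' @export
admissible_wavenumbers <- function(L, n_max) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0,
            is.numeric(n_max), length(n_max) == 1L, n_max >= 1)
  n_max <- as.integer(n_max)
  nm <- expand.grid(n = 0:n_max, m = 0:n_max)
  q <- sort(unique(nm$n^2 + nm$m^2))
  q <- q[q > 0]
  2 * pi * sqrt(q) / L
}

#' Classify the linear stability regime
#'
#' Scans the dispersion relation over a wavenumber grid and labels the
#' parameter set `"stable"` (max \eqn{\mathrm{Re}\,\lambda_+ \le 0}),
#' `"stationary_instability"` (unstable with \eqn{\mathrm{Im}\,\lambda_+ = 0}
#' at the fastest-growing wavenumber — a Turing-type instability), or
#' `"oscillatory_instability"` (unstable with \eqn{\mathrm{Im}\,\lambda_+ \ne
#' 0} there — a Turing-wave instability). The default grid is the set of
#' admissible wavenumbers of the configured domain up to per-axis index
#' `n_max`, matching classification on a finite periodic domain; pass a dense
#' `k_grid` for infinite-domain analysis.
#'
#' @param params A [two_species_params()] object.
#' @param k_grid Optional wavenumber grid (must exclude 0, where both growth
#'   rates are exactly zero by mass conservation).
#' @param n_max Per-axis mode cap for the default admissible-wavenumber grid.
#' @param im_tol Tolerance for treating \eqn{\mathrm{Im}\,\lambda_+} as zero:
#'   `|Im| < im_tol * max(1, |Re|)`.
#' @return A one-row tibble: `label`, `k_star` (fastest-growing wavenumber;
#'   `NA` when stable), `max_re_lambda`, `im_at_k_star`.
#' @examples
#' p <- two_species_params(cc = interaction(0), cr = interaction(0),
#'                         rc = interaction(0), rr = interaction(0))
#' classify_regime(p)$label # "stable": pure diffusion
#' @export
classify_regime <- function(params, k_grid = NULL, n_max = 12,
                            im_tol = 1e-10) {
  stopifnot(inherits(params, "two_species_params"))
  if (is.null(k_grid)) k_grid <- admissible_wavenumbers(params$L, n_max)
  if (length(k_grid) == 0L) stop("`k_grid` must be nonempty", call. = FALSE)
  if (any(k_grid <= 0))
    stop("`k_grid` must exclude k = 0 (neutral mass-conservation mode)",
         call. = FALSE)
  d <- dispersion(params, k_grid)
  i <- which.max(d$re_lambda_plus)
  max_re <- d$re_lambda_plus[i]
  im_star <- d$im_lambda_plus[i]
  label <- if (max_re <= 0) {
    "stable"
  } else if (abs(im_star) < im_tol * max(1, abs(max_re))) {
    "stationary_instability"
  } else {
    "oscillatory_instability"
  }
  tibble::tibble(label = label,
                 k_star = if (max_re > 0) d$k[i] else NA_real_,
                 max_re_lambda = max_re,
                 im_at_k_star = im_star)
}

#' Predict species mixing or separation from the leading eigenvector
#'
#' For a chase-and-run system whose fastest-growing mode has a real growth
#' rate, the relative sign of the chaser and runner amplitudes in the
#' leading eigenvector of the stability matrix predicts whether the
#' early-time pattern is in phase (same sign: the species are `"mixed"`) or
#' out of phase (opposite sign: `"separated"`). With
#' \eqn{B = (1-D)k^2 + \Lambda_{\rho\rho} - \Lambda_{cc}} and
#' \eqn{A = +\sqrt{B^2 + 4\Lambda_{c\rho}\Lambda_{\rho c}}} (the positive
#' root, corresponding to the faster-growing perturbation), the eigenvector
#' satisfies \eqn{a_\rho = (B + A)\, a_c / (2\Lambda_{c\rho})}, so the sign
#' of \eqn{a_\rho/a_c} is \eqn{\mathrm{sign}(B + A)/\mathrm{sign}
#' (2\Lambda_{c\rho})}. If the discriminant is negative the growth rate is
#' complex and the phase relationship rotates in time: `"indeterminate"`.
#'
#' The prediction logic assumes the chase-and-run sign structure
#' (\eqn{\Lambda_{c\rho} > 0}, \eqn{\Lambda_{\rho c} < 0} at the evaluation
#' wavenumber) and refuses other inputs.
#'
#' @param params A [two_species_params()] object in the chase-and-run regime.
#' @param k Wavenumber at which to evaluate; defaults to the fastest-growing
#'   admissible wavenumber `k_star` from [classify_regime()].
#' @param n_max Per-axis mode cap used when finding the default `k`.
#' @return A one-row tibble: `phase` (`"mixed"`, `"separated"`, or
#'   `"indeterminate"`), `k`, `amp_ratio` (\eqn{a_\rho/a_c}; `NA` when
#'   indeterminate), and `discriminant`.
#' @export
predict_phase <- function(params, k = NULL, n_max = 12) {
  stopifnot(inherits(params, "two_species_params"))
  if (is.null(k)) {
    reg <- classify_regime(params, n_max = n_max)
    if (is.na(reg$k_star))
      stop("homogeneous state is linearly stable: no growing mode to ",
           "evaluate; supply `k` explicitly", call. = FALSE)
    k <- reg$k_star
  }
  stopifnot(length(k) == 1L, k > 0)
  L <- .lambdas(params, k)
  if (!(L$cr > 0 && L$rc < 0))
    stop("predict_phase() assumes the chase-and-run sign structure ",
         "(Lambda_cr > 0 and Lambda_rc < 0 at the evaluation wavenumber); ",
         sprintf("got Lambda_cr = %.3g, Lambda_rc = %.3g", L$cr, L$rc),
         call. = FALSE)
  B <- (1 - params$D) * k^2 + (L$rr - L$cc)
  disc <- B^2 + 4 * L$cr * L$rc
  if (disc < 0) {
    return(tibble::tibble(phase = "indeterminate", k = k,
                          amp_ratio = NA_real_, discriminant = disc))
  }
  A <- sqrt(disc)
  ratio <- (B + A) / (2 * L$cr)
  phase <- if (ratio > 0) "mixed" else "separated"
  tibble::tibble(phase = phase, k = k, amp_ratio = ratio,
                 discriminant = disc)
}

# Set a scalar parameter by name: "D", "C", "P", "L", or coupling fields
# like "rc.alpha", "cc.mu", "cr.xi" (xi also updates the kernel range).
.set_param <- function(params, name, value) {
  if (name %in% c("D", "C", "P", "L")) {
    params[[name]] <- value
    return(params)
  }
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("cc", "cr", "rc", "rr") ||
      !parts[2] %in% c("mu", "xi", "alpha"))
    stop("unknown parameter name: ", name, call. = FALSE)
  cp <- params[[parts[1]]]
  cp[[parts[2]]] <- value
  if (parts[2] == "xi") cp$kernel$xi <- value
  params[[parts[1]]] <- interaction(cp$mu, cp$xi, cp$alpha, cp$kernel, cp$g)
  params
}

#' Linear-stability phase diagram over two parameters
#'
#' Evaluates [classify_regime()] on the Cartesian product of two parameter
#' sweeps, e.g. the diffusivity ratio against the chiral running angle.
#'
#' @param base A [two_species_params()] object providing all other values.
#' @param axis1,axis2 Named lists `list(param =, values =)` where `param` is
#'   `"D"`, `"C"`, `"P"`, `"L"`, or a coupling field such as `"rc.alpha"`,
#'   `"cc.mu"`, `"cr.xi"`.
#' @param ... Passed to [classify_regime()] (`k_grid`, `n_max`, `im_tol`).
#' @return A tibble with one row per grid point: the two parameter columns
#'   (named after the swept parameters), `label`, `k_star`,
#'   `max_re_lambda`. Classed `chiral_phase_diagram` for [autoplot()].
#' @examples
#' p <- two_species_params(cc = interaction(1), cr = interaction(0.5),
#'                         rc = interaction(-0.5), rr = interaction(1))
#' phase_diagram(p, list(param = "D", values = c(0.5, 1)),
#'               list(param = "rc.alpha", values = c(0, 45, 90)))
#' @export
phase_diagram <- function(base, axis1, axis2, ...) {
  stopifnot(inherits(base, "two_species_params"),
            is.list(axis1), is.list(axis2),
            all(c("param", "values") %in% names(axis1)),
            all(c("param", "values") %in% names(axis2)))
  grid <- tidyr::expand_grid(v1 = axis1$values, v2 = axis2$values)
  res <- purrr::pmap_dfr(grid, function(v1, v2) {
    p <- .set_param(base, axis1$param, v1)
    p <- .set_param(p, axis2$param, v2)
    classify_regime(p, ...)
  })
  out <- dplyr::bind_cols(grid, res[c("label", "k_star", "max_re_lambda")])
  names(out)[1:2] <- c(axis1$param, axis2$param)
  class(out) <- c("chiral_phase_diagram", class(out))
  out
}
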