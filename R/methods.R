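#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a field state into a long tibble
#'
#' @param x A [field_state()].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `t`, `c`, `rho`, one row per
#'   grid cell.
#' @method tidy field_state
#' @export
tidy.field_state <- function(x, ...) {
  g <- x$grid
  # pull components out first: inside tibble() the freshly built `x` and `c`
  # columns would mask the function arguments of the same name
  tt <- x$t
  cvec <- as.vector(x$c)
  rvec <- as.vector(x$rho)
  tibble::tibble(
    x = rep(g$x, times = g$N),
    y = rep(g$x, each = g$N),
    t = tt,
    c = cvec,
    rho = rvec
  )
}

#' Tidy a trajectory into a long tibble of snapshots
#'
#' @param x A `chiral_trajectory`.
#' @param times Optional subset of snapshot times to keep (matched to the
#'   nearest stored snapshot).
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `t`, `c`, `rho`.
#' @method tidy chiral_trajectory
#' @export
tidy.chiral_trajectory <- function(x, times = NULL, ...) {
  idx <- if (is.null(times)) {
    seq_along(x$times)
  } else {
    unique(vapply(times, function(tt) which.min(abs(x$times - tt)),
                  integer(1)))
  }
  purrr::map_dfr(idx, function(i) tidy(snapshot(x, i)))
}

#' One-row summary of a trajectory
#'
#' @param x A `chiral_trajectory`.
#' @param ... Passed to [pattern_report()].
#' @return A one-row tibble combining the pattern report with solver
#'   metadata.
#' @method glance chiral_trajectory
#' @export
glance.chiral_trajectory <- function(x, ...) {
  dplyr::bind_cols(
    pattern_report(x, ...),
    tibble::tibble(seed = x$seed, method = x$method, rtol = x$rtol,
                   atol = x$atol, N = x$grid$N, L = x$grid$L)
  )
}

#' Plot a dispersion relation
#'
#' Real and imaginary parts of the leading growth rate against wavenumber;
#' the zero line separates growing from decaying perturbations.
#'
#' @param object A `chiral_dispersion` tibble from [dispersion()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chiral_dispersion
#' @export
autoplot.chiral_dispersion <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[c("k", "re_lambda_plus", "im_lambda_plus")],
    cols = -"k", names_to = "part", values_to = "value")
  df$part <- factor(df$part, c("re_lambda_plus", "im_lambda_plus"),
                    c("Re λ+", "Im λ+"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   linetype = .data$part)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber k", y = "growth rate",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a linear-stability phase diagram
#'
#' @param object A `chiral_phase_diagram` tibble from [phase_diagram()].
#' @param ... Unused.
#' @return A ggplot tile map of regime labels.
#' @method autoplot chiral_phase_diagram
#' @export
autoplot.chiral_phase_diagram <- function(object, ...) {
  nms <- names(object)[1:2]
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[nms[1]]], y = .data[[nms[2]]], fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      stable = "#4575b4", oscillatory_instability = "#d73027",
      stationary_instability = "#1a9850")) +
    ggplot2::theme_minimal()
}

#' Plot the two density fields of a state
#'
#' @param object A [field_state()].
#' @param ... Unused.
#' @return A ggplot with one raster facet per species.
#' @method autoplot field_state
#' @export
autoplot.field_state <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), cols = c("c", "rho"),
                            names_to = "species", values_to = "density")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~species) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal()
}

#' Plot pattern amplitude against time for a trajectory
#'
#' @param object A `chiral_trajectory`.
#' @param ... Unused.
#' @return A ggplot of per-species amplitude (max - min) versus time.
#' @method autoplot chiral_trajectory
#' @export
autoplot.chiral_trajectory <- function(object, ...) {
  amp <- function(arr) {
    vapply(seq_along(object$times),
           function(i) max(arr[i, , ]) - min(arr[i, , ]), numeric(1))
  }
  df <- tibble::tibble(
    t = rep(object$times, 2),
    amplitude = c(amp(object$c), amp(object$rho)),
    species = rep(c("c", "rho"), each = length(object$times)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$amplitude,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "pattern amplitude (max - min)") +
    ggplot2::theme_minimal()
}
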