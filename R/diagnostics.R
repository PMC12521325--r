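#' Phase correlation between chasers and runners
#'
#' Pearson correlation over grid cells of the mean-centred chaser and runner
#' fields: strongly positive correlation means the species' density peaks
#' are co-located (in phase, `"mixed"`), strongly negative means they are
#' anti-located (out of phase, `"separated"`). The thresholds (default
#' +/- 0.5) are configurable; late-time states are typically strongly in or
#' out of phase, so the decision boundary is insensitive.
#'
#' @param state A [field_state()].
#' @param thresholds Length-2 numeric `c(separated, mixed)` cut points on r.
#' @return A one-row tibble: `r` (Pearson correlation; `NA` for constant
#'   fields, flagged), `phase_class` (`"mixed"`, `"separated"`, or
#'   `"uncorrelated"`), `constant_field`.
#' @examples
#' g <- sim_grid(16, 8)
#' f <- matrix(runif(256), 16, 16)
#' phase_correlation(field_state(f, 1 - f, grid = g))$phase_class
#' @export
phase_correlation <- function(state, thresholds = c(-0.5, 0.5)) {
  stopifnot(inherits(state, "field_state"), length(thresholds) == 2L,
            thresholds[1] < thresholds[2])
  cc <- as.vector(state$c)
  rr <- as.vector(state$rho)
  if (stats::sd(cc) == 0 || stats::sd(rr) == 0) {
    return(tibble::tibble(r = NA_real_, phase_class = "uncorrelated",
                          constant_field = TRUE))
  }
  r <- stats::cor(cc, rr)
  cls <- if (r >= thresholds[2]) "mixed"
         else if (r <= thresholds[1]) "separated"
         else "uncorrelated"
  tibble::tibble(r = r, phase_class = cls, constant_field = FALSE)
}

#' Stationarity and oscillation diagnostics for a trajectory
#'
#' Two model-free flags computed over the final `window` of a trajectory.
#' The state is `stationary` when the relative rate of change
#' \eqn{\|\Delta \mathrm{state}\| / (\Delta t\, \|\mathrm{state}\|)} stays
#' below `rate_tol` per unit time across the window. It is `oscillatory`
#' when the per-species pattern-amplitude series (max - min per snapshot, on
#' a log scale so that exponential growth detrends to a line, then linearly
#' detrended) has a dominant nonzero frequency whose spectral peak
#' power is at least `peak_factor` times the spectral median. The oscillation
#' test is deliberately independent of the linear theory, since a complex
#' linear growth rate is neither sufficient nor necessary for late-time
#' oscillation.
#'
#' @param trajectory A `chiral_trajectory` with at least 3 snapshots in the
#'   window.
#' @param window Length of the trailing time window (default: the whole
#'   trajectory).
#' @param rate_tol Stationarity threshold on the relative rate of change per
#'   unit time.
#' @param peak_factor Spectral peak-to-median power ratio declaring
#'   oscillation.
#' @return A one-row tibble: `stationary`, `oscillatory`, `max_rate`,
#'   `peak_power_ratio`, `peak_frequency`.
#' @export
stationarity <- function(trajectory, window = NULL, rate_tol = 1e-6,
                         peak_factor = 10) {
  stopifnot(inherits(trajectory, "chiral_trajectory"))
  tt <- trajectory$times
  if (is.null(window)) window <- diff(range(tt))
  keep <- which(tt >= max(tt) - window - 1e-12)
  if (length(keep) < 3L)
    stop("need at least 3 snapshots inside the window", call. = FALSE)
  nt <- length(keep)
  rates <- numeric(nt - 1L)
  for (j in seq_len(nt - 1L)) {
    i0 <- keep[j]; i1 <- keep[j + 1L]
    d <- sqrt(sum((trajectory$c[i1, , ] - trajectory$c[i0, , ])^2) +
                sum((trajectory$rho[i1, , ] - trajectory$rho[i0, , ])^2))
    nrm <- sqrt(sum(trajectory$c[i0, , ]^2) + sum(trajectory$rho[i0, , ]^2))
    rates[j] <- d / (tt[i1] - tt[i0]) / nrm
  }
  amp_series <- function(arr) {
    vapply(keep, function(i) {
      f <- arr[i, , ]
      max(f) - min(f)
    }, numeric(1))
  }
  spec_ratio <- function(a) {
    if (length(a) < 5L || stats::sd(a) == 0) return(c(0, NA_real_))
    if (all(a > 0)) a <- log(a) # exponential growth detrends to a line
    a <- stats::residuals(stats::lm(a ~ seq_along(a)))
    pw <- Mod(stats::fft(a))^2
    pw <- pw[2:(floor(length(a) / 2) + 1L)] # nonzero frequencies
    # residual trend leaks into the slowest bin, which cannot complete a
    # full cycle in the window: a dominant frequency must sit above it
    if (length(pw) < 2L || all(pw[-1] == 0)) return(c(0, NA_real_))
    i <- which.max(pw[-1]) + 1L
    dt <- mean(diff(tt[keep]))
    freq <- i / (length(a) * dt)
    c(pw[i] / max(stats::median(pw[-1]), .Machine$double.xmin), freq)
  }
  sc <- spec_ratio(amp_series(trajectory$c))
  sr <- spec_ratio(amp_series(trajectory$rho))
  best <- if (sc[1] >= sr[1]) sc else sr
  tibble::tibble(stationary = max(rates) < rate_tol,
                 oscillatory = best[1] >= peak_factor,
                 max_rate = max(rates),
                 peak_power_ratio = best[1],
                 peak_frequency = best[2])
}

# Connected components of a logical mask with 8-connectivity and periodic
# wrap; returns an integer label matrix (0 = background).
.periodic_components <- function(mask) {
  N <- nrow(mask); M <- ncol(mask)
  lab <- matrix(0L, N, M)
  cur <- 0L
  idx <- which(mask)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  for (start in idx) {
    si <- (start - 1L) %% N + 1L
    sj <- (start - 1L) %/% N + 1L
    if (lab[si, sj] != 0L) next
    cur <- cur + 1L
    queue <- c(start)
    lab[si, sj] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pi <- (p - 1L) %% N + 1L
      pj <- (p - 1L) %/% N + 1L
      ni <- (pi - 1L + offs$di) %% N + 1L
      nj <- (pj - 1L + offs$dj) %% M + 1L
      for (q in seq_len(nrow(offs))) {
        if (mask[ni[q], nj[q]] && lab[ni[q], nj[q]] == 0L) {
          lab[ni[q], nj[q]] <- cur
          queue <- c(queue, (nj[q] - 1L) * N + ni[q])
        }
      }
    }
  }
  lab
}

#' Count density aggregates in a field
#'
#' Thresholds the field at `mean + threshold_frac * (max - mean)` and counts
#' connected components of the super-level set with 8-connectivity and
#' periodic wrap-around, so an aggregate straddling the domain boundary is
#' counted once. Stationary late-time patterns of these models typically
#' consist of a single aggregate per species.
#'
#' @param field An `N x N` density matrix.
#' @param threshold_frac Fraction in (0, 1) of the max-above-mean range.
#' @return Integer number of aggregates (0 for a flat field).
#' @examples
#' f <- matrix(0, 16, 16); f[4:6, 4:6] <- 1
#' count_aggregates(f)
#' @export
count_aggregates <- function(field, threshold_frac = 0.5) {
  stopifnot(is.matrix(field), threshold_frac > 0, threshold_frac < 1)
  m <- mean(field)
  if (max(field) == m) return(0L)
  lev <- m + threshold_frac * (max(field) - m)
  max(.periodic_components(field >= lev))
}

# Circular-mean coordinate of non-negative weights along one axis of a
# periodic domain [0, L): the phase of the first Fourier mode.
.circular_mean <- function(w_by_pos, x, L) {
  theta <- 2 * pi * x / L
  z <- sum(w_by_pos * exp(1i * theta))
  (Arg(z) %% (2 * pi)) * L / (2 * pi)
}

# Unwrap a periodic coordinate series: per-step displacement takes the
# nearest periodic image.
.unwrap <- function(x, L) {
  d <- diff(x)
  d <- d - L * round(d / L)
  x[1] + c(0, cumsum(d))
}

#' Track aggregates or travelling holes through a trajectory
#'
#' Follows a moving structure across periodic boundaries and measures its
#' speed and signed path curvature — the readouts for population-level
#' chase-and-run pulses (chaser aggregates perpetually pursuing runner
#' aggregates, along straight paths without chirality and curved paths with
#' it) and for travelling holes (localised low-density regions of both
#' species moving through a near-uniform background).
#'
#' Aggregate centroids use the per-axis circular mean (first-Fourier-mode
#' phase) of the species density, the only wrap-consistent first-moment
#' estimator on a torus. Hole centroids use the deficit-weighted circular
#' mean of the lowest-total-density connected region below
#' `hole_frac * median(total density)`; if that region vanishes the track is
#' truncated and flagged. The centroid path is unwrapped (per-step
#' displacement must stay below L/2), optionally smoothed with a centred
#' moving average, and differentiated with central differences to give speed
#' and signed curvature \eqn{\kappa = (\dot x \ddot y - \dot y \ddot x) /
#' (\dot x^2 + \dot y^2)^{3/2}}; curvature is `NA` where the speed is too
#' small for the direction of motion to be defined.
#'
#' @param trajectory A `chiral_trajectory`.
#' @param kind `"aggregate"` or `"hole"`.
#' @param species For aggregates: `"c"` or `"rho"`.
#' @param hole_frac Threshold fraction of the median total density defining
#'   a hole.
#' @param smooth Odd moving-average window on the path (1 = no smoothing).
#' @param speed_tol Curvature is reported only where speed exceeds this.
#' @return A tibble with one row per tracked snapshot: `t`, unwrapped `x`,
#'   `y`, `speed`, `curvature`, `kind`, `species`, and attribute
#'   `"truncated"` if a hole vanished mid-track.
#' @export
track_objects <- function(trajectory, kind = c("aggregate", "hole"),
                          species = c("c", "rho"), hole_frac = 0.5,
                          smooth = 1L, speed_tol = 1e-8) {
  kind <- match.arg(kind)
  species <- match.arg(species)
  stopifnot(inherits(trajectory, "chiral_trajectory"),
            smooth >= 1, smooth %% 2 == 1)
  grid <- trajectory$grid
  tt <- trajectory$times
  nt <- length(tt)
  xs <- ys <- rep(NA_real_, nt)
  truncated <- FALSE
  for (i in seq_len(nt)) {
    if (kind == "aggregate") {
      f <- if (species == "c") trajectory$c[i, , ] else trajectory$rho[i, , ]
      w <- pmax(f - min(f), 0)
    } else {
      tot <- trajectory$c[i, , ] + trajectory$rho[i, , ]
      lev <- hole_frac * stats::median(tot)
      mask <- tot < lev
      if (!any(mask)) {
        # before the hole forms: skip; after: the object was lost
        if (any(!is.na(xs))) { truncated <- TRUE; break }
        next
      }
      lab <- .periodic_components(mask)
      sums <- vapply(seq_len(max(lab)),
                     function(l) sum(tot[lab == l]) / sum(lab == l),
                     numeric(1))
      target <- which.min(sums)
      w <- matrix(0, grid$N, grid$N)
      sel <- lab == target
      w[sel] <- lev - tot[sel]
    }
    xs[i] <- .circular_mean(rowSums(w), grid$x, grid$L)
    ys[i] <- .circular_mean(colSums(w), grid$x, grid$L)
  }
  ok <- !is.na(xs)
  xs <- .unwrap(xs[ok], grid$L)
  ys <- .unwrap(ys[ok], grid$L)
  tk <- tt[ok]
  if (smooth > 1L && length(xs) >= smooth) {
    ker <- rep(1 / smooth, smooth)
    pad <- (smooth - 1L) / 2L
    smooth_ma <- function(v) {
      out <- stats::filter(v, ker, sides = 2)
      out[seq_len(pad)] <- v[seq_len(pad)]
      out[(length(v) - pad + 1L):length(v)] <-
        v[(length(v) - pad + 1L):length(v)]
      as.numeric(out)
    }
    xs <- smooth_ma(xs)
    ys <- smooth_ma(ys)
  }
  n <- length(xs)
  dx <- dy <- ddx <- ddy <- rep(NA_real_, n)
  if (n >= 3L) {
    i2 <- 2:(n - 1L)
    dtf <- tk[i2 + 1L] - tk[i2 - 1L]
    dx[i2] <- (xs[i2 + 1L] - xs[i2 - 1L]) / dtf
    dy[i2] <- (ys[i2 + 1L] - ys[i2 - 1L]) / dtf
    dt2 <- (tk[i2 + 1L] - tk[i2]) * (tk[i2] - tk[i2 - 1L])
    ddx[i2] <- (xs[i2 + 1L] - 2 * xs[i2] + xs[i2 - 1L]) / dt2
    ddy[i2] <- (ys[i2 + 1L] - 2 * ys[i2] + ys[i2 - 1L]) / dt2
  }
  speed <- sqrt(dx^2 + dy^2)
  curvature <- ifelse(!is.na(speed) & speed > speed_tol,
                      (dx * ddy - dy * ddx) / speed^3, NA_real_)
  species_out <- if (kind == "hole") "both" else species
  out <- tibble::tibble(t = tk, x = xs, y = ys, speed = speed,
                        curvature = curvature, kind = kind,
                        species = species_out)
  attr(out, "truncated") <- truncated
  if (truncated)
    warning("tracked region vanished; track truncated at t = ",
            if (length(tk)) max(tk) else tt[1], call. = FALSE)
  out
}

#' Summary pattern report for a trajectory
#'
#' One-stop phenotyping of a finished run: per-species pattern amplitudes,
#' stationarity and oscillation flags, the chaser-runner phase correlation
#' and class, and aggregate counts, taken at the final snapshot (flags over
#' the trailing `window`).
#'
#' @param trajectory A `chiral_trajectory`.
#' @param window Passed to [stationarity()].
#' @param threshold_frac Passed to [count_aggregates()].
#' @return A one-row tibble.
#' @export
pattern_report <- function(trajectory, window = NULL,
                           threshold_frac = 0.5) {
  stopifnot(inherits(trajectory, "chiral_trajectory"))
  st <- snapshot(trajectory)
  flags <- if (length(trajectory$times) >= 3) {
    stationarity(trajectory, window = window)
  } else {
    tibble::tibble(stationary = NA, oscillatory = NA)
  }
  pc <- phase_correlation(st)
  tibble::tibble(
    t_final = st$t,
    amplitude_c = max(st$c) - min(st$c),
    amplitude_rho = max(st$rho) - min(st$rho),
    stationary = flags$stationary,
    oscillatory = flags$oscillatory,
    phase_corr = pc$r,
    phase_class = pc$phase_class,
    n_aggregates_c = count_aggregates(st$c, threshold_frac),
    n_aggregates_rho = count_aggregates(st$rho, threshold_frac),
    mass_drift_c = max(trajectory$mass$drift_c),
    mass_drift_rho = max(trajectory$mass$drift_rho)
  )
}
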