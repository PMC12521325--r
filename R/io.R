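#' Experiment configuration
#'
#' Bundles a full model parameterisation with the numerical settings needed
#' to reproduce a run: the grid resolution, initial-condition noise and
#' seed, and solver controls. Configurations round-trip losslessly through
#' YAML via [save_config()] / [load_config()], and every trajectory embeds
#' its configuration so stored runs can be re-analysed without the original
#' file.
#'
#' @param params A [two_species_params()] object.
#' @param N Grid points per side.
#' @param sigma Initial-condition noise standard deviation.
#' @param seed Integer noise seed.
#' @param t_end Final integration time.
#' @param output_times Snapshot times (default: 21 evenly spaced on
#'   `[0, t_end]`).
#' @param rtol,atol Solver tolerances.
#' @param method \pkg{deSolve} method name.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(params, N = 100, sigma = 1e-3, seed = 1L,
                              t_end = 100, output_times = NULL,
                              rtol = 1e-6, atol = 1e-8, method = "adams") {
  stopifnot(inherits(params, "two_species_params"),
            is.numeric(N), N >= 8, is.numeric(t_end), t_end > 0,
            is.numeric(sigma), sigma >= 0)
  if (is.null(output_times)) output_times <- seq(0, t_end, length.out = 21)
  if (max(output_times) > t_end)
    stop("`output_times` may not exceed `t_end`", call. = FALSE)
  structure(list(params = params, N = as.integer(N), sigma = sigma,
                 seed = as.integer(seed), t_end = t_end,
                 output_times = as.numeric(output_times),
                 rtol = rtol, atol = atol, method = method),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> N = %d, t_end = %g, seed = %d\n",
              x$N, x$t_end, x$seed))
  print(x$params)
  invisible(x)
}

#' Run the experiment described by a configuration
#'
#' @param config An [experiment_config()].
#' @param ... Overrides passed to [simulate_two_species()] (e.g. `seed`).
#' @return A `chiral_trajectory` with the configuration attached as
#'   `$config`.
#' @export
run_experiment <- function(config, ...) {
  stopifnot(inherits(config, "experiment_config"))
  args <- list(params = config$params,
               grid = sim_grid(config$N, config$params$L),
               output_times = config$output_times, sigma = config$sigma,
               seed = config$seed, rtol = config$rtol, atol = config$atol,
               method = config$method)
  dots <- list(...)
  args[names(dots)] <- dots
  tr <- do.call(simulate_two_species, args)
  tr$config <- config
  tr
}

.coupling_to_list <- function(cp) {
  list(mu = cp$mu, xi = cp$xi, alpha = cp$alpha,
       kernel = list(family = cp$kernel$family, xi = cp$kernel$xi,
                     cutoff = cp$kernel$cutoff),
       g = cp$g)
}

.coupling_from_list <- function(x, where) {
  .check_keys(x, c("mu", "xi", "alpha", "kernel", "g"),
              required = c("mu", "xi"), where = where)
  kern <- NULL
  if (!is.null(x$kernel)) {
    .check_keys(x$kernel, c("family", "xi", "cutoff"),
                required = "family", where = paste0(where, "$kernel"))
    kern <- kernel_spec(x$kernel$family,
                        xi = if (is.null(x$kernel$xi)) x$xi else x$kernel$xi,
                        cutoff = x$kernel$cutoff)
  }
  interaction(mu = x$mu, xi = x$xi,
              alpha = if (is.null(x$alpha)) 0 else x$alpha,
              kernel = kern, g = if (is.null(x$g)) "identity" else x$g)
}

.check_keys <- function(x, allowed, required, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required key(s) in ", where, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Save or load an experiment configuration as YAML
#'
#' The schema is validated strictly on load: unknown keys, missing required
#' keys, and constraint violations (such as a chiral angle outside
#' (-90, 90]) are errors with actionable messages.
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `load_config()` returns an [experiment_config()];
#'   `save_config()` returns `path` invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  p <- config$params
  x <- list(
    model = list(sensing = p$sensing, volume_filling = p$volume_filling,
                 D = p$D, L = p$L,
                 couplings = list(cc = .coupling_to_list(p$cc),
                                  cr = .coupling_to_list(p$cr),
                                  rc = .coupling_to_list(p$rc),
                                  rr = .coupling_to_list(p$rr))),
    ic = list(C = p$C, P = p$P, sigma = config$sigma, seed = config$seed),
    grid = list(N = config$N),
    solver = list(t_end = config$t_end,
                  output_times = config$output_times,
                  rtol = config$rtol, atol = config$atol,
                  method = config$method)
  )
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  .check_keys(x, c("model", "ic", "grid", "solver"),
              required = c("model", "ic", "grid", "solver"), where = "config")
  .check_keys(x$model, c("sensing", "volume_filling", "D", "L", "couplings"),
              required = c("sensing", "D", "L", "couplings"),
              where = "model")
  .check_keys(x$model$couplings, c("cc", "cr", "rc", "rr"),
              required = c("cc", "cr", "rc", "rr"),
              where = "model$couplings")
  .check_keys(x$ic, c("C", "P", "sigma", "seed"), required = c("C", "P"),
              where = "ic")
  .check_keys(x$grid, "N", required = "N", where = "grid")
  .check_keys(x$solver, c("t_end", "output_times", "rtol", "atol", "method"),
              required = "t_end", where = "solver")
  vf <- if (is.null(x$model$volume_filling)) "linear" else x$model$volume_filling
  params <- two_species_params(
    D = x$model$D,
    cc = .coupling_from_list(x$model$couplings$cc, "couplings$cc"),
    cr = .coupling_from_list(x$model$couplings$cr, "couplings$cr"),
    rc = .coupling_from_list(x$model$couplings$rc, "couplings$rc"),
    rr = .coupling_from_list(x$model$couplings$rr, "couplings$rr"),
    C = x$ic$C, P = x$ic$P, L = x$model$L, sensing = x$model$sensing,
    volume_filling = vf)
  experiment_config(
    params, N = x$grid$N,
    sigma = if (is.null(x$ic$sigma)) 1e-3 else x$ic$sigma,
    seed = if (is.null(x$ic$seed)) 1L else x$ic$seed,
    t_end = x$solver$t_end,
    output_times = x$solver$output_times,
    rtol = if (is.null(x$solver$rtol)) 1e-6 else x$solver$rtol,
    atol = if (is.null(x$solver$atol)) 1e-8 else x$solver$atol,
    method = if (is.null(x$solver$method)) "adams" else x$solver$method)
}

#' Persist and reload trajectories
#'
#' Stores the full hierarchical trajectory (snapshot arrays, times,
#' per-species masses, seed, and the embedded configuration) so a run can be
#' re-classified later without the original config file.
#'
#' @param trajectory A `chiral_trajectory`.
#' @param path File path (`.rds`).
#' @return `read_trajectory()` returns the `chiral_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "chiral_trajectory"))
  saveRDS(trajectory, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- readRDS(path)
  if (!inherits(tr, "chiral_trajectory"))
    stop("file does not contain a trajectory: ", path, call. = FALSE)
  tr
}

#' Export a dispersion curve or phase diagram as CSV
#'
#' @param x A tibble from [dispersion()] or [phase_diagram()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
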