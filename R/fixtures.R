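#' Named scenario fixtures
#'
#' Ready-made [experiment_config()] presets, one per headline behaviour of
#' the chiral chase-and-run models. Values stated alongside the published
#' scenarios are used verbatim (the chiral chasing and running angles
#' \eqn{\alpha_{c\rho} = -20^\circ}, \eqn{\alpha_{\rho c} = 70^\circ}; the
#' shorter running range \eqn{\xi_{\rho c} = 1} against \eqn{\xi = 2}
#' elsewhere for population-level chase-and-run; near-capacity initial
#' densities \eqn{C = P = 0.48} for travelling holes). The remaining
#' strengths, ranges, and domain sizes are this package's own calibrated
#' defaults, chosen so each preset sits squarely in its advertised linear
#' regime (verified through [classify_regime()]) and reproduces the
#' qualitative nonlinear behaviour at desk scale:
#'
#' * `chiral_enables_pattern` — linearly stable with parallel chase-and-run;
#'   switching on the chiral angles tips it into a stationary instability
#'   and a one-aggregate-per-species pattern.
#' * `oscillation_suppression` — a Turing-wave (oscillatory) instability at
#'   \eqn{\alpha_{\rho c} = 0}; the preset's \eqn{\alpha_{\rho c} = 75^\circ}
#'   makes the discriminant non-negative and the pattern stationary.
#' * `catch` — linear theory predicts separation (stronger chaser
#'   self-attraction), but chasing far outweighs running, so at later times
#'   the chasers progressively catch the runners and erode the separation.
#' * `escape` — mirror image: mixing predicted despite running far
#'   outweighing chasing; mixed states are markedly more robust to this
#'   nonlinear pressure than separated ones.
#' * `volume_filling_mixing` — no cross-coupling at all; the two identical
#'   self-attracting species can still end up perfectly in phase through
#'   volume filling alone.
#' * `population_chase_run` — a chaser aggregate perpetually pursues a
#'   runner aggregate; the preset is non-chiral (straight pulse), and
#'   setting `rc.alpha` to 40 degrees bends the pulse onto a curved path.
#' * `travelling_hole` — near carrying capacity, a localised low-density
#'   hole in both species travels through the high-density background.
#'
#' @param name One of `"chiral_enables_pattern"`, `"oscillation_suppression"`,
#'   `"catch"`, `"escape"`, `"volume_filling_mixing"`,
#'   `"population_chase_run"`, `"travelling_hole"`,
#'   `"growth_benchmark"`.
#' @param chiral For `chiral_enables_pattern` and `growth_benchmark`: `TRUE`
#'   (default) applies the chiral angles (-20, 70); `FALSE` gives the
#'   parallel (all-angles-zero) counterpart.
#' @return An [experiment_config()].
#' @examples
#' fixture_config("chiral_enables_pattern")$params
#' @export
fixture_config <- function(name = c("chiral_enables_pattern",
                                    "oscillation_suppression",
                                    "catch", "escape",
                                    "volume_filling_mixing",
                                    "population_chase_run",
                                    "travelling_hole",
                                    "growth_benchmark"),
                           chiral = TRUE) {
  name <- match.arg(name)
  exp_int <- function(mu, xi, alpha = 0)
    interaction(mu, xi, alpha, kernel_spec("exponential", xi))
  top_int <- function(mu, xi, alpha = 0)
    interaction(mu, xi, alpha, kernel_spec("tophat", xi))
  acr <- if (chiral) -20 else 0
  arc <- if (chiral) 70 else 0
  switch(name,
    chiral_enables_pattern = experiment_config(
      two_species_params(
        D = 1,
        cc = exp_int(24, 0.75), cr = exp_int(14.4, 0.75, acr),
        rc = exp_int(-14.4, 0.75, arc), rr = exp_int(0, 0.75),
        C = 0.2, P = 0.2, L = 12),
      N = 64, t_end = 60, output_times = seq(0, 60, 5)),
    oscillation_suppression = experiment_config(
      two_species_params(
        D = 1,
        cc = exp_int(30, 0.75), cr = exp_int(16, 0.75),
        rc = exp_int(-16, 0.75, if (chiral) 75 else 0),
        rr = exp_int(10, 0.75),
        C = 0.2, P = 0.2, L = 12),
      N = 48, t_end = 650, output_times = seq(0, 650, 5)),
    catch = experiment_config(
      two_species_params(
        D = 1,
        cc = exp_int(22, 0.75), cr = exp_int(60, 0.75, -20),
        rc = exp_int(-1, 0.75, 70), rr = exp_int(11, 0.75),
        C = 0.2, P = 0.2, L = 12),
      N = 48, t_end = 250, output_times = seq(0, 250, 10)),
    escape = experiment_config(
      two_species_params(
        D = 1,
        cc = exp_int(11, 0.75), cr = exp_int(1, 0.75, -20),
        rc = exp_int(-60, 0.75, 70), rr = exp_int(22, 0.75),
        C = 0.2, P = 0.2, L = 12),
      N = 48, t_end = 250, output_times = seq(0, 250, 10)),
    volume_filling_mixing = experiment_config(
      two_species_params(
        D = 1,
        cc = exp_int(30, 1), cr = exp_int(0, 1),
        rc = exp_int(0, 1), rr = exp_int(30, 1),
        C = 0.4, P = 0.4, L = 12),
      N = 48, t_end = 400, output_times = seq(0, 400, 20)),
    population_chase_run = experiment_config(
      two_species_params(
        D = 1,
        cc = top_int(20, 2), cr = top_int(30, 2),
        rc = top_int(-10, 1), rr = top_int(20, 2),
        C = 0.15, P = 0.15, L = 12),
      N = 48, t_end = 200, output_times = seq(0, 200, 2.5)),
    travelling_hole = experiment_config(
      two_species_params(
        D = 1,
        cc = exp_int(110, 1), cr = exp_int(75, 1),
        rc = exp_int(-5, 1), rr = exp_int(55, 1),
        C = 0.48, P = 0.48, L = 12),
      N = 48, t_end = 300, output_times = seq(0, 300, 10)),
    growth_benchmark = experiment_config(
      two_species_params(
        D = 1,
        cc = exp_int(92, 1), cr = exp_int(55.2, 1, acr),
        rc = exp_int(-55.2, 1, arc), rr = exp_int(0, 1),
        C = 0.2, P = 0.2, L = 16),
      N = 64, t_end = 2, output_times = seq(0, 2, 0.25),
      rtol = 1e-9, atol = 1e-12)
  )
}

#' List the available fixture names
#'
#' @return Character vector of preset names accepted by [fixture_config()].
#' @export
fixture_names <- function() {
  c("chiral_enables_pattern", "oscillation_suppression", "catch", "escape",
    "volume_filling_mixing", "population_chase_run", "travelling_hole",
    "growth_benchmark")
}
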