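---
title: "Chiral chase-and-run: models, linear theory, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chiral chase-and-run: models, linear theory, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(chiralchase)
```

## The models

`chiralchase` studies two populations — *chasers* with density $c(\mathbf{x}, t)$
and *runners* with density $\rho(\mathbf{x}, t)$ — that move by diffusion and by
nonlocal advection induced by sensing each other across a distance. The
distinguishing ingredient is **chirality**: the induced movement may be tilted
by a fixed angle $\alpha$ relative to the line of separation between the
interacting individuals (direct sensing) or relative to the sensed density
gradient (gradient sensing). Consistent left-right-biased escape responses of
this kind are documented in fish behaviour, and in zebrafish skin the two
interacting pigment cell types move at roughly $-20^\circ$ (xanthophore-like
chasers) and $+70^\circ$ (melanophore-like runners) off the separation axis.

In non-dimensional form the direct-sensing model is

$$
\partial_t c = \nabla^2 c - \nabla \cdot \Big( c\,\phi_c(c,\rho)
  \sum_{v \in \{c,\rho\}} \frac{\mu_{cv}}{\xi_{cv}^2} \int_{\mathbb{R}^2}
  R(\alpha_{cv})\,\hat{\mathbf{s}}\; \Omega_{cv}\!\big(s/\xi_{cv}\big)\,
  g_{cv}(v(\mathbf{x}+\mathbf{s}))\, d^2\mathbf{s} \Big),
$$

with the analogous equation for $\rho$ carrying a relative diffusivity $D$;
the gradient-sensing variant replaces the vector sum of rotated unit
separation vectors $R(\alpha)\hat{\mathbf{s}}$ by the rotated gradient of a
kernel-smoothed density, with a $\mu/\xi$ prefactor. Each of the four
couplings (chaser–chaser, chaser–runner, runner–chaser, runner–runner) has its
own signed strength $\mu$ (attraction $>0$, repulsion $<0$), range $\xi$,
angle $\alpha \in (-90^\circ, 90^\circ]$, and kernel. *Chase-and-run* means
$\mu_{c\rho} > 0$ with $\mu_{\rho c} < 0$. The volume-filling factor
$\phi = 1 - c - \rho$ throttles motion near the carrying capacity; response
functions are the identity, $g(v) = v$. There are no birth or death terms, so
both masses are conserved exactly and the homogeneous state $(C, P)$ is fixed
by the initial masses.

Two normalised kernel families are provided: exponential,
$\Omega(u) = e^{-u}/2\pi$, and tophat, $\Omega(u) = \pi^{-1}[u \le 1]$. Both
integrate to one over the plane so that $\mu$ alone carries the interaction
strength.

## Linear stability and what chirality does to it

Linearising about $(C, P)$ and expanding in modes $e^{i\mathbf{k}\cdot
\mathbf{x}} e^{\lambda t}$ reduces each coupling to a real scalar
contribution. For direct sensing

$$
\Lambda_{uv}(k) = \cos(\alpha_{uv})\; 2\pi\, U \phi_u(C,P)\,
  g'_{uv}(V)\, \frac{\mu_{uv}}{\xi_{uv}^2}\, k
  \int_0^\infty \Omega_{uv}(s/\xi_{uv})\, s\, J_1(ks)\, ds,
$$

an order-1 Hankel transform of the kernel; gradient sensing gives the same
expression with the order-0 transform and $k^2/\xi$. `hankel1()` and
`hankel0()` implement these radial integrals with closed forms where they
exist (both orders for the exponential family, order 0 for the tophat) and
adaptive quadrature otherwise (tophat order 1 involves Struve functions; we
integrate numerically to 1e-10 rather than pull in fragile special-function
code). The quadrature scheme and its tolerance are this package's choices.

The key structural fact — checked against a full two-dimensional Fourier
integral in the test suite — is that the angle enters **only through
$\cos\alpha$**: $\hat{\mathbf k}^T R(\alpha) \hat{\mathbf k} = \cos\alpha$.
Only the component of induced advection parallel to the separation (or
gradient) moves mass between crests and troughs of a perturbation; the
perpendicular component moves individuals along level sets and is invisible
to linear theory. Hence a coupling at $\alpha = 90^\circ$ is linearly inert,
and chirality can *weaken* but never *reverse* an interaction's linear effect.

The growth rates are the eigenvalues of the $2\times 2$ stability matrix,

$$
\lambda_\pm(k) = \tfrac12\Big( -(1+D)k^2 + \Lambda_{cc} + \Lambda_{\rho\rho}
 \pm \sqrt{\,4\Lambda_{c\rho}\Lambda_{\rho c}
 + \big[(1-D)k^2 + \Lambda_{\rho\rho} - \Lambda_{cc}\big]^2\,}\Big).
$$

Chase-and-run makes $\Lambda_{c\rho}\Lambda_{\rho c} < 0$, so those couplings
can only lower $\mathrm{Re}\,\lambda_+$ (suppressing patterns) and drive the
discriminant negative (promoting temporal oscillation — a Turing-wave
instability). *Differential self-interaction*, the squared bracket, opposes
both effects. Chirality scales the cross product by
$\cos\alpha_{c\rho}\cos\alpha_{\rho c}$, which is why sufficiently chiral
chase-and-run systems recover stationary Turing patterns: this is the
`chiral_enables_pattern` and `oscillation_suppression` pair of behaviours.

```{r dispersion-example}
cfg  <- fixture_config("chiral_enables_pattern")               # alpha = (-20, 70)
cfg0 <- fixture_config("chiral_enables_pattern", chiral = FALSE)
ks <- seq(0.05, 3, by = 0.05)
rbind(parallel = classify_regime(cfg0$params),
      chiral   = classify_regime(cfg$params))
```

On a periodic domain only wavenumbers $2\pi\sqrt{n^2+m^2}/L$ fit
(`admissible_wavenumbers()`); `classify_regime()` scans those by default
(per-axis index up to 12), and accepts a dense grid for infinite-domain work.
"Zero imaginary part" is judged at $|\mathrm{Im}\,\lambda| <
10^{-10}\max(1, |\mathrm{Re}\,\lambda|)$: the discriminant crossing is exact
in theory and anything smaller is floating-point noise.

When the fastest-growing mode is stationary, the sign pattern of its
eigenvector predicts species arrangement: with
$B = (1-D)k^2 + \Lambda_{\rho\rho} - \Lambda_{cc}$ and $A = +\sqrt{B^2 +
4\Lambda_{c\rho}\Lambda_{\rho c}}$ (the positive root, belonging to the faster
mode), $a_\rho / a_c = (B + A)/2\Lambda_{c\rho}$. In the chase-and-run sign
structure this reduces to: the species whose *net* self-aggregation (kernel
attraction plus diffusion) is weaker dictates the outcome — stronger chaser
self-attraction predicts **separation**, stronger runner self-attraction
predicts **mixing** (`predict_phase()`). `predict_phase()` evaluates at the
fastest-growing admissible wavenumber by default, since that mode dominates
the emerging pattern. With a negative discriminant the phase relationship
rotates in time and the prediction is refused as indeterminate.

## Discretisation

Simulations run on a cell-centred periodic $N \times N$ grid over $[0, L]^2$.
The nonlocal terms are tabulated once per run at every periodic lattice
offset — $R(\alpha)\hat{\mathbf s}\,\Omega(|\mathbf s|/\xi)\,h^2/\xi^2$ for
direct sensing, the scalar $\tilde\Omega\,h^2/\xi$ for gradient sensing — and
applied by FFT circular cross-correlation, so one right-hand-side evaluation
costs a handful of $N^2 \log N$ transforms. Numerical choices that matter:

* **Truncation.** The exponential kernel is cut off at a disc of radius $L/2$
  (interpreting "half the domain length in all directions" as a disc) so any
  two points interact at most once; truncated kernels are *not* renormalised,
  and the linear-stability transforms always use the untruncated kernel. For
  quantitative agreement between simulated growth rates and the analytic
  dispersion relation, keep $L/2 \gtrsim 8\xi$: the discarded tail then
  carries $(1 + 8)e^{-8} \approx 0.3\%$ of the mass. At $L/2 = 2\xi$ the
  truncation alone shifts growth rates by tens of percent.
* **Origin and Nyquist cells.** The $\mathbf s = 0$ entry of the vector
  kernel is zero ($\hat{\mathbf s}$ is undefined there and the continuum
  integrand is odd). Offsets on the Nyquist ring $|\mathbf s| = L/2$ are their
  own periodic mirror image and are excluded, preserving the exact
  antisymmetry that makes the homogeneous state an exact fixed point of the
  discrete operator.
* **Differential operators** are second-order central differences. Their
  divergence telescopes, so the transport terms conserve each species' grid
  sum to machine precision at every evaluation — mass conservation in the
  reported trajectories is limited only by solver rounding. Central
  differences were preferred over spectral differentiation because
  volume-filling fronts are sharp and finite differences limit Gibbs
  ringing.
* **Time integration** uses deSolve's adaptive variable-order Adams
  multistep (functional iteration). The nonlocal coupling makes the Jacobian
  fully dense, so implicit stiff methods that factor it do not scale to
  $2N^2$ unknowns; these transport systems are accuracy- rather than
  stiffness-limited at the resolutions used here, and the Adams scheme
  recovers linear growth rates to well under the measurement tolerances.
  Defaults `rtol = 1e-6`, `atol = 1e-8` sit far below the $10^{-3}$ noise
  scale of the standard initial condition. Other deSolve methods (including
  `"bdf"`) can be selected.
* **No clamping.** Densities are integrated as written; small negative
  undershoots (beyond $-10\,\mathrm{atol}$) or totals above carrying capacity
  are reported as diagnostic flags, never corrected.

The standard initial condition is the homogeneous state plus i.i.d. Gaussian
noise of standard deviation $10^{-3}$, reproducible from one integer seed
through a private generator that leaves the session's RNG untouched.

## Diagnostics

`pattern_report()` summarises a finished run. Its components:

* `phase_correlation()` — Pearson correlation of the mean-centred fields over
  cells. The published late-time states are strongly in or out of phase, so
  the classification thresholds ($\pm 0.5$) are insensitive; they are
  configurable because "mixed vs separated" has no canonical quantitative
  definition.
* `stationarity()` — stationary when the relative rate of change stays below
  $10^{-6}$ per unit time over the trailing window; oscillatory when the
  per-snapshot amplitude series (log scale, linearly detrended) has a
  dominant frequency at least $10\times$ the spectral median. The dominant
  frequency must complete more than one cycle in the window: the slowest bin
  is excluded because the residual trend of a still-converging pattern leaks
  there and is indistinguishable from sub-cycle oscillation. The detector is
  deliberately model-free: a complex linear growth rate is neither necessary
  nor sufficient for late-time oscillation.
* `count_aggregates()` — connected components (8-connectivity with periodic
  wrap) of the super-level set at `mean + frac * (max - mean)`.
* `track_objects()` — centroids by per-axis circular mean (the phase of the
  first Fourier mode), the only wrap-consistent first moment on a torus;
  paths unwrapped by nearest periodic image, optionally smoothed, and
  differentiated centrally for speed and signed curvature
  $\kappa = (\dot x \ddot y - \dot y \ddot x)/(\dot x^2 + \dot y^2)^{3/2}$.
  Holes are tracked as the deficit-weighted centroid of the lowest-density
  connected region below half the median total density; the track is flagged
  truncated if the region later vanishes.

## Scenario fixtures and the synthetic study conditions

`fixture_config()` holds one calibrated preset per headline behaviour.
Values stated with the published scenarios are used verbatim: the chiral
angle pair $(-20^\circ, 70^\circ)$, the shorter running range
$\xi_{\rho c} = 1$ against $\xi = 2$ elsewhere for population-level
chase-and-run, near-capacity densities $C = P = 0.48$ for travelling holes,
and a $40^\circ$ running angle for curved pulses. The interaction strengths,
remaining ranges, and domain sizes are this package's own calibration — each
preset was placed in its advertised linear regime using `classify_regime()`
and `dispersion()` (e.g. the oscillation-suppression preset has a negative
discriminant at its fastest-growing mode at $\alpha_{\rho c} = 0$ that turns
positive near $67^\circ$) and then frozen. Problem sizes are desk scale:
grids of $40^2$–$64^2$ and domains $L = 12$–$16$ rather than production
$100^2$ runs, which keeps the full scenario suite at minutes of CPU.

What the synthetic conditions do and do not emulate: they reproduce the
models' mathematical structure exactly (the generator *is* the model), but
say nothing about how well the models describe any real biological system;
quantitative agreement between simulation and linear theory here validates
the numerics, not the biology. Two scenario-level caveats from our
calibration, both consistent with the published account of nonlinear
robustness: a mixed state resists even a $90\times$ running-over-chasing
imbalance (so the `escape` preset demonstrates early-time prediction and
late-time erosion rather than a full reversal to separation), and the
travelling-hole preset produces deep, persistent holes whose drift at
$48^2$ desk scale is very slow.

## Known limitations

* Periodic square domains only; no-flux or mixed boundaries change which
  patterns are viable (chiral interactions induce circulation along pattern
  level sets that closed boundaries would obstruct) and are out of scope.
* Identity response functions and the linear volume-filling factor are the
  only nonlinearities implemented; the types are enums so other choices can
  be added without API changes.
* Linear theory is trusted only where it should be: early times and small
  amplitudes. Several shipped fixtures exist precisely because its late-time
  predictions fail (volume-filling mixing, catch dynamics, travelling
  holes).
* The growth-rate measurement (`measure_mode_growth()`) seeds the leading
  eigenvector; with nearly degenerate eigenvalues the subdominant mode decays
  slowly and can bias short fits.
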