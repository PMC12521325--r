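# Oracle: the per-coupling dispersion contribution evaluated from the full
# 2D Fourier integral of the rotated kernel, with no angular reduction.
# Lambda = -i k * U phi g' (mu/xi^2) khat . R(alpha) int shat Omega e^{iks}
lambda_cc_2d_oracle <- function(params, k, alpha) {
  cp <- params$cc
  xi <- cp$xi
  a <- alpha * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  nth <- 800
  th <- (seq_len(nth) - 0.5) * 2 * pi / nth
  gl <- pracma::gaussLegendre(240, 0, 30 * xi)
  # inner radial integral for each theta: int Omega(s/xi) s e^{iks cos th} ds
  E <- exp(1i * k * outer(gl$x, cos(th)))          # ns x nth
  w <- kernel_value(cp$kernel, gl$x) * gl$x * gl$w # ns
  inner <- colSums(E * w)                          # nth
  I2 <- c(sum(cos(th) * inner), sum(sin(th) * inner)) * (2 * pi / nth)
  U <- params$C
  phi <- volume_filling_factor(params$volume_filling, params$C, params$P)
  Re(-1i * k * U * phi * (cp$mu / xi^2) * drop(t(c(1, 0)) %*% R %*% I2))
}

test_that("lambda_uv matches the full 2D Fourier integral of the rotated kernel", {
  for (alpha in c(-60, 30, 70)) {
    for (k in c(0.5, 2, 5)) {
      p <- make_params(acc = alpha, xi = 1.3)
      got <- lambda_uv(p, "c", "c", k)
      expect_equal(got, lambda_cc_2d_oracle(p, k, alpha), tolerance = 1e-6)
    }
  }
})

test_that("chirality enters only through cos(alpha)", {
  ks <- c(0.5, 2, 5)
  for (sensing in c("direct", "gradient")) {
    for (fam in c("exponential", "tophat")) {
      base <- make_params(sensing = sensing, fam = fam, xi = 1.5)
      lam0 <- lambda_uv(base, "c", "c", ks)
      for (alpha in c(-60, 30, 70)) {
        p <- make_params(acc = alpha, sensing = sensing, fam = fam, xi = 1.5)
        expect_equal(lambda_uv(p, "c", "c", ks),
                     cos(alpha * pi / 180) * lam0, tolerance = 1e-12)
      }
      # a purely perpendicular coupling contributes nothing at any k
      p90 <- make_params(acc = 90, sensing = sensing, fam = fam, xi = 1.5)
      expect_equal(lambda_uv(p90, "c", "c", seq(0.1, 10, by = 0.7)),
                   rep(0, 15), tolerance = 1e-12)
    }
  }
  # mu = 0 kills the contribution too
  expect_equal(lambda_uv(make_params(mucc = 0), "c", "c", ks), rep(0, 3))
})

test_that("alpha = 90 on one coupling equals mu = 0 on that coupling for the whole curve", {
  ks <- seq(0.1, 8, by = 0.25)
  d90 <- dispersion(make_params(arc = 90), ks)
  d0 <- dispersion(make_params(murc = 0), ks)
  for (col in c("re_lambda_plus", "im_lambda_plus", "re_lambda_minus",
                "discriminant")) {
    expect_equal(d90[[col]], d0[[col]], tolerance = 1e-12)
  }
})

test_that("dispersion agrees with a generic eigensolver of the stability matrix", {
  set.seed(7)
  for (rep in 1:25) {
    p <- make_params(mucc = runif(1, -3, 3), mucr = runif(1, -3, 3),
                     murc = runif(1, -3, 3), murr = runif(1, -3, 3),
                     acc = runif(1, -89, 90), acr = runif(1, -89, 90),
                     arc = runif(1, -89, 90), arr = runif(1, -89, 90),
                     D = runif(1, 0.2, 3), xi = runif(1, 0.5, 2),
                     sensing = sample(c("direct", "gradient"), 1))
    k <- runif(1, 0.05, 6)
    d <- dispersion(p, k)
    F <- matrix(c(-k^2 + d$Lambda_cc, d$Lambda_rc,
                  d$Lambda_cr, -p$D * k^2 + d$Lambda_rr), 2, 2)
    ev <- eigen(F)$values
    lp <- ev[which.max(Re(ev))]
    lm <- ev[which.min(Re(ev))]
    expect_equal(complex(real = d$re_lambda_plus,
                         imaginary = abs(d$im_lambda_plus)),
                 complex(real = Re(lp), imaginary = abs(Im(lp))),
                 tolerance = 1e-10)
    expect_equal(d$re_lambda_minus, Re(lm), tolerance = 1e-10)
  }
})

test_that("both growth rates vanish at k = 0 and the decoupled case is block-diagonal", {
  d <- dispersion(make_params(), 0)
  expect_equal(d$re_lambda_plus, 0)
  expect_equal(d$im_lambda_plus, 0)
  expect_equal(d$re_lambda_minus, 0)
  p <- make_params(mucr = 0, murc = 0, mucc = 2, murr = 1.5, D = 1.7)
  ks <- c(0.5, 1, 2)
  d <- dispersion(p, ks)
  lc <- -ks^2 + d$Lambda_cc
  lr <- -p$D * ks^2 + d$Lambda_rr
  expect_equal(d$re_lambda_plus, pmax(lc, lr), tolerance = 1e-12)
  expect_equal(d$re_lambda_minus, pmin(lc, lr), tolerance = 1e-12)
  expect_equal(d$im_lambda_plus, rep(0, 3))
})

test_that("admissible wavenumbers enumerate the periodic lattice", {
  expect_equal(admissible_wavenumbers(2 * pi, 1), c(1, sqrt(2)))
  expect_equal(admissible_wavenumbers(8, 2),
               2 * pi / 8 * c(1, sqrt(2), 2, sqrt(5), 2 * sqrt(2)))
  for (L in c(3, 8, 12.5)) {
    expect_equal(min(admissible_wavenumbers(L, 6)), 2 * pi / L)
  }
  expect_error(admissible_wavenumbers(-1, 3))
})

test_that("classification is stable for pure diffusion and rejects bad grids", {
  p <- make_params(mucc = 0, mucr = 0, murc = 0, murr = 0, D = 1)
  expect_equal(classify_regime(p)$label, "stable")
  expect_true(is.na(classify_regime(p)$k_star))
  expect_error(classify_regime(p, k_grid = numeric(0)), "nonempty")
  expect_error(classify_regime(p, k_grid = c(0, 1)), "exclude")
})

test_that("chase-and-run couplings can only lower the growth rate", {
  # raising |Lambda_cr * Lambda_rc| with the product negative never raises
  # max Re lambda+, monotonically over the coupling magnitude
  scales <- seq(0, 2, by = 0.25)
  maxre <- vapply(scales, function(s) {
    p <- make_params(mucc = 25, murr = 18, mucr = 8 * s, murc = -8 * s,
                     xi = 0.75, L = 12)
    classify_regime(p)$max_re_lambda
  }, numeric(1))
  expect_true(all(diff(maxre) <= 1e-10))
})

test_that("growing chirality flips a Turing-wave fixture to a stationary instability", {
  mk <- function(arc) make_params(mucc = 30, mucr = 16, murc = -16,
                                  murr = 10, arc = arc, xi = 0.75, L = 12)
  expect_equal(classify_regime(mk(0))$label, "oscillatory_instability")
  expect_equal(classify_regime(mk(75))$label, "stationary_instability")
  # locate the discriminant sign change by bisection in alpha
  k_star <- classify_regime(mk(0))$k_star
  disc_at <- function(arc) dispersion(mk(arc), k_star)$discriminant
  lo <- 0; hi <- 75
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (disc_at(mid) < 0) lo <- mid else hi <- mid
  }
  expect_lt(disc_at(lo), 0)
  expect_gte(disc_at(hi), 0)
  expect_lt(hi - lo, 1e-8)
  # and labels agree on either side of the crossing at k_star's regime
  expect_equal(classify_regime(mk(hi + 3))$label, "stationary_instability")
  expect_equal(classify_regime(mk(max(lo - 3, 0)))$label,
               "oscillatory_instability")
})

test_that("phase prediction follows the relative self-aggregation strengths", {
  sep <- make_params(mucc = 22, murr = 11, mucr = 4, murc = -4,
                     acr = -20, arc = 70, xi = 0.75, L = 12)
  mix <- make_params(mucc = 11, murr = 22, mucr = 4, murc = -4,
                     acr = -20, arc = 70, xi = 0.75, L = 12)
  expect_equal(predict_phase(sep)$phase, "separated")
  expect_equal(predict_phase(mix)$phase, "mixed")
  # B = 0 forces a negative discriminant: indeterminate
  sym <- make_params(mucc = 22, murr = 22, mucr = 4, murc = -4, D = 1,
                     xi = 0.75, L = 12)
  expect_equal(predict_phase(sym, k = 0.7)$phase, "indeterminate")
  expect_lt(predict_phase(sym, k = 0.7)$discriminant, 0)
  # refuses inputs without the chase-and-run sign structure
  notcr <- make_params(mucr = -0.5, murc = -0.5)
  expect_error(predict_phase(notcr, k = 1), "chase-and-run")
})

test_that("predicted phase matches the numerically computed leading eigenvector", {
  set.seed(11)
  n_checked <- 0
  for (rep in 1:1000) {
    p <- make_params(mucc = runif(1, 0, 40), murr = runif(1, 0, 40),
                     mucr = runif(1, 0.5, 20), murc = -runif(1, 0.5, 20),
                     D = runif(1, 0.3, 3), xi = 0.75, L = 12)
    k <- runif(1, 0.3, 3)
    d <- dispersion(p, k)
    if (d$discriminant < 0) next
    pp <- predict_phase(p, k = k)
    F <- matrix(c(-k^2 + d$Lambda_cc, d$Lambda_rc,
                  d$Lambda_cr, -p$D * k^2 + d$Lambda_rr), 2, 2)
    es <- eigen(F)
    v <- Re(es$vectors[, which.max(Re(es$values))])
    oracle <- if (sign(v[1]) == sign(v[2])) "mixed" else "separated"
    expect_equal(pp$phase, oracle)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 500)
})

test_that("phase diagram grids reduce to classify_regime and respect cos-parity", {
  base <- make_params(mucc = 30, mucr = 16, murc = -16, murr = 10,
                      xi = 0.75, L = 12)
  # degenerate 1x1 grid
  pd <- phase_diagram(base, list(param = "D", values = 1),
                      list(param = "rc.alpha", values = 0))
  expect_equal(pd$label, classify_regime(base)$label)
  # alpha -> -alpha symmetry for couplings entering only via cos
  sweep <- phase_diagram(base, list(param = "D", values = c(0.8, 1.2)),
                         list(param = "rc.alpha",
                              values = c(-80, -40, 0, 40, 80)))
  for (d in c(0.8, 1.2)) {
    sub <- sweep[sweep$D == d, ]
    expect_equal(sub$label[match(c(-80, -40), sub$rc.alpha)],
                 sub$label[match(c(80, 40), sub$rc.alpha)])
  }
  # along an alpha_rc sweep at fixed D the label changes at most twice
  sweep2 <- phase_diagram(base, list(param = "D", values = 1),
                          list(param = "rc.alpha", values = seq(0, 90, 5)))
  changes <- sum(sweep2$label[-1] != sweep2$label[-nrow(sweep2)])
  expect_lte(changes, 2)
  expect_error(phase_diagram(base, list(param = "bogus", values = 1),
                             list(param = "D", values = 1)), "unknown")
})

test_that("direct and gradient sensing agree when the kernels are a derivative pair", {
  # For the exponential family, Omega = -xi d(Omega~)/ds up to the stated
  # normalisation, so the two sensing modes share one dispersion relation.
  ks <- seq(0.2, 6, by = 0.4)
  pd <- make_params(sensing = "direct", xi = 1.4)
  pg <- make_params(sensing = "gradient", xi = 1.4)
  expect_equal(lambda_uv(pd, "c", "c", ks), lambda_uv(pg, "c", "c", ks),
               tolerance = 1e-10)
  # equivalently at the transform level: k H1 / xi = k^2 H0
  spec <- kernel_spec("exponential", 1.4)
  expect_equal(ks * hankel1(spec, ks) / 1.4, ks^2 * hankel0(spec, ks),
               tolerance = 1e-12)
})
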