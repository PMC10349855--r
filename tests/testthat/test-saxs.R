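# Debye curves, Guinier fits, p(r) analysis, chi-square fitting.

test_that("Guinier underestimates Rg for elongated particles as expected", {
  # on the anisometric bound toy the qRg < 1.3 Guinier fit is biased low
  # by several percent -- the approximation's textbook behaviour, worth
  # pinning so the bias is never mistaken for an estimator bug
  conf <- toyTruth()$conformer
  q <- seq(0.006, 0.2, by = 0.002)
  cv <- debyeCurve(conf, q, weights = "uniform")
  g <- guinierRg(scatteringCurve(cv@q, cv@I, 0.01 * cv@I))$rg
  rg_p <- pofrRg(pofrFromModel(conf, bin = 0.5, weights = "uniform"))
  expect_lt(g, rg_p)                     # biased low
  expect_lt(abs(g - rg_p) / rg_p, 0.10)  # but not grossly
})

test_that("Debye curves obey the closed forms for one and two beads", {
  one <- beadConformer(matrix(0, 1, 3))
  c1 <- debyeCurve(one, seq(0.01, 0.5, by = 0.01), weights = "uniform")
  expect_true(all(c1@I == c1@I[1]))  # flat: no interference
  d <- 10
  two <- beadConformer(matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE))
  q <- seq(0.01, 0.5, by = 0.005)
  c2 <- debyeCurve(two, q, weights = "uniform")
  expect_equal(c2@I / c2@I[1] * (1 + sin(q[1] * d) / (q[1] * d)) / 2,
               (1 + sin(q * d) / (q * d)) / 2, tolerance = 1e-9)
  # I(0) equals (sum f)^2
  expect_equal(debyeCurve(two, 0, weights = "uniform")@I, 4)
})

test_that("Guinier fit recovers Rg exactly and under noise", {
  q <- seq(0.005, 0.2, by = 0.002)
  I <- 100 * exp(-q^2 * 15^2 / 3)
  g <- guinierRg(scatteringCurve(q, I, 0.01 * I))
  expect_equal(g$rg, 15, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-4)
  expect_lte(g$qrg, 1.3)
  # 1 percent noise, 100 replicates: mean within 2 percent
  set.seed(41)
  rgs <- replicate(100, {
    In <- I + rnorm(length(I), 0, 0.01 * I)
    guinierRg(scatteringCurve(q, In, 0.01 * I))$rg
  })
  expect_lt(abs(mean(rgs) - 15) / 15, 0.02)
  # no valid regime: all points beyond the qRg rule
  qq <- seq(0.2, 0.5, by = 0.01)
  expect_error(guinierRg(scatteringCurve(qq, 100 * exp(-qq^2 * 50^2 / 3))),
               "Guinier failure")
})

test_that("sphere bead cloud reproduces the analytic Guinier radius", {
  conf <- sphereCloud()
  q <- seq(0.005, 0.12, by = 0.002)
  cv <- debyeCurve(conf, q, weights = "uniform")
  g <- guinierRg(scatteringCurve(cv@q, cv@I, 0.005 * cv@I))
  expect_equal(g$rg, sqrt(3 / 5) * 20, tolerance = 0.03 * 15.5)
})

test_that("model p(r) histogram has exact Dmax, moments and scaling", {
  two <- beadConformer(matrix(c(0, 0, 0, 10, 0, 0), 2, byrow = TRUE))
  p <- pofrFromModel(two, bin = 0.5, weights = "uniform")
  expect_equal(dmax(p), 10)
  expect_equal(sum(p@p > 0), 1)  # single occupied bin
  # p(r)-based Rg equals coordinate Rg within 1 percent
  truth <- toyTruth()
  pd <- pofrFromModel(truth$conformer, bin = 0.5, weights = "uniform")
  expect_equal(pofrRg(pd), coordinateRg(truth$conformer),
               tolerance = 0.01 * coordinateRg(truth$conformer))
  # doubling the coordinates doubles Dmax and Rg
  big <- truth$conformer
  coords(big) <- 2 * coords(big)
  pd2 <- pofrFromModel(big, bin = 0.5, weights = "uniform")
  expect_equal(dmax(pd2), 2 * dmax(pd), tolerance = 1e-9)
  expect_equal(pofrRg(pd2), 2 * pofrRg(pd), tolerance = 1e-9)
})

test_that("Debye curve and p(r) are mutually consistent transforms", {
  truth <- toyTruth()
  q <- seq(0.01, 0.3, by = 0.005)
  cv <- debyeCurve(truth$conformer, q, weights = "uniform")
  pd <- pofrFromModel(truth$conformer, bin = 0.5, weights = "uniform")
  a <- atoms(truth$conformer)
  n_beads <- length(unique(paste(a$chain_id, a$residue_number)))
  sinc <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)
  # I(q) = sum f_i^2 (self term) + 2 * sum_k p_k sinc(q r_k)
  Ihat <- n_beads + vapply(q, function(qq)
    2 * sum(pd@p * sinc(qq * pd@r)), 1.0)
  expect_lt(max(abs(Ihat - cv@I) / cv@I[1]), 0.01)
})

test_that("indirect transform recovers a known p(r) and flags bad Dmax", {
  # synthesize from a 2-Gaussian mixture
  r0 <- seq(0.5, 59.5, by = 1)
  p0 <- 3 * exp(-(r0 - 18)^2 / 18) + exp(-(r0 - 38)^2 / 32)
  q <- seq(0.008, 0.35, by = 0.004)
  sinc <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)
  I <- vapply(q, function(qq) sum(p0 * sinc(qq * r0)), 1.0)
  cv <- scatteringCurve(q, I, pmax(0.002 * max(I), 0.005 * abs(I)))
  fit <- pofrFromCurve(cv, dmax_trial = 60, n_bins = 60)
  pin <- approx(r0, p0, xout = fit@r, rule = 2)$y
  expect_gt(cor(fit@p, pin), 0.99)
  expect_false(attr(fit, "large_misfit"))
  # sphere curve: p(r) peak near 1.05 R
  R <- 20
  sph <- sphereCloud(R = R)
  cs <- debyeCurve(sph, seq(0.008, 0.4, by = 0.004), weights = "uniform")
  cs <- scatteringCurve(cs@q, cs@I, 0.01 * cs@I)
  ps <- pofrFromCurve(cs, dmax_trial = 2 * R, n_bins = 50)
  expect_lt(abs(ps@r[which.max(ps@p)] - 1.05 * R), 0.1 * 1.05 * R)
  # grossly undersized Dmax is flagged
  bad <- pofrFromCurve(cs, dmax_trial = R / 2, n_bins = 30)
  expect_true(attr(bad, "large_misfit"))
})

test_that("chi-square fitting finds scale and offset and calibrates", {
  truth <- toyTruth()
  q <- seq(0.01, 0.3, length.out = 200)
  m <- debyeCurve(truth$conformer, q)
  self <- scatteringCurve(q, m@I, rep(1, length(q)))
  expect_equal(fitChi2(m, self)$chi2, 0, tolerance = 1e-12)
  # affine-transformed data recovered exactly
  aff <- scatteringCurve(q, 2 * m@I + 5, rep(1, length(q)))
  f <- fitChi2(m, aff)
  expect_equal(f$chi2, 0, tolerance = 1e-9)
  expect_equal(f$scale, 2, tolerance = 1e-9)
  expect_equal(f$offset, 5, tolerance = 1e-6)
  # unit-sigma noise: chi2 ~ 1
  set.seed(61)
  noisy <- scatteringCurve(q, m@I + rnorm(200), rep(1, 200))
  expect_equal(fitChi2(m, noisy)$chi2, 1, tolerance = 0.2)
  expect_error(fitChi2(m, scatteringCurve(0.5, 1, 1)), "overlap")
})

test_that("scattering curve files round-trip with headers ignored", {
  cv <- scatteringCurve(c(0.01, 0.02, 0.03), c(100, 90, 70), c(1, 1, 2))
  tmp <- tempfile(fileext = ".dat")
  writeScatteringCurve(cv, tmp)
  back <- readScatteringCurve(tmp)
  expect_equal(back@q, cv@q)
  expect_equal(back@I, cv@I)
  expect_equal(back@sigma, cv@sigma)
})
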