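# PRE: intensity ratios, Gamma2 conversions, restraint classification,
# back-calculation.

PREPAR <- list(tauc = 8.4, field = 600.13, t_evol = 0.01, r2_dia = 15)

test_that("intensity ratios divide element-wise with propagation", {
  para <- data.frame(residue_number = 1:4, intensity = c(50, 0, 120, 90))
  dia <- data.frame(residue_number = 1:4, intensity = c(100, 80, 100, 60))
  pr <- intensityRatio(para, dia)
  expect_equal(pr$ratio, c(0.5, 0, 1.2, 1.5))
  expect_true(pr$anomalous[4])   # ratio > 1.2 flagged
  expect_false(any(pr$anomalous[1:3]))
  # identical tables give ratio 1
  expect_true(all(intensityRatio(dia, dia)$ratio == 1))
  # non-positive diamagnetic intensities are skipped with a warning
  dia2 <- dia; dia2$intensity[2] <- 0
  expect_warning(pr2 <- intensityRatio(para, dia2), "skipped")
  expect_equal(pr2$residue_number, c(1, 3, 4))
})

test_that("ratio to Gamma2 inversion is exact and monotone", {
  # forward value from (Gamma2 = 20, R2 = 15, t = 10 ms) inverts back
  fwd <- gamma2ToRatio(20, 15, 0.01)
  expect_equal(fwd, 0.3509, tolerance = 1e-4)
  expect_equal(as.numeric(ratioToGamma2(fwd, 15, 0.01)), 20,
               tolerance = 1e-6)
  # no paramagnetic effect
  g1 <- ratioToGamma2(1, 15, 0.01)
  expect_equal(as.numeric(g1), 0)
  expect_equal(attr(g1, "flag"), "no-effect")
  g0 <- ratioToGamma2(0, 15, 0.01)
  expect_true(is.infinite(g0[1]))
  expect_equal(attr(g0, "flag"), "lower-bound-only")
  # smaller ratio, larger Gamma2
  g <- as.numeric(ratioToGamma2(c(0.8, 0.5, 0.2, 0.05), 15, 0.01))
  expect_true(all(diff(g) > 0))
})

test_that("Solomon-Bloembergen distance conversion matches the closed form", {
  # worked example ~14.2 A
  r <- gamma2ToDistance(50, PREPAR$tauc, PREPAR$field)
  K <- 1.23e-32
  om <- 2 * pi * PREPAR$field * 1e6
  tc <- PREPAR$tauc * 1e-9
  direct <- (K / 50 * (4 * tc + 3 * tc / (1 + om^2 * tc^2)))^(1 / 6) * 1e8
  expect_equal(r, direct, tolerance = 1e-12)
  expect_equal(r, 14.2, tolerance = 0.05)
  # sixth-root scaling: 64x Gamma2 halves the distance
  expect_equal(gamma2ToDistance(64 * 50, PREPAR$tauc, PREPAR$field),
               r / 2, tolerance = 1e-10)
  # monotone decreasing
  expect_true(all(diff(gamma2ToDistance(c(5, 20, 80), 8.4, 600)) < 0))
  # round trip distance -> Gamma2 -> distance
  g <- distanceToGamma2(r, PREPAR$tauc, PREPAR$field)
  expect_equal(gamma2ToDistance(g, PREPAR$tauc, PREPAR$field), r,
               tolerance = 1e-6)
  expect_error(gamma2ToDistance(-1, 8.4, 600), "undefined")
})

test_that("full inversion chain recovers distances below 0.1 A", {
  d <- seq(12, 26, by = 0.5)
  g <- distanceToGamma2(d, PREPAR$tauc, PREPAR$field)
  ratio <- gamma2ToRatio(g, PREPAR$r2_dia, PREPAR$t_evol)
  keep <- ratio > 0.05 & ratio < 0.95
  g2 <- as.numeric(ratioToGamma2(ratio[keep], PREPAR$r2_dia, PREPAR$t_evol))
  d2 <- gamma2ToDistance(g2, PREPAR$tauc, PREPAR$field)
  expect_lt(max(abs(d2 - d[keep])), 0.1)
})

test_that("restraint classification is exhaustive and threshold-driven", {
  prof <- data.frame(residue_number = 1:3, ratio = c(0.05, 0.5, 0.95))
  site <- spinLabelSite(10)
  r <- buildPreRestraints(prof, site, tauc = PREPAR$tauc,
                          field_1H = PREPAR$field, t_evol = PREPAR$t_evol,
                          r2_dia = PREPAR$r2_dia)
  expect_equal(r$class, c("upper", "quantitative", "lower"))
  expect_equal(r$lower[1], 0)
  expect_true(is.infinite(r$upper[3]))
  expect_true(r$lower[2] <= r$target[2] && r$target[2] <= r$upper[2])
  # all ratios 1: lower-bound-only everywhere
  prof1 <- data.frame(residue_number = 1:4, ratio = 1)
  r1 <- buildPreRestraints(prof1, site, tauc = PREPAR$tauc,
                           field_1H = PREPAR$field, t_evol = PREPAR$t_evol,
                           r2_dia = PREPAR$r2_dia)
  expect_true(all(r1$class == "lower"))
  # classes partition the whole ratio axis
  grid <- data.frame(residue_number = seq_along(seq(0, 1.2, 0.01)),
                     ratio = seq(0, 1.2, 0.01))
  rg <- buildPreRestraints(grid, site, tauc = PREPAR$tauc,
                           field_1H = PREPAR$field, t_evol = PREPAR$t_evol,
                           r2_dia = PREPAR$r2_dia)
  expect_true(all(rg$class %in% c("upper", "quantitative", "lower")))
  expect_error(buildPreRestraints(prof, site), "configuration")
})

test_that("error-aware classification demotes borderline ratios", {
  site <- spinLabelSite(10)
  prof <- data.frame(residue_number = 1:2, ratio = c(0.84, 0.16),
                     error = c(0.05, 0.05))
  r <- buildPreRestraints(prof, site, tauc = PREPAR$tauc,
                          field_1H = PREPAR$field, t_evol = PREPAR$t_evol,
                          r2_dia = PREPAR$r2_dia)
  expect_equal(r$class, c("lower", "upper"))
})

test_that("back-calculated profiles are monotone in distance and invert", {
  X <- cbind(seq(8, 108, by = 4), 0, 0)
  n <- nrow(X)
  at <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(atom_name = c("N", "CA", "CB"), residue_name = "ALA",
               chain_id = "A", residue_number = i, element = c("N", "C", "C"),
               x = X[i, 1] + c(0, 0.8, 0.8), y = c(0, 0, 1.5), z = 0)))
  conf <- Conformer(at)
  site <- spinLabelSite(1, offset = 6)
  bc <- backcalculatePre(conf, site, PREPAR$tauc, PREPAR$field,
                         PREPAR$t_evol, PREPAR$r2_dia)
  # further from the label: ratio increases toward 1
  expect_true(all(diff(bc$ratio[-1]) > 0))
  expect_gt(bc$ratio[n], 1 - 1e-3)  # ~100 A away: no effect
  # composition identity with the forward chain
  g <- distanceToGamma2(bc$distance, PREPAR$tauc, PREPAR$field)
  expect_equal(bc$ratio, gamma2ToRatio(g, PREPAR$r2_dia, PREPAR$t_evol),
               tolerance = 1e-12)
})

test_that("quantitative distances survive 5 percent ratio noise (RMSE)", {
  # 50-residue toy: distances spread across the quantitative window
  set.seed(13)
  d_true <- runif(50, 14, 24)
  g <- distanceToGamma2(d_true, PREPAR$tauc, PREPAR$field)
  ratio_true <- gamma2ToRatio(g, PREPAR$r2_dia, PREPAR$t_evol)
  errs <- replicate(200, {
    robs <- pmin(pmax(ratio_true * (1 + rnorm(50, 0, 0.05)), 1e-4), 0.999)
    keep <- robs >= 0.15 & robs <= 0.85
    g2 <- as.numeric(ratioToGamma2(robs[keep], PREPAR$r2_dia,
                                   PREPAR$t_evol))
    d2 <- gamma2ToDistance(g2, PREPAR$tauc, PREPAR$field)
    d2 - d_true[keep]
  })
  rmse <- sqrt(mean(unlist(errs)^2))
  expect_lt(rmse, 1.5)
})

test_that("self-consistency: restraints from a known structure hold on it", {
  truth <- toyTruth()
  rs <- simulatedRestraints(truth, seed = 19)
  quant <- rs$pre[rs$pre$class == "quantitative", ]
  ev <- restraintEnergy(truth$conformer, list(pre = quant,
                                              ambiguous = NULL))
  ok <- mean(ev$violations$violation <= 1e-9)
  expect_gte(ok, 0.9)  # >= 90 percent satisfied within bounds
})
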