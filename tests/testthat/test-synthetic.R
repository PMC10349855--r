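# Toy complex construction and forward-simulated observables.

test_that("default toy complex satisfies its structural contract", {
  truth <- toyTruth()
  conf <- truth$conformer; part <- truth$partition
  a <- atoms(conf)
  expect_true(validObject(conf))
  segs <- domainSegments(part)
  expect_equal(segs$name, c("D1", "L0", "D2", "L1", "D3", "RNA"))
  expect_equal(sum(segs$role == "flexible"), 1)
  expect_equal(sum(a$chain_id == "R") / 3, 12)  # 12-mer, 3 beads per nt
  expect_true(geometrySane(conf))
  # bound mode: RNA within restraint distance of at least 2 domains
  rna <- coords(conf)[a$chain_id == "R", ]
  near <- vapply(c("A:1-18", "A:26-33", "A:54-71"), function(sel) {
    X <- coords(conf)[selectAtoms(conf, sel), ]
    min(as.matrix(pracma::distmat(X, rna)))
  }, 1.0)
  expect_gte(sum(near < 6), 2)
  # determinism
  t2 <- makeToyComplex(toyComplexSpec())
  expect_equal(coords(t2$conformer), coords(conf))
  # infeasible spec rejected
  expect_error(toyComplexSpec(linker_lengths = c(7, 2)))
})

test_that("apo toy is strictly more extended than the bound toy", {
  truth <- toyTruth()
  apo <- makeToyComplex(toyComplexSpec(mode = "apo"))
  expect_true(geometrySane(apo$conformer))
  expect_false("R" %in% atoms(apo$conformer)$chain_id)
  d_apo <- dmax(pofrFromModel(apo$conformer))
  d_bound <- dmax(pofrFromModel(truth$conformer))
  expect_gt(d_apo, d_bound)
})

test_that("simulated observables are self-consistent at zero noise", {
  truth <- toyTruth()
  bun <- simulateObservables(truth, noise = list(pre = 0, decay = 0,
                                                 saxs = 0, itc = 0,
                                                 csp = 0), seed = 2)
  # PRE closure: profile ratios equal the direct back-calculation
  bc <- backcalculatePre(truth$conformer, truth$label_sites[[1]],
                         truth$tauc, truth$field_1H, truth$t_evol,
                         truth$r2_dia)
  expect_equal(bun$pre[[1]]$ratio, bc$ratio, tolerance = 1e-12)
  # distances recovered below 0.1 A where ratios are informative
  keep <- bun$pre[[1]]$ratio > 0.05 & bun$pre[[1]]$ratio < 0.95
  g <- as.numeric(ratioToGamma2(bun$pre[[1]]$ratio[keep], truth$r2_dia,
                                truth$t_evol))
  d <- gamma2ToDistance(g, truth$tauc, truth$field_1H)
  expect_lt(max(abs(d - bc$distance[keep])), 0.1)
  # relaxation closure: fitted rates match truth to < 0.1 percent and the
  # R2/R1 route returns the domain tauc
  r1fit <- fitRates(bun$r1_decay[bun$r1_decay$residue_number %in% 1:5, ])
  tr <- bun$rates_true[bun$rates_true$residue_number %in% 1:5, ]
  expect_lt(max(abs(r1fit$rate - tr$r1) / tr$r1), 1e-3)
  tc <- tumblingTime(tr$r2 / tr$r1, truth$field_1H)
  expect_equal(tc, rep(13, 5), tolerance = 1e-6)
  # CSP labels: exactly the contact residues are above threshold
  prof <- computeCsp(bun$free_peaks, bun$bound_peaks)
  expect_equal(selectAboveThreshold(prof), sort(truth$contact_residues))
  # SAXS closure: Guinier Rg of the noiseless curve ~ coordinate Rg of
  # the weighted bead model (within 1 percent of the p(r) route)
  g2 <- guinierRg(bun$saxs)
  expect_equal(g2$rg, pofrRg(pofrFromModel(truth$conformer)),
               tolerance = 0.01 * g2$rg)
  # ITC closure: noiseless fit returns the true thermodynamics
  fit <- fitOneSite(bun$isotherm)
  expect_equal(fit$kd, truth$kd, tolerance = 1e-4)
  expect_equal(fit$dh, truth$dh, tolerance = 1e-4)
})

test_that("PRE ratios are lower near the label than far from it", {
  truth <- toyTruth()
  bun <- simulateObservables(truth, seed = 3)
  p <- bun$pre[[1]]
  site_res <- truth$label_sites[[1]]$residue_number
  near <- p$ratio[abs(p$residue_number - site_res) <= 2]
  far <- p$ratio[abs(p$residue_number - site_res) >= 30]
  expect_lt(max(near), min(far))
})

test_that("fixture directories round-trip through the module readers", {
  truth <- toyTruth()
  bun <- simulateObservables(truth, seed = 4)
  dir <- tempfile("fixture")
  writeObservables(truth, bun, dir)
  expect_equal(readPeakTable(file.path(dir, "peaks_free.tsv")),
               bun$free_peaks, tolerance = 1e-9)
  expect_equal(readPreProfile(file.path(dir, "pre_site1.tsv"))$ratio,
               bun$pre[[1]]$ratio, tolerance = 1e-9)
  expect_equal(readDecayTable(file.path(dir, "r1_decay.tsv"))$intensity,
               bun$r1_decay$intensity, tolerance = 1e-6)
  cv <- readScatteringCurve(file.path(dir, "saxs.dat"))
  expect_equal(cv@I, bun$saxs@I, tolerance = 1e-6)
  iso <- readIsotherm(file.path(dir, "isotherm.txt"))
  expect_equal(heats(iso), heats(bun$isotherm), tolerance = 1e-5)
  conf <- readStructure(file.path(dir, "template.pdb"))
  expect_equal(length(conf), length(truth$conformer))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$tauc, truth$tauc)
})
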