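# Restraint energies and simulated annealing refinement.

test_that("restraint energy follows flat-bottom and r^-6 conventions", {
  # two fixed beads 10 A apart with a satisfiable PRE-style restraint
  at <- data.frame(
    atom_name = c("N", "CA", "CB", "N", "CA", "CB"),
    residue_name = "ALA", chain_id = "A",
    residue_number = c(1, 1, 1, 2, 2, 2), element = c("N", "C", "C"),
    x = c(0, 0.8, 0.8, 10, 10.8, 10.8), y = c(0, 0, 1.5, 0, 0, 1.5),
    z = 0)
  conf <- Conformer(at)
  mkpre <- function(lo, up) data.frame(
    residue_number = 2, chain_id = "A", site_residue = 1, site_chain = "A",
    site_offset = 0, class = "quantitative", target = (lo + up) / 2,
    lower = lo, upper = up, weight = 1, type = "pre")
  # satisfied: zero energy, zero violations
  # (amide N of residue 2 sits 10 A from the label at CA of residue 1...
  #  offset 0 so label = CA1 at (0.8,0,0): distance = 9.2)
  ok <- restraintEnergy(conf, list(pre = mkpre(8, 11), ambiguous = NULL))
  expect_equal(ok$energy, 0)
  expect_true(all(ok$violations$violation == 0))
  # violated by 1 A with unit weight: energy 1
  v <- restraintEnergy(conf, list(pre = mkpre(10.2, 12), ambiguous = NULL))
  expect_equal(v$energy, 1, tolerance = 1e-9)
  expect_equal(max(v$violations$violation), 1, tolerance = 1e-9)
  # decomposition sums exactly to the total
  expect_equal(v$energy, sum(v$breakdown), tolerance = 1e-12)
  # invariance under rigid motion
  v2 <- restraintEnergy(rigidlyMove(conf),
                        list(pre = mkpre(10.2, 12), ambiguous = NULL))
  expect_equal(v2$energy, v$energy, tolerance = 1e-9)
})

test_that("ambiguous effective distance contracts by 2^(-1/6) for twins", {
  # protein residue with one heavy atom equidistant (r) from two RNA atoms
  r <- 6
  at <- rbind(
    data.frame(atom_name = "CA", residue_name = "ALA", chain_id = "A",
               residue_number = 1, element = "C", x = 0, y = 0, z = 0),
    data.frame(atom_name = c("P", "P"), residue_name = "U", chain_id = "R",
               residue_number = c(6, 7), element = "P",
               x = c(r, -r), y = 0, z = 0))
  conf <- Conformer(at)
  amb <- buildAmbiguousRestraints(1, 6:7, target = 4, halfwidth = 1)
  ev <- restraintEnergy(conf, list(pre = NULL, ambiguous = amb),
                        energyModel(w_steric = 0))
  reff <- 2^(-1 / 6) * r
  expect_equal(max(ev$violations$violation), reff - 5, tolerance = 1e-9)
  expect_equal(ev$energy, (reff - 5)^2, tolerance = 1e-9)
  # unresolvable atoms raise a hard error naming the restraint
  bad <- buildAmbiguousRestraints(99, 6:7)
  expect_error(restraintEnergy(conf, list(pre = NULL, ambiguous = bad)),
               "unresolvable|restraint")
})

test_that("the incremental annealing evaluator matches restraintEnergy", {
  truth <- toyTruth()
  conf <- truth$conformer; part <- truth$partition
  rs <- simulatedRestraints(truth, seed = 29)
  restr <- list(pre = rs$pre, ambiguous = rs$ambiguous)
  model <- energyModel()
  ectx <- nmrflex:::.annealContext(conf, restr, part, model)
  pool <- generatePool(conf, part, samplingConfig(n_attempts = 5, seed = 9))
  for (i in seq_len(length(pool))) {
    m <- poolMember(pool, i)
    fused <- nmrflex:::.fastTotal(
      nmrflex:::.fastComponents(coords(m), ectx), model)
    ref <- restraintEnergy(m, restr, model)$energy
    expect_equal(fused, ref, tolerance = 1e-10)
  }
})

test_that("annealing is deterministic, monotone and geometry-preserving", {
  truth <- toyTruth()
  conf <- truth$conformer; part <- truth$partition
  rs <- simulatedRestraints(truth, seed = 23)
  restr <- list(pre = rs$pre, ambiguous = rs$ambiguous)
  pool <- generatePool(conf, part, samplingConfig(n_attempts = 2, seed = 4))
  start <- poolMember(pool, 1)
  sch <- annealingSchedule(steps = c(300, 200, 100),
                           amplitudes = c(60, 20, 6), polish_passes = 6)
  s1 <- anneal(start, restr, energyModel(), sch, part, seed = 99)
  s2 <- anneal(start, restr, energyModel(), sch, part, seed = 99)
  expect_equal(coords(s1$conformer), coords(s2$conformer),
               tolerance = 1e-12)
  expect_equal(s1$energy, s2$energy)
  expect_lte(s1$energy, s1$start_energy)
  expect_equal(s1$energy, sum(s1$breakdown), tolerance = 1e-9)
  # rigid-segment internal geometry preserved through refinement
  segs <- domainSegments(part)
  rigid <- segs[segs$role == "rigid", ]
  for (k in seq_len(nrow(rigid))) {
    idx <- selectAtoms(conf, sprintf("%s:%d-%d", rigid$chain_id[k],
                                     rigid$start[k], rigid$end[k]))
    expect_lt(max(abs(dist(coords(conf)[idx, ]) -
                        dist(coords(s1$conformer)[idx, ]))), 1e-6)
  }
})

test_that("a single inter-domain restraint is annealed to satisfaction", {
  truth <- toyTruth()
  conf <- truth$conformer; part <- truth$partition
  pool <- generatePool(conf, part, samplingConfig(n_attempts = 3, seed = 6))
  start <- poolMember(pool, 2)
  # one satisfiable distance restraint between D1 and D3 amides,
  # violated by ~20 A at the start
  tgt <- 20
  pre <- data.frame(residue_number = 60, chain_id = "A", site_residue = 9,
                    site_chain = "A", site_offset = 6,
                    class = "quantitative", target = tgt,
                    lower = tgt - 0.25, upper = tgt + 0.25, weight = 1,
                    type = "pre")
  e0 <- restraintEnergy(start, list(pre = pre, ambiguous = NULL))
  expect_gt(max(e0$violations$violation), 3)
  s <- anneal(start, list(pre = pre, ambiguous = NULL), energyModel(),
              annealingSchedule(steps = c(500, 300, 200),
                                amplitudes = c(60, 20, 6),
                                polish_passes = 10),
              part, seed = 17)
  expect_lt(max(s$violations$violation), 0.5)
})

test_that("annealing with no violated terms leaves energy at zero", {
  truth <- toyTruth()
  conf <- truth$conformer; part <- truth$partition
  # restraints generated from the truth itself, noise-free: satisfied
  bc <- backcalculatePre(conf, truth$label_sites[[1]], truth$tauc,
                         truth$field_1H, truth$t_evol, truth$r2_dia)
  prof <- data.frame(residue_number = bc$residue_number, ratio = bc$ratio)
  pre <- buildPreRestraints(prof, truth$label_sites[[1]],
                            tauc = truth$tauc, field_1H = truth$field_1H,
                            t_evol = truth$t_evol, r2_dia = truth$r2_dia)
  st <- restraintEnergy(conf, list(pre = pre, ambiguous = NULL))
  expect_lt(st$energy, 1e-6)
  s <- anneal(conf, list(pre = pre, ambiguous = NULL), energyModel(),
              annealingSchedule(steps = c(100, 80, 50),
                                polish_passes = 2), part, seed = 1)
  expect_lt(s$energy, 1e-6)
})

test_that("ensemble selection takes the k lowest with stable ties", {
  truth <- toyTruth()
  conf <- truth$conformer
  mk <- function(e, cf = conf) list(conformer = cf, energy = e)
  scored <- lapply(c(5, 1, 3, 1, 2), mk)
  ens <- selectEnsemble(scored, k = 3)
  expect_equal(ens$order, c(2, 4, 5))  # stable on the tie at energy 1
  expect_equal(ens$energies, c(1, 1, 2))
  # identical conformers: zero mean pairwise RMSD
  expect_equal(ens$rmsd_mean, 0, tolerance = 1e-9)
  # k = 1: stats undefined
  e1 <- selectEnsemble(scored, k = 1)
  expect_true(is.na(e1$rmsd_mean))
  expect_error(selectEnsemble(scored, k = 9), "pool size")
})

test_that("schedule validation rejects malformed cooling", {
  expect_error(annealingSchedule(scales = c(1, 3, 10)), "decreasing")
  expect_error(annealingSchedule(scales = c(5, 5, 1)), "decreasing")
  expect_error(annealingSchedule(scales = c(10, 1)), "3 stages")
  expect_error(energyModel(w_distance = 0, w_ambiguous = 0),
               "restraint term")
})
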