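# Coordinate model, PDB round trips, superposition, sterics, torsions.

test_that("PDB round trip preserves atoms, chains and coordinates", {
  tmp <- tempfile(fileext = ".pdb")
  fx <- writeTwoChainFixture(tmp)
  conf <- readStructure(tmp)
  a <- atoms(conf)
  expect_equal(nrow(a), fx$n_protein + fx$n_rna)
  expect_equal(sum(a$chain_id == "A"), fx$n_protein)
  expect_equal(sum(a$chain_id == "R"), fx$n_rna)
  expect_equal(unique(a$chain_id), c("A", "R"))  # chain order preserved
  # fixed-format precision: 3 decimals survive a second round trip
  tmp2 <- tempfile(fileext = ".pdb")
  writeStructure(conf, tmp2)
  conf2 <- readStructure(tmp2)
  expect_equal(coords(conf2), coords(conf), tolerance = 1e-9)
  # single-atom file parses to the stated coordinates
  one <- beadConformer(matrix(c(123.456, -7.89, 0.001), 1))
  tmp3 <- tempfile(fileext = ".pdb")
  writeStructure(one, tmp3)
  expect_true(any(grepl("123.456", readLines(tmp3), fixed = TRUE)))
  got <- readStructure(tmp3)
  expect_equal(length(got), 1)
  expect_equal(as.numeric(coords(got)), c(123.456, -7.89, 0.001))
})

test_that("malformed and empty PDB inputs raise informative errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  GLY A   1      xx.xxx   0.000   0.000"),
             bad)
  expect_error(readStructure(bad), "line 1")
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(readStructure(empty), "empty model")
  expect_error(writeStructure(beadConformer(matrix(0, 1, 3))[0], tempfile()))
})

test_that("superposition recovers rigid transforms and matches bio3d", {
  set.seed(11)
  X <- matrix(rnorm(30 * 3, sd = 6), 30)
  ref <- beadConformer(X)
  mob <- rigidlyMove(ref, angle = 1.1, axis = c(0.3, -1, 2),
                     shift = c(8, 1, -4))
  fit <- superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(coords(fit$fitted), coords(ref), tolerance = 1e-6)
  # identical structures: rmsd 0
  expect_lt(superpose(ref, ref)$rmsd, 1e-12)
  # non-degenerate pair: agree with bio3d least-squares fit
  Y <- X + matrix(rnorm(30 * 3, sd = 1.5), 30)
  mob2 <- beadConformer(Y)
  ours <- superpose(mob2, ref)$rmsd
  xyz_fixed <- as.vector(t(X)); xyz_mob <- as.vector(t(Y))
  fitted <- bio3d::fit.xyz(fixed = xyz_fixed, mobile = xyz_mob,
                           fixed.inds = 1:90, mobile.inds = 1:90)
  theirs <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - X)^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)
  expect_error(superpose(beadConformer(X[1:2, ]), beadConformer(X[1:2, ])),
               "insufficient")
})

test_that("backbone RMSD is symmetric and matches the d/sqrt(n) law", {
  set.seed(21)
  X <- matrix(rnorm(12 * 3, sd = 5), 12)
  a <- beadConformer(X)
  expect_equal(backboneRmsd(a, a), 0, tolerance = 1e-9)
  b <- rigidlyMove(a)
  expect_equal(backboneRmsd(a, b), backboneRmsd(b, a), tolerance = 1e-9)
  # displace one atom by d among n in a fixed frame (fit disabled)
  Y <- X; d <- 3.7
  Y[5, ] <- Y[5, ] + c(d, 0, 0)
  expect_equal(backboneRmsd(a, beadConformer(Y), fit = FALSE),
               d / sqrt(nrow(X)), tolerance = 1e-12)
})

test_that("steric energy is repulsive-only and matches a brute-force sum", {
  two <- beadConformer(matrix(c(0, 0, 0, 10, 0, 0), 2, byrow = TRUE))
  expect_equal(vdwEnergy(two), 0)
  # at contact: zero; strictly increasing as the pair approaches
  rmin <- 2 * 1.7  # C-C contact
  at <- function(r) vdwEnergy(beadConformer(
    matrix(c(0, 0, 0, r, 0, 0), 2, byrow = TRUE), chain = c("A", "B")))
  expect_equal(at(rmin), 0)
  e <- vapply(c(3.0, 2.5, 2.0, 1.5), at, 1.0)
  expect_true(all(diff(e) > 0))
  # 3-atom cluster equals the direct pairwise loop
  X <- matrix(c(0, 0, 0, 2.1, 0, 0, 1, 1.5, 0.4), 3, byrow = TRUE)
  cl <- beadConformer(X, chain = c("A", "B", "C"))
  direct <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (r < rmin) direct <- direct + (rmin - r)^4
  }
  expect_equal(vdwEnergy(cl), direct, tolerance = 1e-12)
  # invariance under rigid motion and atom order
  expect_equal(vdwEnergy(rigidlyMove(cl)), direct, tolerance = 1e-9)
})

test_that("linker torsion rotations preserve rigid geometry and bonds", {
  truth <- toyTruth()
  conf <- truth$conformer; part <- truth$partition
  tors <- data.frame(chain_id = "A", residue_number = c(40, 45),
                     dphi = c(35, -120), dpsi = c(80, 10))
  rot <- setLinkerTorsions(conf, part, tors)
  # identity when all torsions are zero
  tors0 <- transform(tors, dphi = 0, dpsi = 0)
  expect_equal(coords(setLinkerTorsions(conf, part, tors0)), coords(conf))
  # 360-degree rotation is the identity
  tors360 <- transform(tors, dphi = 360, dpsi = 360)
  expect_equal(coords(setLinkerTorsions(conf, part, tors360)),
               coords(conf), tolerance = 1e-6)
  # intra-rigid pairwise distances preserved to 1e-6 A
  segs <- domainSegments(part)
  for (k in which(segs$role == "rigid")) {
    sel <- sprintf("%s:%d-%d", segs$chain_id[k], segs$start[k], segs$end[k])
    i <- selectAtoms(conf, sel)
    d0 <- dist(coords(conf)[i, ]); d1 <- dist(coords(rot)[i, ])
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }
  # bond lengths unchanged
  expect_true(geometrySane(rot))
  # a mid-linker rotation changes the inter-domain center distance
  ctr <- function(cf, sel) colMeans(coords(cf)[selectAtoms(cf, sel), ])
  d_before <- sqrt(sum((ctr(conf, "A:1-18") - ctr(conf, "A:54-71"))^2))
  d_after <- sqrt(sum((ctr(rot, "A:1-18") - ctr(rot, "A:54-71"))^2))
  expect_gt(abs(d_after - d_before), 0.5)
  # torsions on rigid residues are rejected
  expect_error(setLinkerTorsions(conf, part, data.frame(
    chain_id = "A", residue_number = 5, dphi = 10, dpsi = 0)),
    "domain violation")
})

test_that("selection mini-language picks chains, ranges and atom names", {
  truth <- toyTruth()
  conf <- truth$conformer
  a <- atoms(conf)
  i <- selectAtoms(conf, "A:1-18")
  expect_true(all(a$chain_id[i] == "A" & a$residue_number[i] <= 18))
  j <- selectAtoms(conf, "A:1-18:CA")
  expect_equal(length(j), 18)
  k <- selectAtoms(conf, "A:1-2:CA,R:1-3")
  expect_equal(length(k), 2 + 9)
  expect_equal(selectAtoms(conf, "*"), seq_len(nrow(a)))
})
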