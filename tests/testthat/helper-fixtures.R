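# Small fixtures built in code, shared across test files.

# a minimal conformer from a coordinate matrix (one CA-like atom per row)
beadConformer <- function(X, chain = "A", atom_name = "CA",
                          element = "C") {
  n <- nrow(X)
  Conformer(data.frame(
    atom_name = atom_name, residue_name = "GLY", chain_id = chain,
    residue_number = seq_len(n), element = element,
    x = X[, 1], y = X[, 2], z = X[, 3], stringsAsFactors = FALSE))
}

# random rigid transform applied to a conformer
rigidlyMove <- function(conf, angle = 0.7, axis = c(1, 2, 3),
                        shift = c(5, -3, 2)) {
  R <- nmrflex:::.rotationMatrix(axis, angle)
  X <- coords(conf) %*% R
  coords(conf) <- sweep(X, 2, shift, `+`)
  conf
}

# two-chain toy PDB file (protein + RNA), returns path and atom counts
writeTwoChainFixture <- function(path) {
  prot <- data.frame(
    atom_name = rep(c("N", "CA", "C"), 3), residue_name = "ALA",
    chain_id = "A", residue_number = rep(1:3, each = 3), element =
      rep(c("N", "C", "C"), 3),
    x = seq(0, 8, by = 1), y = 0, z = 0, stringsAsFactors = FALSE)
  rna <- data.frame(
    atom_name = rep(c("P", "C4"), 2), residue_name = "U",
    chain_id = "R", residue_number = rep(1:2, each = 2), element =
      rep(c("P", "C"), 2),
    x = seq(0, 3, by = 1), y = 5, z = 0, stringsAsFactors = FALSE)
  writeStructure(Conformer(rbind(prot, rna)), path)
  list(path = path, n_protein = nrow(prot), n_rna = nrow(rna))
}

# globular bead cloud of radius R (uniform solid sphere)
sphereCloud <- function(n = 600, R = 20, seed = 31) {
  set.seed(seed)
  X <- matrix(runif(3 * n * 3, -R, R), ncol = 3)
  X <- X[rowSums(X^2) <= R^2, , drop = FALSE][seq_len(n), ]
  beadConformer(X)
}

# standard R1 delay grid (seconds), with duplicates
r1DelayGrid <- function() {
  c(21.6, 21.6, 86.4, 162, 248.4, 345.6, 518.4, 669.6,
    885.6, 885.6, 1144.8, 1382.4) / 1000
}

# the twelve binding-site residues named in the CSP-restraint protocol
rrm2CspResidues <- function() {
  c(231L, 232L, 233L, 236L, 238L, 262L, 265L, 268L, 274L, 276L, 278L, 313L)
}

# default bound-state toy, cached per test session
toyTruth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeToyComplex(toyComplexSpec())
    cache
  }
})

# restraint set simulated from a ground truth (the standard recovery input)
simulatedRestraints <- function(truth, seed, d3 = c(54, 71)) {
  bun <- simulateObservables(truth, seed = seed)
  profile <- computeCsp(bun$free_peaks, bun$bound_peaks)
  hits <- selectAboveThreshold(profile)
  hits_d3 <- hits[hits >= d3[1] & hits <= d3[2]]
  amb <- buildAmbiguousRestraints(hits_d3, 6:12)
  pre <- do.call(rbind, lapply(seq_along(truth$label_sites), function(i)
    buildPreRestraints(bun$pre[[i]], truth$label_sites[[i]],
                       tauc = truth$tauc, field_1H = truth$field_1H,
                       t_evol = truth$t_evol, r2_dia = truth$r2_dia)))
  list(pre = pre, ambiguous = amb, bundle = bun)
}
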