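## Headline parameter-recovery experiment: simulate observables from the
## toy ground truth, rebuild restraints, sample, anneal, and measure the
## ensemble-centroid error.

#' Run the restraint-driven recovery experiment on the toy complex
#'
#' For each seed: observables are forward-simulated from the bound toy
#' ground truth (5 percent PRE ratio noise by default), CSP hits in the
#' third domain are turned into ambiguous RNA restraints, PRE profiles
#' into flat-bottom distance restraints, a randomized linker pool is
#' generated, its lowest-restraint-energy members are annealed, and the
#' backbone C-alpha RMSD between the low-energy ensemble centroid and the
#' ground truth is recorded.
#'
#' @param truth A `"GroundTruth"` from [makeToyComplex()]; default builds
#'   the standard bound toy.
#' @param seeds Integer vector of seeds, one experiment per seed
#'   (default 1:20).
#' @param n_pool Randomization attempts per seed (default 40).
#' @param n_anneal Pool members annealed per seed, lowest initial
#'   restraint energy first (default 12).
#' @param k Ensemble size (default 10).
#' @param schedule An [annealingSchedule()].
#' @param noise Noise configuration passed to [simulateObservables()].
#' @param verbose Print one line per seed.
#' @return data.frame with columns `seed`, `centroid_rmsd` (Angstrom),
#'   `ensemble_rmsd_mean`, `min_energy`.
#' @export
recoveryExperiment <- function(truth = makeToyComplex(toyComplexSpec()),
                               seeds = 1:20, n_pool = 40, n_anneal = 12,
                               k = 10, schedule = annealingSchedule(),
                               noise = list(pre = 0.05, decay = 0.02,
                                            saxs = 0.02, itc = 1e-7,
                                            csp = 0.004),
                               verbose = FALSE) {
  conf <- truth$conformer
  part <- truth$partition
  segs <- domainSegments(part)
  d3 <- segs[segs$name == "D3", ]
  out <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    bun <- simulateObservables(truth, noise = noise, seed = seed)
    profile <- computeCsp(bun$free_peaks, bun$bound_peaks)
    hits <- selectAboveThreshold(profile)
    hits_d3 <- hits[hits >= d3$start & hits <= d3$end]
    amb <- buildAmbiguousRestraints(hits_d3, 6:12)
    pre <- do.call(rbind, lapply(seq_along(truth$label_sites), function(i)
      buildPreRestraints(bun$pre[[i]], truth$label_sites[[i]],
                         tauc = truth$tauc, field_1H = truth$field_1H,
                         t_evol = truth$t_evol, r2_dia = truth$r2_dia)))
    restr <- list(pre = pre, ambiguous = amb)
    pool <- generatePool(conf, part,
                         samplingConfig(n_attempts = n_pool, seed = seed))
    e0 <- vapply(seq_len(length(pool)), function(i)
      restraintEnergy(poolMember(pool, i), restr)$energy, 1.0)
    ordp <- order(e0)[seq_len(min(n_anneal, length(pool)))]
    scored <- lapply(seq_along(ordp), function(j)
      anneal(poolMember(pool, ordp[j]), restr, energyModel(), schedule,
             part, seed = seed * 1000L + j))
    ens <- selectEnsemble(scored, k = min(k, length(scored)),
                          partition = part)
    cen <- ensembleCentroid(ens$ensemble)
    rmsd <- backboneRmsd(cen, conf)
    out[[si]] <- data.frame(seed = seed, centroid_rmsd = rmsd,
                            ensemble_rmsd_mean = ens$rmsd_mean,
                            min_energy = min(ens$energies))
    if (verbose)
      message(sprintf("seed %d: centroid RMSD %.2f A", seed, rmsd))
  }
  do.call(rbind, out)
}
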