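## End-to-end orchestration: observables -> restraints -> pool ->
## annealing -> SAXS validation (+ ITC), with a JSON report.

#' Pipeline configuration
#'
#' @param fixture_dir Directory holding the inputs, laid out as written by
#'   [writeObservables()] (template.pdb, peaks_free.tsv, peaks_bound.tsv,
#'   pre_site*.tsv, label_sites.tsv, partition.tsv, saxs.dat,
#'   isotherm.txt, truth.json).
#' @param out_dir Output directory.
#' @param seed Master seed; all stage randomness derives from it.
#' @param alpha CSP nitrogen scaling (default 0.2).
#' @param csp_threshold CSP selection threshold, ppm (default 0.08).
#' @param csp_segment Segment name whose residues are eligible for
#'   CSP-derived ambiguous restraints (default "D3", the domain without a
#'   high-resolution complex structure).
#' @param rna_positions RNA nucleotides for the ambiguous restraints
#'   (default 6:12).
#' @param target,halfwidth Ambiguous restraint bounds, Angstrom
#'   (defaults 4 and 1).
#' @param vdw_tolerance Steric acceptance tolerance for sampling
#'   (default 0.10).
#' @param n_attempts Randomization runs (default 2000; reduce for quick
#'   runs).
#' @param n_anneal Pool members to anneal, lowest-steric first
#'   (default 20).
#' @param k Ensemble size (default 10).
#' @param schedule An [annealingSchedule()].
#' @param tauc,t_evol,r2_dia,field_1H PRE conversion parameters; NULL
#'   reads them from truth.json.
#' @return List of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(fixture_dir, out_dir = file.path(fixture_dir, "out"),
                           seed = 1, alpha = 0.2, csp_threshold = 0.08,
                           csp_segment = "D3", rna_positions = 6:12,
                           target = 4, halfwidth = 1, vdw_tolerance = 0.10,
                           n_attempts = 2000, n_anneal = 20, k = 10,
                           schedule = annealingSchedule(),
                           tauc = NULL, t_evol = NULL, r2_dia = NULL,
                           field_1H = NULL) {
  structure(as.list(environment()), class = "PipelineConfig")
}

.stageFail <- function(stage, msg) {
  stop(sprintf("pipeline aborted at stage '%s': %s", stage, msg),
       call. = FALSE)
}

#' Run the modeling pipeline
#'
#' Executes the stages in order: CSP mapping and ambiguous restraint
#' generation; PRE conversion to distance restraints; linker-randomized
#' pool generation; restraint-driven annealing and low-energy ensemble
#' selection; SAXS chi-square validation of the ensemble centroid against
#' the provided curve; one-site ITC fit. Identical config + seed give an
#' identical report. Outputs (ensemble PDB, restraint tables, energy
#' report, JSON summary) are written under `config$out_dir`.
#'
#' @param config A [pipelineConfig()].
#' @return The report list (also written as report.json), with elements
#'   per stage.
#' @export
runPipeline <- function(config) {
  fd <- config$fixture_dir
  need <- function(f, stage) {
    p <- file.path(fd, f)
    if (!file.exists(p)) .stageFail(stage, paste("missing input", f))
    p
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth_meta <- jsonlite::read_json(need("truth.json", "init"),
                                    simplifyVector = TRUE)
  prm <- function(name) {
    v <- config[[name]]
    if (is.null(v)) truth_meta[[name]] else v
  }
  template <- readStructure(need("template.pdb", "init"))
  partition <- domainPartition(utils::read.table(
    need("partition.tsv", "init"), header = TRUE, stringsAsFactors = FALSE))
  ## stage: csp
  free <- readPeakTable(need("peaks_free.tsv", "csp"))
  bound <- readPeakTable(need("peaks_bound.tsv", "csp"))
  profile <- computeCsp(free, bound, alpha = config$alpha)
  hits <- selectAboveThreshold(profile, config$csp_threshold)
  segs <- domainSegments(partition)
  segrow <- segs[segs$name == config$csp_segment, , drop = FALSE]
  if (nrow(segrow) != 1) .stageFail("csp", "csp_segment not in partition")
  hits_seg <- hits[hits >= segrow$start & hits <= segrow$end]
  if (length(hits_seg) == 0) .stageFail("csp", "no CSP hits in segment")
  amb <- buildAmbiguousRestraints(hits_seg, config$rna_positions,
                                  target = config$target,
                                  halfwidth = config$halfwidth,
                                  protein_chain = segrow$chain_id,
                                  rna_chain = "R")
  utils::write.table(profile, file.path(config$out_dir, "csp_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ## stage: pre
  site_tab_path <- need("label_sites.tsv", "pre")
  sites <- utils::read.table(site_tab_path, header = TRUE,
                             stringsAsFactors = FALSE)
  pre_list <- list()
  for (i in seq_len(nrow(sites))) {
    pf <- need(sprintf("pre_site%d.tsv", sites$site[i]), "pre")
    prof <- readPreProfile(pf)
    site <- spinLabelSite(sites$residue_number[i], sites$chain_id[i],
                          offset = sites$offset[i])
    pre_list[[i]] <- buildPreRestraints(
      prof, site, tauc = prm("tauc"), field_1H = prm("field_1H"),
      t_evol = prm("t_evol"), r2_dia = prm("r2_dia"))
  }
  pre <- do.call(rbind, pre_list)
  writeRestraints(pre, file.path(config$out_dir, "restraints_pre.tsv"))
  writeRestraints(amb, file.path(config$out_dir, "restraints_ambiguous.tsv"))
  restraints <- list(pre = pre, ambiguous = amb)
  ## stage: sample
  pool <- generatePool(template, partition,
                       samplingConfig(n_attempts = config$n_attempts,
                                      vdw_tolerance = config$vdw_tolerance,
                                      seed = config$seed))
  if (length(pool) < config$k) .stageFail("sample", "pool smaller than k")
  ## stage: anneal
  model <- energyModel()
  n_ann <- min(config$n_anneal, length(pool))
  scored <- vector("list", n_ann)
  for (i in seq_len(n_ann)) {
    scored[[i]] <- anneal(poolMember(pool, i), restraints, model,
                          config$schedule, partition,
                          seed = config$seed + i)
    scored[[i]]$id <- i
  }
  ens <- selectEnsemble(scored, k = config$k, partition = partition)
  writeStructure(ens$ensemble, file.path(config$out_dir, "ensemble.pdb"))
  energy_tab <- data.frame(
    model = seq_along(scored),
    energy = vapply(scored, `[[`, 1.0, "energy"),
    max_violation = vapply(scored, function(s)
      if (nrow(s$violations)) max(s$violations$violation) else 0, 1.0))
  utils::write.table(energy_tab, file.path(config$out_dir, "energies.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ## stage: saxs
  curve <- readScatteringCurve(need("saxs.dat", "saxs"))
  centroid <- ensembleCentroid(ens$ensemble)
  model_curve <- debyeCurve(centroid, curve@q)
  chi <- fitChi2(model_curve, curve)
  ## stage: itc
  iso <- readIsotherm(need("isotherm.txt", "itc"))
  fit <- fitOneSite(iso)
  thermo <- bindingThermodynamics(fit$kd, fit$dh, iso@temperature)
  report <- list(
    seed = config$seed,
    csp = list(n_hits = length(hits), n_hits_segment = length(hits_seg),
               n_ambiguous_restraints = nrow(amb)),
    pre = list(n_restraints = nrow(pre),
               n_quantitative = sum(pre$class == "quantitative")),
    sampling = list(attempted = pool@attempted, accepted = pool@accepted),
    annealing = list(n_annealed = n_ann,
                     ensemble_energy = unname(ens$energies),
                     rmsd_mean = ens$rmsd_mean, rmsd_sd = ens$rmsd_sd),
    saxs = list(chi2 = chi$chi2, n = chi$n),
    itc = list(kd = fit$kd, dh = fit$dh, n = fit$n, dG = thermo$dG,
               minus_TdS = thermo$minus_TdS))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}
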