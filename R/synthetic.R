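## Synthetic toy multidomain protein-RNA systems with simulated
## observables for end-to-end parameter-recovery testing.

#' Specification of a toy multidomain protein-RNA complex
#'
#' The default emulates a three-domain RNA-binding protein: two rigid
#' modules (an RRM-like domain coupled to a small ZnF-like domain through
#' a short rigid linker) and a second RRM-like domain connected through a
#' long flexible linker, bound to a 12-mer single-stranded RNA.
#'
#' @param domain_lengths Residues per rigid domain (default c(18, 8, 18)).
#' @param linker_lengths Residues per linker (default c(7, 20): a short
#'   rigid L0-like linker and a 20-residue flexible L1-like linker).
#' @param rna_length Nucleotides (default 12).
#' @param mode `"bound"` (compact, domains folded onto the RNA) or
#'   `"apo"` (extended, no RNA).
#' @param seed Integer seed; construction is deterministic.
#' @return List of class `"ToyComplexSpec"`.
#' @export
toyComplexSpec <- function(domain_lengths = c(18, 8, 18),
                           linker_lengths = c(7, 20), rna_length = 12,
                           mode = c("bound", "apo"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(all(domain_lengths >= 1), all(linker_lengths >= 3),
            rna_length >= 1)
  structure(list(domain_lengths = domain_lengths,
                 linker_lengths = linker_lengths, rna_length = rna_length,
                 mode = mode, seed = as.integer(seed)),
            class = "ToyComplexSpec")
}

# coarse-grained geometry constants
.STEP_LINKER <- 3.3   # A per linker residue along the path
.HELIX_RISE <- 1.5    # A per residue along a domain helix axis
.HELIX_RADIUS <- 2.3  # CA helix radius (alpha-helix-like)
.HELIX_TWIST <- 100   # degrees per residue
.ZIG <- 0.9           # alternating z offset on linkers (non-collinearity)
.BOND_OFFSET <- 0.8   # N/C placement along the local chain direction
.RNA_LIFT <- 6.5      # RNA path height above the smoothed protein axis

# CA trace: rigid domains are alpha-helix-like coils along the current
# path direction; linkers are semi-extended steps with a z zig-zag. The
# in-plane direction angle per residue (degrees) sets turns.
.caTrace <- function(angles_deg, is_domain) {
  n <- length(angles_deg)
  ca <- matrix(0, n, 3)
  pos <- c(0, 0, 0)
  k <- 0  # position within the current helix
  for (i in seq_len(n)) {
    phi <- angles_deg[i] * pi / 180
    a <- c(cos(phi), sin(phi), 0)
    b <- c(-sin(phi), cos(phi), 0)
    cz <- c(0, 0, 1)
    if (is_domain[i]) {
      k <- if (i > 1 && is_domain[i - 1]) k + 1 else 1
      th0 <- (k - 1) * .HELIX_TWIST * pi / 180
      th1 <- k * .HELIX_TWIST * pi / 180
      step <- .HELIX_RISE * a +
        .HELIX_RADIUS * ((cos(th1) - cos(th0)) * b +
                           (sin(th1) - sin(th0)) * cz)
      pos <- pos + step
    } else {
      k <- 0
      pos <- pos + .STEP_LINKER * a
      pos[3] <- 0.5 * pos[3] + .ZIG * (-1)^i  # relax z toward a zig-zag
    }
    ca[i, ] <- pos
  }
  ca
}

# running mean of the CA trace ~ local chain axis
.smoothTrace <- function(ca, half = 2) {
  n <- nrow(ca)
  t(vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    colMeans(ca[idx, , drop = FALSE])
  }, numeric(3)))
}

.proteinAtoms <- function(ca, chain = "A") {
  n <- nrow(ca)
  u <- ca - ca[c(1, seq_len(n - 1)), , drop = FALSE]   # incoming direction
  u[1, ] <- ca[2, ] - ca[1, ]
  v <- ca[c(seq_len(n)[-1], n), , drop = FALSE] - ca   # outgoing direction
  v[n, ] <- u[n, ]
  norm1 <- function(m) m / sqrt(rowSums(m^2))
  u <- norm1(u); v <- norm1(v)
  # side-chain direction: radial from the local chain axis (outward on
  # helices), falling back to the in-plane normal where degenerate
  sm <- .smoothTrace(ca)
  w <- ca - sm
  wn <- sqrt(rowSums(w^2))
  flat <- wn < 0.5
  w[flat, ] <- cbind(-u[flat, 2], u[flat, 1], 0)
  wn <- sqrt(rowSums(w^2))
  w[wn < 1e-6, ] <- rep(c(0, 1, 0), each = sum(wn < 1e-6))
  w <- norm1(w)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- data.frame(
      atom_name = c("N", "CA", "C", "CB"),
      residue_name = "ALA", chain_id = chain, residue_number = i,
      element = c("N", "C", "C", "C"),
      x = c(ca[i, 1] - .BOND_OFFSET * u[i, 1], ca[i, 1],
            ca[i, 1] + .BOND_OFFSET * v[i, 1], ca[i, 1] + 1.5 * w[i, 1]),
      y = c(ca[i, 2] - .BOND_OFFSET * u[i, 2], ca[i, 2],
            ca[i, 2] + .BOND_OFFSET * v[i, 2], ca[i, 2] + 1.5 * w[i, 2]),
      z = c(ca[i, 3] - .BOND_OFFSET * u[i, 3], ca[i, 3],
            ca[i, 3] + .BOND_OFFSET * v[i, 3], ca[i, 3] + 1.5 * w[i, 3]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# resample a piecewise-linear path to n equidistant points
.resamplePath <- function(waypoints, n) {
  seg <- sqrt(rowSums(diff(waypoints)^2))
  s <- c(0, cumsum(seg))
  tgt <- seq(0, s[length(s)], length.out = n)
  t(vapply(tgt, function(d) {
    j <- max(which(s <= d + 1e-9)); j <- min(j, nrow(waypoints) - 1)
    f <- (d - s[j]) / max(s[j + 1] - s[j], 1e-9)
    waypoints[j, ] + f * (waypoints[j + 1, ] - waypoints[j, ])
  }, numeric(3)))
}

.rnaAtoms <- function(path, chain = "R") {
  n <- nrow(path)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- data.frame(
      atom_name = c("P", "C4", "N1"), residue_name = "U",
      chain_id = chain, residue_number = i, element = c("P", "C", "N"),
      x = path[i, 1] + c(-1.2, 0, 1.2), y = path[i, 2] + c(0.8, 0, -0.8),
      z = path[i, 3] + c(0, 0, 0), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build a toy multidomain protein-RNA complex with known ground truth
#'
#' Constructs a pseudo-atomic (N/CA/C + CB) protein chain along a
#' coarse-grained folded path: in the bound mode the flexible linker makes
#' a U-turn so the third domain packs antiparallel against the first
#' module and a 12-mer RNA bead chain (P/C4/N1 per nucleotide) runs in the
#' groove contacting both; in the apo mode the path is extended and no RNA
#' is present, so the apo Dmax strictly exceeds the bound Dmax.
#'
#' @param spec A [toyComplexSpec()].
#' @return List of class `"GroundTruth"`: `conformer`, `partition`,
#'   `label_sites` (spin labels, one in domain 1 and two in domain 3),
#'   `tauc` (overall, ns), `domain_tauc` (per segment), `field_1H` (MHz),
#'   `t_evol` (s), `r2_dia` (1/s), `kd` (M), `dh` (kcal/mol), `n_sites`,
#'   `rna_chain`, `contact_residues` (protein residues within the CSP
#'   contact cutoff of RNA), `spec`.
#' @export
makeToyComplex <- function(spec = toyComplexSpec()) {
  dl <- spec$domain_lengths; ll <- spec$linker_lengths
  if (length(dl) != 3 || length(ll) != 2)
    stop("construction error: expected 3 domains and 2 linkers")
  nres <- sum(dl) + sum(ll)
  b <- cumsum(c(dl[1], ll[1], dl[2], ll[2], dl[3]))
  seg <- data.frame(
    name = c("D1", "L0", "D2", "L1", "D3"), chain_id = "A",
    start = c(1, b[1] + 1, b[2] + 1, b[3] + 1, b[4] + 1),
    end = b, role = c("rigid", "rigid", "rigid", "flexible", "rigid"),
    stringsAsFactors = FALSE)
  is_domain <- rep(TRUE, nres)
  lin <- c(seq(seg$start[2], seg$end[2]), seq(seg$start[4], seg$end[4]))
  is_domain[lin] <- FALSE
  angles <- rep(0, nres)
  if (spec$mode == "bound") {
    # tight U-turn early in L1 so the third domain packs antiparallel
    # against the first module across a narrow RNA-binding groove
    l1 <- seq(seg$start[4], seg$end[4])
    turn <- l1[seq_len(min(6, length(l1)))]
    angles[turn] <- seq(0, 180, length.out = length(turn) + 1)[-1]
    after <- seq(max(turn) + 1, nres)
    angles[after] <- 180
  }
  ca <- .caTrace(angles, is_domain)
  prot <- .proteinAtoms(ca)
  atoms_all <- prot
  contact <- integer()
  if (spec$mode == "bound" && spec$rna_length >= 2) {
    sm <- .smoothTrace(ca)
    d1_idx <- seq(seg$start[1], seg$end[1])
    d3_idx <- seq(seg$start[5], seg$end[5])
    l0_idx <- seq(seg$start[2], seg$end[2])
    ymid <- (mean(sm[d1_idx, 2]) + mean(sm[d3_idx, 2])) / 2
    xleft <- min(c(sm[d1_idx, 1], sm[d3_idx, 1])) - 2
    xright <- max(min(sm[d1_idx, 1]), min(sm[d3_idx, 1])) +
      0.75 * (min(max(sm[d1_idx, 1]), max(sm[d3_idx, 1])) -
                max(min(sm[d1_idx, 1]), min(sm[d3_idx, 1])))
    l0mid <- colMeans(sm[l0_idx, , drop = FALSE])
    # 5' end emerges near the short-linker module, 3' half threads the
    # inter-domain groove in-plane
    way <- rbind(c(l0mid[1], l0mid[2] + 5, 0),
                 c(xright, ymid, 0),
                 c(xleft, ymid, 0))
    path <- .resamplePath(way, spec$rna_length)
    rna <- .rnaAtoms(path)
    atoms_all <- rbind(prot, rna)
    # CSP contact labels: protein residues whose CA lies within 7 A of an
    # RNA bead -- the RNA-facing surface, as amide CSPs report the
    # interface rather than the whole domain
    D <- as.matrix(stats::dist(rbind(ca, path)))
    dmin <- apply(D[seq_len(nres), nres + seq_len(spec$rna_length),
                    drop = FALSE], 1, min)
    contact <- as.integer(which(dmin < 7.0))
    seg <- rbind(seg, data.frame(name = "RNA", chain_id = "R", start = 1,
                                 end = spec$rna_length, role = "rigid"))
  }
  conf <- Conformer(atoms_all)
  part <- domainPartition(seg)
  mid <- function(k) round((seg$start[k] + seg$end[k]) / 2)
  # one label in domain 1, three across domain 3 (the experimental layout:
  # one site in the first RRM, three across the second)
  sites <- list(spinLabelSite(mid(1), "A"),
                spinLabelSite(seg$start[5] + 2, "A"),
                spinLabelSite(mid(5), "A"),
                spinLabelSite(seg$end[5] - 2, "A"))
  domain_tauc <- c(D1 = 13, L0 = 13, D2 = 13, L1 = 5, D3 = 12)
  structure(list(conformer = conf, partition = part, label_sites = sites,
                 tauc = 13, domain_tauc = domain_tauc, field_1H = 600.13,
                 t_evol = 0.02, r2_dia = 15, kd = 0.133e-6, dh = -19.1,
                 n_sites = 1, rna_chain = "R",
                 contact_residues = contact, spec = spec),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth toy complex (%s mode): %d atoms, tauc %.1f ns, KD %.3g M\n",
              x$spec$mode, length(x$conformer), x$tauc, x$kd))
  invisible(x)
}

# inverse of the R2/R1 tumbling estimator
.r2r1FromTauc <- function(tauc_ns, field_1H) {
  nuN <- field_1H * 1e6 * .NH_FREQ_RATIO
  ((4 * pi * nuN * tauc_ns * 1e-9)^2 + 7) / 6
}

.residueTauc <- function(truth) {
  s <- domainSegments(truth$partition)
  s <- s[s$chain_id == "A", , drop = FALSE]
  res <- unlist(lapply(seq_len(nrow(s)), function(i)
    seq(s$start[i], s$end[i])))
  tc <- unlist(lapply(seq_len(nrow(s)), function(i)
    rep(truth$domain_tauc[[s$name[i]]], s$end[i] - s$start[i] + 1)))
  data.frame(residue_number = res, tauc = tc)[order(res), ]
}

.simDecayTable <- function(rates, delays, noise) {
  rows <- lapply(seq_len(nrow(rates)), function(i) {
    I <- 100 * exp(-rates$rate[i] * delays)
    I <- I * (1 + stats::rnorm(length(delays), 0, noise))
    data.frame(residue_number = rates$residue_number[i], delay_s = delays,
               intensity = I)
  })
  do.call(rbind, rows)
}

#' Simulate every observable of the pipeline from a ground truth
#'
#' Forward-simulates PRE intensity-ratio profiles per spin label (via the
#' Solomon-Bloembergen chain), free/bound HSQC peak tables whose combined
#' CSP exceeds 0.08 ppm exactly for the RNA-contact residues, 15N R1 and
#' R1rho decay tables on standard delay grids with duplicate delays, a
#' SAXS curve (Debye model), and a one-site ITC isotherm.
#'
#' @param truth A `"GroundTruth"` from [makeToyComplex()].
#' @param noise Named list of noise levels: `pre` (relative SD on ratios,
#'   default 0.05), `decay` (relative intensity SD, 0.02), `saxs`
#'   (relative SD, 0.02), `itc` (kcal SD per injection, 1e-7), `csp`
#'   (ppm jitter on non-contact residues, 0.004).
#' @param seed Integer seed.
#' @return List of class `"ObservableBundle"`: `pre` (list of profiles,
#'   one per label site), `free_peaks`, `bound_peaks`, `r1_decay`,
#'   `r1rho_decay`, `offsets` (per-residue nu1/delta_nu/field),
#'   `rates_true`, `saxs` ([ScatteringCurve-class]), `isotherm`
#'   ([Isotherm-class]), `noise`, `seed`.
#' @export
simulateObservables <- function(truth,
                                noise = list(pre = 0.05, decay = 0.02,
                                             saxs = 0.02, itc = 1e-7,
                                             csp = 0.004),
                                seed = 1) {
  set.seed(seed)
  conf <- truth$conformer
  a <- atoms(conf)
  prot_res <- sort(unique(a$residue_number[a$chain_id == "A"]))
  ## PRE profiles per site
  pre <- lapply(truth$label_sites, function(site) {
    bc <- backcalculatePre(conf, site, truth$tauc, truth$field_1H,
                           truth$t_evol, truth$r2_dia, chain_id = "A")
    ratio <- bc$ratio * (1 + stats::rnorm(nrow(bc), 0, noise$pre))
    data.frame(residue_number = bc$residue_number,
               ratio = pmax(ratio, 0), error = noise$pre * pmax(bc$ratio, 0.05))
  })
  ## peak tables: contacts get CSP > 0.08, others stay below threshold
  nres <- length(prot_res)
  free <- data.frame(residue_number = prot_res, residue_name = "ALA",
                     dH_ppm = 7.6 + stats::runif(nres, 0, 1.6),
                     dN_ppm = 108 + stats::runif(nres, 0, 22),
                     intensity = 1e5 * stats::runif(nres, 0.5, 1.5))
  bound <- free
  is_contact <- prot_res %in% truth$contact_residues
  dH <- ifelse(is_contact,
               (0.10 + stats::runif(nres, 0, 0.20)) *
                 sign(stats::runif(nres) - 0.5),
               stats::rnorm(nres, 0, noise$csp))
  dN <- ifelse(is_contact,
               (0.5 + stats::runif(nres, 0, 1.0)) *
                 sign(stats::runif(nres) - 0.5),
               stats::rnorm(nres, 0, 5 * noise$csp))
  bound$dH_ppm <- free$dH_ppm + dH
  bound$dN_ppm <- free$dN_ppm + dN
  ## relaxation decays
  rtab <- .residueTauc(truth)
  ratio21 <- .r2r1FromTauc(rtab$tauc, truth$field_1H)
  r1 <- 12 / rtab$tauc
  r2 <- ratio21 * r1
  nu1 <- 2000
  dnu <- stats::runif(nrow(rtab), -400, 400)
  theta <- atan2(nu1, dnu)
  r1rho <- r1 * cos(theta)^2 + r2 * sin(theta)^2
  r1_delays <- c(21.6, 21.6, 86.4, 162, 248.4, 345.6, 518.4, 669.6,
                 885.6, 885.6, 1144.8, 1382.4) / 1000
  r1rho_delays <- c(5, 5, 10, 15, 20, 40, 80, 100, 100, 130, 160, 180) / 1000
  r1_decay <- .simDecayTable(
    data.frame(residue_number = rtab$residue_number, rate = r1),
    r1_delays, noise$decay)
  r1rho_decay <- .simDecayTable(
    data.frame(residue_number = rtab$residue_number, rate = r1rho),
    r1rho_delays, noise$decay)
  offsets <- data.frame(residue_number = rtab$residue_number, nu1 = nu1,
                        delta_nu = dnu, field_1H = truth$field_1H)
  rates_true <- data.frame(residue_number = rtab$residue_number,
                           tauc = rtab$tauc, r1 = r1, r2 = r2,
                           r1rho = r1rho)
  ## SAXS
  q <- seq(0.01, 0.35, length.out = 120)
  ideal <- debyeCurve(conf, q)
  sig <- noise$saxs * ideal@I
  saxs <- scatteringCurve(q, ideal@I + stats::rnorm(length(q), 0, sig), sig)
  ## ITC
  proto <- isotherm(cellVolume = 200e-6, cellConc = 10e-6,
                    syringeConc = 130e-6, injVolumes = rep(1.5e-6, 26))
  iso <- simulateIsotherm(truth$kd, truth$dh, truth$n_sites, proto,
                          noise = noise$itc)
  structure(list(pre = pre, free_peaks = free, bound_peaks = bound,
                 r1_decay = r1_decay, r1rho_decay = r1rho_decay,
                 offsets = offsets, rates_true = rates_true, saxs = saxs,
                 isotherm = iso, noise = noise, seed = seed),
            class = "ObservableBundle")
}

#' Write an observable bundle as a self-contained fixture directory
#'
#' Writes the toy structure (PDB), peak tables, decay tables, PRE
#' profiles, SAXS curve (.dat), isotherm and a JSON provenance record,
#' each readable by its consuming function without modification.
#'
#' @param truth A `"GroundTruth"`.
#' @param bundle An `"ObservableBundle"` from [simulateObservables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeObservables <- function(truth, bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  writeStructure(truth$conformer, file.path(dir, "template.pdb"))
  wt(bundle$free_peaks, "peaks_free.tsv")
  wt(bundle$bound_peaks, "peaks_bound.tsv")
  wt(bundle$r1_decay, "r1_decay.tsv")
  wt(bundle$r1rho_decay, "r1rho_decay.tsv")
  wt(bundle$offsets, "offsets.tsv")
  for (i in seq_along(bundle$pre))
    writePreProfile(bundle$pre[[i]], file.path(dir,
                                               sprintf("pre_site%d.tsv", i)))
  writeScatteringCurve(bundle$saxs, file.path(dir, "saxs.dat"))
  writeIsotherm(bundle$isotherm, file.path(dir, "isotherm.txt"))
  site_tab <- data.frame(
    site = seq_along(truth$label_sites),
    residue_number = vapply(truth$label_sites, `[[`, 1L, "residue_number"),
    chain_id = vapply(truth$label_sites, `[[`, "", "chain_id"),
    offset = vapply(truth$label_sites, `[[`, 1.0, "offset"))
  wt(site_tab, "label_sites.tsv")
  wt(domainSegments(truth$partition), "partition.tsv")
  jsonlite::write_json(
    list(seed = bundle$seed, noise = bundle$noise, tauc = truth$tauc,
         field_1H = truth$field_1H, t_evol = truth$t_evol,
         r2_dia = truth$r2_dia, kd = truth$kd, dh = truth$dh,
         n_sites = truth$n_sites, mode = truth$spec$mode),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
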