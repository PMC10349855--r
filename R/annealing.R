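## Restraint energies and Metropolis simulated annealing in torsion space.

#' Energy model weights
#'
#' @param w_distance Weight of the flat-bottom PRE distance term
#'   (harmonic outside bounds; default 1).
#' @param w_ambiguous Weight of the ambiguous CSP term, evaluated on the
#'   r^-6-summed effective distance (default 1).
#' @param w_steric Weight of the bead-level steric repulsion (default 0.1).
#' @param w_bonded Weight of the linker bonded-geometry term (default 1;
#'   torsion-space moves keep bonds exact so this term is normally 0).
#' @return A list of class `"EnergyModel"`.
#' @export
energyModel <- function(w_distance = 1, w_ambiguous = 1, w_steric = 0.1,
                        w_bonded = 1) {
  stopifnot(w_distance >= 0, w_ambiguous >= 0, w_steric >= 0, w_bonded >= 0)
  if (w_distance == 0 && w_ambiguous == 0)
    stop("at least one restraint term must be active")
  structure(list(w_distance = w_distance, w_ambiguous = w_ambiguous,
                 w_steric = w_steric, w_bonded = w_bonded),
            class = "EnergyModel")
}

#' Three-stage annealing schedule
#'
#' @param scales Temperature-like scales, strictly decreasing, length 3
#'   (default c(30, 6, 1); energy units).
#' @param steps Metropolis steps per stage (default c(600, 400, 250)).
#' @param amplitudes Torsion move amplitudes in degrees per stage
#'   (default c(60, 20, 6)).
#' @param polish_passes Maximum sweeps per step size of the deterministic
#'   cyclic coordinate descent run after the last stage (step ladder
#'   16 -> 0.5 degrees; default 50, i.e. effectively sweep-to-convergence;
#'   0 disables).
#' @param polish_budget Total proposal budget of the coordinate descent
#'   (default 12000); caps the runtime of slowly converging runs, whose
#'   members are then discarded by energy-based ensemble selection.
#' @return A list of class `"AnnealingSchedule"`.
#' @export
annealingSchedule <- function(scales = c(30, 6, 1),
                              steps = c(600, 400, 250),
                              amplitudes = c(60, 20, 6),
                              polish_passes = 50,
                              polish_budget = 12000) {
  if (length(scales) != 3 || length(steps) != 3 || length(amplitudes) != 3)
    stop("configuration error: schedule must have exactly 3 stages")
  if (any(diff(scales) >= 0))
    stop("configuration error: stage scales must be strictly decreasing")
  structure(list(scales = scales, steps = as.integer(steps),
                 amplitudes = amplitudes,
                 polish_passes = as.integer(polish_passes),
                 polish_budget = as.integer(polish_budget)),
            class = "AnnealingSchedule")
}

# split a combined restraint data.frame by type
.splitRestraints <- function(restraints) {
  if (is.data.frame(restraints)) {
    list(pre = restraints[restraints$type == "pre", , drop = FALSE],
         ambiguous = restraints[restraints$type == "ambiguous", ,
                                drop = FALSE])
  } else {
    list(pre = restraints$pre, ambiguous = restraints$ambiguous)
  }
}

# Precompute atom indices for fast restraint evaluation.
.restraintContext <- function(conformer, restraints) {
  a <- atoms(conformer)
  rs <- .splitRestraints(restraints)
  pre <- rs$pre; amb <- rs$ambiguous
  pctx <- NULL
  if (!is.null(pre) && nrow(pre) > 0) {
    iN <- iCA <- iCB <- integer(nrow(pre))
    for (i in seq_len(nrow(pre))) {
      iN[i] <- .one(.atomIndex(a, pre$chain_id[i], pre$residue_number[i], "N"),
                    sprintf("pre restraint %d: amide proxy N %s:%d", i,
                            pre$chain_id[i], pre$residue_number[i]))
      iCA[i] <- .one(.atomIndex(a, pre$site_chain[i], pre$site_residue[i],
                                "CA"),
                     sprintf("pre restraint %d: label CA", i))
      cb <- .atomIndex(a, pre$site_chain[i], pre$site_residue[i], "CB")
      iCB[i] <- if (length(cb) == 1) cb else NA_integer_
    }
    pctx <- list(iN = iN, iCA = iCA, iCB = iCB, off = pre$site_offset,
                 lo = pre$lower, up = pre$upper, w = pre$weight)
  }
  actx <- NULL
  if (!is.null(amb) && nrow(amb) > 0) {
    pair_i <- pair_j <- grp <- integer()
    for (g in seq_len(nrow(amb))) {
      pi_ <- which(a$chain_id == amb$protein_chain[g] &
                     a$residue_number == amb$residue_number[g] &
                     a$element != "H")
      pos <- as.integer(strsplit(amb$rna_positions[g], ",")[[1]])
      ri <- which(a$chain_id == amb$rna_chain[g] &
                    a$residue_number %in% pos & a$element != "H")
      if (length(pi_) == 0 || length(ri) == 0)
        stop(sprintf("ambiguous restraint %d: unresolvable atoms", g))
      eg <- expand.grid(i = pi_, j = ri)
      pair_i <- c(pair_i, eg$i); pair_j <- c(pair_j, eg$j)
      grp <- c(grp, rep(g, nrow(eg)))
    }
    actx <- list(pair_i = pair_i, pair_j = pair_j, grp = grp,
                 n = nrow(amb), lo = amb$lower, up = amb$upper,
                 w = amb$weight)
  }
  list(pre = pctx, amb = actx)
}

.one <- function(idx, what) {
  if (length(idx) != 1) stop("unresolvable atom: ", what)
  idx
}

.evalRestraints <- function(X, rctx) {
  pre_v <- amb_v <- numeric()
  e_pre <- e_amb <- 0
  p <- rctx$pre
  if (!is.null(p)) {
    ca <- X[p$iCA, , drop = FALSE]
    lab <- ca
    has_cb <- !is.na(p$iCB)
    if (any(has_cb)) {
      cb <- X[p$iCB[has_cb], , drop = FALSE]
      u <- cb - ca[has_cb, , drop = FALSE]
      u <- u / sqrt(rowSums(u^2))
      lab[has_cb, ] <- ca[has_cb, , drop = FALSE] + p$off[has_cb] * u
    }
    d <- sqrt(rowSums((X[p$iN, , drop = FALSE] - lab)^2))
    pre_v <- pmax(0, p$lo - d, d - p$up)
    e_pre <- sum(p$w * pre_v^2)
  }
  am <- rctx$amb
  if (!is.null(am)) {
    dx <- X[am$pair_i, 1] - X[am$pair_j, 1]
    dy <- X[am$pair_i, 2] - X[am$pair_j, 2]
    dz <- X[am$pair_i, 3] - X[am$pair_j, 3]
    r6 <- (dx * dx + dy * dy + dz * dz)^(-3)
    s <- as.vector(rowsum(r6, am$grp))
    deff <- s^(-1 / 6)
    amb_v <- pmax(0, am$lo - deff, deff - am$up)
    e_amb <- sum(am$w * amb_v^2)
  }
  list(e_pre = e_pre, e_amb = e_amb, pre_viol = pre_v, amb_viol = amb_v)
}

#' Restraint energy and violations of a conformer
#'
#' Flat-bottom terms: zero inside `[lower, upper]`, harmonic
#' (weight x violation^2) outside. Ambiguous restraints are evaluated on
#' the r^-6-summed effective distance
#' \eqn{r_{eff} = (\sum_{pairs} r^{-6})^{-1/6}} over their heavy-atom
#' pairs. The total also includes the weighted bead-level steric term.
#'
#' @param conformer A [Conformer-class].
#' @param restraints A combined restraint data.frame (with a `type`
#'   column, `"pre"`/`"ambiguous"`) or a list with elements `pre` and
#'   `ambiguous`.
#' @param model An [energyModel()].
#' @return List with `energy` (total), `breakdown` (named terms summing
#'   exactly to the total) and `violations` (data.frame: restraint type,
#'   index, violation in Angstrom).
#' @export
restraintEnergy <- function(conformer, restraints, model = energyModel()) {
  rctx <- .restraintContext(conformer, restraints)
  X <- coords(conformer)
  ev <- .evalRestraints(X, rctx)
  a <- atoms(conformer)
  si <- .stericIndices(a)
  e_st <- if (model$w_steric > 0 && length(si) >= 2) {
    rad <- .vdwRadius(a$element[si])
    Rmin <- outer(rad, rad, `+`)
    excl <- outer(a$chain_id[si], a$chain_id[si], `==`) &
      abs(outer(a$residue_number[si], a$residue_number[si], `-`)) <= 1
    excl[lower.tri(excl, diag = TRUE)] <- TRUE
    D <- as.matrix(stats::dist(X[si, , drop = FALSE]))
    viol <- D < Rmin & !excl
    if (any(viol)) sum((Rmin[viol] - D[viol])^4) else 0
  } else 0
  breakdown <- c(distance = model$w_distance * ev$e_pre,
                 ambiguous = model$w_ambiguous * ev$e_amb,
                 steric = model$w_steric * e_st,
                 bonded = 0)
  viol <- rbind(
    if (length(ev$pre_viol))
      data.frame(type = "pre", index = seq_along(ev$pre_viol),
                 violation = ev$pre_viol),
    if (length(ev$amb_viol))
      data.frame(type = "ambiguous", index = seq_along(ev$amb_viol),
                 violation = ev$amb_viol))
  if (is.null(viol))
    viol <- data.frame(type = character(), index = integer(),
                       violation = numeric())
  list(energy = sum(breakdown), breakdown = breakdown, violations = viol)
}

#' Refine a conformer against restraints by simulated annealing
#'
#' Metropolis Monte Carlo over the flexible-linker phi/psi torsions with a
#' three-stage cooling schedule, followed by a deterministic greedy
#' polish. Rigid-segment internal geometry and covalent bonds are
#' preserved exactly (moves are torsion rotations). Returns the
#' lowest-energy conformer visited, so the final energy never exceeds the
#' starting energy. Deterministic under a fixed seed.
#'
#' @param start A [Conformer-class].
#' @param restraints Restraints as in [restraintEnergy()].
#' @param model An [energyModel()].
#' @param schedule An [annealingSchedule()].
#' @param partition A [DomainPartition-class].
#' @param seed Optional integer; if given, `set.seed(seed)` is called.
#' @return List (a scored conformer): `conformer`, `energy`, `breakdown`,
#'   `violations`, `start_energy`, `n_accepted`.
#' @export
anneal <- function(start, restraints, model = energyModel(),
                   schedule = annealingSchedule(), partition, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ectx <- .annealContext(start, restraints, partition, model)
  sctx <- ectx$sctx; rctx <- ectx$rctx
  X <- coords(start)
  comp <- .fastComponents(X, ectx)
  e <- .fastTotal(comp, model)
  e_start <- e
  bestX <- X; bestComp <- comp; bestE <- e
  nmove <- length(sctx$moves)
  n_acc <- 0L
  fm_of <- function(mi, at) ectx$fast_moves[[2 * (mi - 1) +
                                               if (at == "phi") 1 else 2]]
  apply_prop <- function(prop) {
    comp <<- list(pre = comp$pre + prop$d_pre, amb = prop$amb_new,
                  st = comp$st + prop$d_st)
    X <<- prop$X
    e <<- .fastTotal(comp, model)
  }
  for (stg in 1:3) {
    Tst <- schedule$scales[stg]
    amp <- schedule$amplitudes[stg] * pi / 180
    for (s in seq_len(schedule$steps[stg])) {
      mi <- sample.int(nmove, 1)
      at <- if (stats::runif(1) < 0.5) "phi" else "psi"
      th <- stats::rnorm(1, 0, amp)
      prop <- .fastPropose(X, ectx, fm_of(mi, at), th)
      et <- .fastTotal(list(pre = comp$pre + prop$d_pre,
                            amb = prop$amb_new,
                            st = comp$st + prop$d_st), model)
      if (et <= e || stats::runif(1) < exp(-(et - e) / Tst)) {
        apply_prop(prop)
        n_acc <- n_acc + 1L
        if (e < bestE) { bestE <- e; bestX <- X; bestComp <- comp }
      }
    }
    # resynchronize cached components against drift between stages
    comp <- .fastComponents(X, ectx)
    e <- .fastTotal(comp, model)
  }
  # deterministic cyclic coordinate descent over torsions with a step
  # ladder (the final minimization stage)
  X <- bestX; comp <- .fastComponents(X, ectx); e <- .fastTotal(comp, model)
  if (schedule$polish_passes > 0) {
    budget <- schedule$polish_budget
    for (step in c(16, 8, 4, 2, 1, 0.5)) {
      th0 <- step * pi / 180
      for (p in seq_len(schedule$polish_passes)) {
        improved <- FALSE
        for (mi in seq_len(nmove)) {
          for (at in c("phi", "psi")) {
            fm <- fm_of(mi, at)
            for (s in c(th0, -th0)) {
              if (budget <= 0L) break
              budget <- budget - 1L
              prop <- .fastPropose(X, ectx, fm, s)
              et <- .fastTotal(list(pre = comp$pre + prop$d_pre,
                                    amb = prop$amb_new,
                                    st = comp$st + prop$d_st), model)
              if (et < e - 1e-9) {
                apply_prop(prop)
                improved <- TRUE
                break
              }
            }
            if (budget <= 0L) break
          }
          if (budget <= 0L) break
        }
        if (!improved || budget <= 0L) break
      }
      if (budget <= 0L) break
    }
  }
  out <- start
  coords(out) <- X
  ev <- .evalRestraints(X, rctx)
  e_st <- .ctxStericEnergy(X, sctx)
  breakdown <- c(distance = model$w_distance * ev$e_pre,
                 ambiguous = model$w_ambiguous * ev$e_amb,
                 steric = model$w_steric * e_st, bonded = 0)
  viol <- rbind(
    if (length(ev$pre_viol))
      data.frame(type = "pre", index = seq_along(ev$pre_viol),
                 violation = ev$pre_viol),
    if (length(ev$amb_viol))
      data.frame(type = "ambiguous", index = seq_along(ev$amb_viol),
                 violation = ev$amb_viol))
  list(conformer = out, energy = sum(breakdown), breakdown = breakdown,
       violations = viol, start_energy = e_start, n_accepted = n_acc)
}

# backbone-CA RMSD after superposition on a fit subset
.rmsdFitSubset <- function(a, b, fit_sel, measure_sel) {
  pair <- .pairAtoms(a, b, "*")
  aa <- atoms(a)
  keyed <- function(sel) {
    idx <- selectAtoms(a, sel)
    pair$mobile %in% idx & aa$atom_name[pair$mobile] == "CA"
  }
  fi <- keyed(fit_sel); mi <- keyed(measure_sel)
  X <- coords(a)[pair$mobile, , drop = FALSE]
  Y <- coords(b)[pair$reference, , drop = FALSE]
  k <- .kabsch(X[fi, , drop = FALSE], Y[fi, , drop = FALSE])
  Xt <- sweep(X %*% k$rotation, 2, k$translation, `+`)
  sqrt(mean(rowSums((Xt[mi, , drop = FALSE] - Y[mi, , drop = FALSE])^2)))
}

.rigidSelection <- function(partition) {
  s <- domainSegments(partition)
  s <- s[s$role == "rigid", , drop = FALSE]
  paste(sprintf("%s:%d-%d", s$chain_id, s$start, s$end), collapse = ",")
}

#' Select the low-energy ensemble from scored conformers
#'
#' Takes the `k` strictly lowest total energies (ties broken by input
#' order, a stable sort on provenance) and reports the mean and sample SD
#' of all pairwise backbone C-alpha RMSDs, superposing each pair on the
#' rigid segments when a partition is supplied (global CA fit otherwise).
#'
#' @param scored List of scored conformers ([anneal()] outputs, or lists
#'   with elements `conformer` and `energy`).
#' @param k Ensemble size (default 10).
#' @param partition Optional [DomainPartition-class] for the rigid-segment
#'   superposition.
#' @return List: `ensemble` (list of conformers), `energies`,
#'   `rmsd_mean`, `rmsd_sd` (NA when k < 2), `order` (indices into
#'   `scored`).
#' @export
selectEnsemble <- function(scored, k = 10, partition = NULL) {
  if (length(scored) < k)
    stop(sprintf("pool size %d < k = %d", length(scored), k))
  en <- vapply(scored, function(s) s$energy, 1.0)
  ord <- order(en)[seq_len(k)]
  ensemble <- lapply(scored[ord], function(s) s$conformer)
  if (k < 2) {
    return(list(ensemble = ensemble, energies = en[ord],
                rmsd_mean = NA_real_, rmsd_sd = NA_real_, order = ord))
  }
  fit_sel <- if (!is.null(partition)) .rigidSelection(partition) else "*"
  pr <- utils::combn(k, 2)
  rmsds <- vapply(seq_len(ncol(pr)), function(j)
    .rmsdFitSubset(ensemble[[pr[1, j]]], ensemble[[pr[2, j]]],
                   fit_sel, "*"), 1.0)
  list(ensemble = ensemble, energies = en[ord],
       rmsd_mean = mean(rmsds),
       rmsd_sd = if (length(rmsds) > 1) stats::sd(rmsds) else 0,
       order = ord)
}

#' Coordinate centroid of an ensemble
#'
#' Superposes every member onto the first (all-atom Kabsch) and averages
#' coordinates. The centroid is a summary object for RMSD comparisons,
#' not a stereochemically valid model.
#'
#' @param ensemble List of [Conformer-class] objects.
#' @return A [Conformer-class] with averaged coordinates.
#' @export
ensembleCentroid <- function(ensemble) {
  stopifnot(length(ensemble) >= 1)
  ref <- ensemble[[1]]
  acc <- coords(ref)
  if (length(ensemble) > 1) {
    for (i in 2:length(ensemble))
      acc <- acc + coords(superpose(ensemble[[i]], ref)$fitted)
  }
  out <- ref
  coords(out) <- acc / length(ensemble)
  out
}
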