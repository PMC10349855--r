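## Flexible-linker conformer sampling with rigid domains and a steric
## acceptance rule.

#' Sampling configuration
#'
#' @param n_attempts Number of randomization runs (default 2000).
#' @param vdw_tolerance Fractional steric-energy increase allowed relative
#'   to the starting energy of each run (default 0.10, i.e. a proposed
#'   rotation is accepted only if the molecule-wide clash energy does not
#'   rise by more than 10 percent).
#' @param seed Integer seed; the pool is a pure function of
#'   (template, partition, config).
#' @param minimize_steps Passes of the short greedy steric minimization
#'   run after each randomization (default 3).
#' @return A list of class `"SamplingConfig"`.
#' @export
samplingConfig <- function(n_attempts = 2000, vdw_tolerance = 0.10,
                           seed = 1, minimize_steps = 3) {
  stopifnot(n_attempts >= 1, vdw_tolerance >= 0)
  structure(list(n_attempts = as.integer(n_attempts),
                 vdw_tolerance = vdw_tolerance, seed = as.integer(seed),
                 minimize_steps = as.integer(minimize_steps)),
            class = "SamplingConfig")
}

# Bead subset used for fast molecule-wide steric energy: protein CA plus
# one central bead per RNA nucleotide.
.stericIndices <- function(a) {
  which(a$atom_name %in% c("CA", "C4"))
}

# Precomputed machinery for fast torsion moves and steric evaluation.
.samplingContext <- function(conformer, partition) {
  a <- atoms(conformer)
  flex <- flexibleResidues(partition)
  if (nrow(flex) == 0) stop("nothing to sample: no flexible residues")
  moves <- vector("list", nrow(flex))
  for (i in seq_len(nrow(flex))) {
    ch <- flex$chain_id[i]; rn <- flex$residue_number[i]
    iN <- .atomIndex(a, ch, rn, "N"); iCA <- .atomIndex(a, ch, rn, "CA")
    iC <- .atomIndex(a, ch, rn, "C")
    if (length(iN) != 1 || length(iCA) != 1 || length(iC) != 1)
      stop(sprintf("flexible residue %s:%d lacks N/CA/C", ch, rn))
    phi_move <- which(a$chain_id == ch &
                        (a$residue_number > rn |
                           (a$residue_number == rn &
                              !(a$atom_name %in% c("N", "CA")))))
    psi_move <- which(a$chain_id == ch &
                        (a$residue_number > rn |
                           (a$residue_number == rn & a$atom_name == "O")))
    moves[[i]] <- list(chain = ch, resno = rn, iN = iN, iCA = iCA, iC = iC,
                       phi_move = phi_move, psi_move = psi_move)
  }
  si <- .stericIndices(a)
  rad <- .vdwRadius(a$element[si])
  ns <- length(si)
  pr <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  keep <- !(a$chain_id[si][pr[, 1]] == a$chain_id[si][pr[, 2]] &
              abs(a$residue_number[si][pr[, 1]] -
                    a$residue_number[si][pr[, 2]]) <= 1)
  pi_ <- si[pr[keep, 1]]; pj <- si[pr[keep, 2]]
  rmin <- rad[pr[keep, 1]] + rad[pr[keep, 2]]
  linker_chains <- unique(flex$chain_id)
  list(atoms = a, moves = moves, steric_idx = si,
       pair_i = pi_, pair_j = pj, rmin2 = rmin^2, rmin = rmin,
       linker_chains = linker_chains)
}

.ctxStericEnergy <- function(X, ctx, k = 1) {
  dx <- X[ctx$pair_i, 1] - X[ctx$pair_j, 1]
  dy <- X[ctx$pair_i, 2] - X[ctx$pair_j, 2]
  dz <- X[ctx$pair_i, 3] - X[ctx$pair_j, 3]
  d2 <- dx * dx + dy * dy + dz * dz
  v <- d2 < ctx$rmin2
  if (!any(v)) return(0)
  sum(k * (ctx$rmin[v] - sqrt(d2[v]))^4)
}

.ctxRotate <- function(X, move, angle_type, theta) {
  if (angle_type == "phi") {
    origin <- X[move$iCA, ]; axis <- X[move$iCA, ] - X[move$iN, ]
    idx <- move$phi_move
  } else {
    origin <- X[move$iC, ]; axis <- X[move$iC, ] - X[move$iCA, ]
    idx <- move$psi_move
  }
  if (length(idx))
    X[idx, ] <- .rotateAbout(X[idx, , drop = FALSE], origin, axis, theta)
  X
}

.ctxSane <- function(X, ctx, max_bond = 3.0) {
  a <- ctx$atoms
  for (ch in ctx$linker_chains) {
    sel <- a$chain_id == ch & a$atom_name %in% c("N", "CA", "C")
    ai <- which(sel)
    ord <- ai[order(a$residue_number[ai],
                    match(a$atom_name[ai], c("N", "CA", "C")))]
    d <- sqrt(rowSums((X[ord[-1], , drop = FALSE] -
                         X[ord[-length(ord)], , drop = FALSE])^2))
    if (length(d) && max(d) > max_bond) return(FALSE)
  }
  TRUE
}

# greedy small-angle steric relaxation ("short minimization")
.stericMinimize <- function(X, ctx, passes = 3, step = 5) {
  e <- .ctxStericEnergy(X, ctx)
  if (e == 0 || passes == 0) return(X)
  th <- step * pi / 180
  for (p in seq_len(passes)) {
    for (m in ctx$moves) {
      for (at in c("phi", "psi")) {
        for (s in c(th, -th)) {
          Xt <- .ctxRotate(X, m, at, s)
          et <- .ctxStericEnergy(Xt, ctx)
          if (et < e) { X <- Xt; e <- et; break }
        }
      }
    }
    if (e == 0) break
  }
  X
}

#' One linker randomization run
#'
#' Walks the flexible residues N-to-C, proposing one random (phi, psi)
#' rotation per residue drawn uniformly from (-180, 180] degrees. A
#' proposal is accepted only if the molecule-wide steric energy does not
#' exceed `(1 + vdw_tolerance)` times the energy at the start of the run;
#' otherwise that residue's rotation is reverted. A short greedy steric
#' minimization follows. Uses the current RNG state ([generatePool()]
#' seeds it).
#'
#' @param template A [Conformer-class].
#' @param partition A [DomainPartition-class] with >= 1 flexible segment.
#' @param config A [samplingConfig()].
#' @param ctx Optional precomputed context (internal reuse).
#' @return List with `conformer` (NULL if rejected), `accepted` (logical),
#'   `n_rotations_accepted` and `vdw_energy`.
#' @export
randomizeLinker <- function(template, partition, config = samplingConfig(),
                            ctx = NULL) {
  if (is.null(ctx)) ctx <- .samplingContext(template, partition)
  X <- coords(template)
  e_start <- .ctxStericEnergy(X, ctx)
  budget <- (1 + config$vdw_tolerance) * e_start
  n_acc <- 0L
  for (m in ctx$moves) {
    ang <- stats::runif(2, -pi, pi)
    Xt <- .ctxRotate(X, m, "phi", ang[1])
    Xt <- .ctxRotate(Xt, m, "psi", ang[2])
    e <- .ctxStericEnergy(Xt, ctx)
    if (e <= budget || !is.finite(budget)) {
      X <- Xt; n_acc <- n_acc + 1L
    }
  }
  X <- .stericMinimize(X, ctx, passes = config$minimize_steps)
  e_final <- .ctxStericEnergy(X, ctx)
  if (!.ctxSane(X, ctx))
    return(list(conformer = NULL, accepted = FALSE,
                n_rotations_accepted = n_acc, vdw_energy = e_final))
  out <- template
  coords(out) <- X
  list(conformer = out, accepted = TRUE,
       n_rotations_accepted = n_acc, vdw_energy = e_final)
}

#' Generate a randomized conformer pool
#'
#' Runs `config$n_attempts` linker randomizations from the template and
#' collects the runs whose final geometry passes the backbone sanity
#' check. Deterministic under the config seed.
#'
#' @param template A [Conformer-class].
#' @param partition A [DomainPartition-class].
#' @param config A [samplingConfig()].
#' @return A [ConformerPool-class].
#' @export
generatePool <- function(template, partition, config = samplingConfig()) {
  ctx <- .samplingContext(template, partition)
  if (!.ctxSane(coords(template), ctx))
    stop("template fails geometry sanity check")
  set.seed(config$seed)
  conformers <- list()
  prov <- vector("list", config$n_attempts)
  for (i in seq_len(config$n_attempts)) {
    r <- randomizeLinker(template, partition, config, ctx = ctx)
    if (r$accepted) conformers[[length(conformers) + 1]] <- r$conformer
    prov[[i]] <- data.frame(attempt = i, accepted = r$accepted,
                            n_rotations_accepted = r$n_rotations_accepted,
                            vdw_energy = r$vdw_energy)
  }
  new("ConformerPool", conformers = conformers,
      provenance = do.call(rbind, prov),
      attempted = config$n_attempts, accepted = length(conformers))
}
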