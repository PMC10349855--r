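## Incremental energy evaluation for the annealing inner loops.
##
## A torsion move rotates a contiguous downstream atom set rigidly, so
## only energy terms with exactly one endpoint in the moved set change:
## steric pairs and PRE rows are re-evaluated on precomputed "cross"
## subsets per (residue, angle) move, the ambiguous term (whose protein
## atoms are always downstream of every linker move here) is recomputed
## in full, and per-term components are cached between accepted moves.
## restraintEnergy() remains the reference implementation; the fused
## evaluator must agree with it (asserted by tests).

.annealContext <- function(conformer, restraints, partition, model) {
  sctx <- .samplingContext(conformer, partition)
  rctx <- .restraintContext(conformer, restraints)
  n_atoms <- nrow(atoms(conformer))
  moves <- sctx$moves
  fast_moves <- vector("list", 2 * length(moves))
  for (k in seq_along(moves)) {
    m <- moves[[k]]
    for (ti in 1:2) {
      type <- c("phi", "psi")[ti]
      moved_idx <- if (type == "phi") m$phi_move else m$psi_move
      moved <- logical(n_atoms)
      moved[moved_idx] <- TRUE
      cross_st <- which(xor(moved[sctx$pair_i], moved[sctx$pair_j]))
      cross_pre <- integer()
      if (!is.null(rctx$pre)) {
        site_moved <- moved[rctx$pre$iCA]
        cross_pre <- which(xor(moved[rctx$pre$iN], site_moved))
      }
      fast_moves[[2 * (k - 1) + ti]] <- list(
        move = m, type = type, moved_idx = moved_idx,
        origin = if (type == "phi") m$iCA else m$iC,
        ax_from = if (type == "phi") m$iN else m$iCA,
        ax_to = if (type == "phi") m$iCA else m$iC,
        cross_st = cross_st, cross_pre = cross_pre)
    }
  }
  list(sctx = sctx, rctx = rctx, fast_moves = fast_moves, model = model)
}

.stericSubset <- function(X, sctx, ids, k = 1) {
  if (length(ids) == 0) return(0)
  i <- sctx$pair_i[ids]; j <- sctx$pair_j[ids]
  dx <- X[i, 1] - X[j, 1]; dy <- X[i, 2] - X[j, 2]; dz <- X[i, 3] - X[j, 3]
  d2 <- dx * dx + dy * dy + dz * dz
  rm2 <- sctx$rmin2[ids]
  v <- d2 < rm2
  if (!any(v)) return(0)
  sum(k * (sctx$rmin[ids][v] - sqrt(d2[v]))^4)
}

.preSubset <- function(X, p, rows) {
  if (length(rows) == 0) return(0)
  ica <- p$iCA[rows]
  lab <- X[ica, , drop = FALSE]
  icb <- p$iCB[rows]
  has <- !is.na(icb)
  if (any(has)) {
    u <- X[icb[has], , drop = FALSE] - lab[has, , drop = FALSE]
    u <- u / sqrt(rowSums(u^2))
    lab[has, ] <- lab[has, , drop = FALSE] + p$off[rows][has] * u
  }
  dN <- X[p$iN[rows], , drop = FALSE] - lab
  d <- sqrt(rowSums(dN^2))
  viol <- pmax(0, p$lo[rows] - d, d - p$up[rows])
  sum(p$w[rows] * viol^2)
}

.ambFull <- function(X, am) {
  if (is.null(am)) return(0)
  dx <- X[am$pair_i, 1] - X[am$pair_j, 1]
  dy <- X[am$pair_i, 2] - X[am$pair_j, 2]
  dz <- X[am$pair_i, 3] - X[am$pair_j, 3]
  r6 <- (dx * dx + dy * dy + dz * dz)^(-3)
  deff <- as.vector(rowsum(r6, am$grp))^(-1 / 6)
  viol <- pmax(0, am$lo - deff, deff - am$up)
  sum(am$w * viol^2)
}

# full component evaluation (initialization / resynchronization)
.fastComponents <- function(X, ectx) {
  p <- ectx$rctx$pre
  list(
    pre = if (is.null(p)) 0 else .preSubset(X, p, seq_along(p$iN)),
    amb = .ambFull(X, ectx$rctx$amb),
    st = if (ectx$model$w_steric > 0)
      .stericSubset(X, ectx$sctx, seq_along(ectx$sctx$pair_i)) else 0)
}

.fastTotal <- function(comp, model) {
  model$w_distance * comp$pre + model$w_ambiguous * comp$amb +
    model$w_steric * comp$st
}

# propose rotating fast-move fm by theta; return new coords restricted to
# the moved rows plus the component deltas
.fastPropose <- function(X, ectx, fm, theta) {
  idx <- fm$moved_idx
  origin <- X[fm$origin, ]
  axis <- X[fm$ax_to, ] - X[fm$ax_from, ]
  Xm <- .rotateAbout(X[idx, , drop = FALSE], origin, axis, theta)
  X2 <- X
  X2[idx, ] <- Xm
  model <- ectx$model
  d_pre <- if (length(fm$cross_pre))
    .preSubset(X2, ectx$rctx$pre, fm$cross_pre) -
      .preSubset(X, ectx$rctx$pre, fm$cross_pre) else 0
  d_st <- if (model$w_steric > 0 && length(fm$cross_st))
    .stericSubset(X2, ectx$sctx, fm$cross_st) -
      .stericSubset(X, ectx$sctx, fm$cross_st) else 0
  amb_new <- .ambFull(X2, ectx$rctx$amb)
  list(X = X2, d_pre = d_pre, d_st = d_st, amb_new = amb_new)
}
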