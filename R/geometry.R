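## Geometry: superposition, RMSD, steric energy, torsion manipulation.

.pairAtoms <- function(mobile, reference, selection = "*") {
  im <- selectAtoms(mobile, selection)
  ir <- selectAtoms(reference, selection)
  am <- atoms(mobile)[im, , drop = FALSE]
  ar <- atoms(reference)[ir, , drop = FALSE]
  km <- paste(am$chain_id, am$residue_number, am$atom_name)
  kr <- paste(ar$chain_id, ar$residue_number, ar$atom_name)
  common <- intersect(km, kr)
  list(mobile = im[match(common, km)], reference = ir[match(common, kr)])
}

.kabsch <- function(X, Y) {
  # rotation R (row-vector convention x' = x %*% R) and translation t
  # minimizing ||X R + t - Y||
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  C <- crossprod(Xc, Yc)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cy - as.vector(cx %*% R)
  rmsd <- sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Least-squares superposition of one conformer onto another
#'
#' Kabsch superposition over atoms paired by
#' `(chain_id, residue_number, atom_name)` within a selection. The returned
#' rotation is proper (determinant +1).
#'
#' @param mobile,reference [Conformer-class] objects.
#' @param selection Atom selection (see [selectAtoms()]); default all atoms.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, at the optimum) and `fitted` (the transformed mobile
#'   conformer). The transform maps mobile coordinates as
#'   `x' = x \%*\% rotation + translation`.
#' @examples
#' ## a rigidly displaced copy superposes back with rmsd ~ 0
#' @export
superpose <- function(mobile, reference, selection = "*") {
  pair <- .pairAtoms(mobile, reference, selection)
  if (length(pair$mobile) < 3)
    stop("insufficient pairs: need >= 3 paired atoms for superposition")
  X <- coords(mobile)[pair$mobile, , drop = FALSE]
  Y <- coords(reference)[pair$reference, , drop = FALSE]
  k <- .kabsch(X, Y)
  fitted <- mobile
  coords(fitted) <- sweep(coords(mobile) %*% k$rotation, 2,
                          k$translation, `+`)
  list(rotation = k$rotation, translation = k$translation,
       rmsd = k$rmsd, fitted = fitted)
}

#' Backbone RMSD between two conformers
#'
#' RMSD over paired backbone atoms (C-alpha by default), optionally after
#' least-squares superposition. Symmetric in its arguments.
#'
#' @param a,b [Conformer-class] objects.
#' @param selection Atom selection applied to both (default all).
#' @param atom_names Backbone atom names to pair; default `"CA"`.
#' @param fit Superpose before measuring (default TRUE). With `fit = FALSE`
#'   coordinates are compared in the frame they are in.
#' @return RMSD in Angstrom.
#' @export
backboneRmsd <- function(a, b, selection = "*", atom_names = "CA",
                         fit = TRUE) {
  pair <- .pairAtoms(a, b, selection)
  an <- atoms(a)$atom_name[pair$mobile]
  keep <- an %in% atom_names
  ia <- pair$mobile[keep]; ib <- pair$reference[keep]
  if (length(ia) < 3 && fit)
    stop("insufficient pairs: need >= 3 paired backbone atoms")
  if (length(ia) == 0) stop("no paired backbone atoms")
  X <- coords(a)[ia, , drop = FALSE]
  Y <- coords(b)[ib, , drop = FALSE]
  if (fit) .kabsch(X, Y)$rmsd else sqrt(mean(rowSums((X - Y)^2)))
}

.VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, H = 1.2,
                ZN = 1.39)
.vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Purely repulsive steric (van der Waals clash) energy
#'
#' Quartic repulsion summed over non-bonded atom pairs:
#' \deqn{E = \sum_{r_{ij} < r_{min,ij}} k (r_{min,ij} - r_{ij})^4}
#' with \eqn{r_{min,ij}} the sum of element van der Waals radii times
#' `scale`. Pairs within the same residue or in sequence-adjacent residues
#' of the same chain are excluded (bonded-neighbour rule). The term is
#' zero when no pair is closer than its contact distance; there is no
#' attractive component.
#'
#' @param conformer A [Conformer-class].
#' @param selection Atoms to include (default all). Coarse selections
#'   (e.g. `"CA"` beads) give a faster clash score for sampling.
#' @param k Force constant, arbitrary units per Angstrom^4 (default 1).
#' @param scale Multiplier on the radius sum defining the contact distance
#'   (default 1).
#' @return Non-negative energy in arbitrary units (0 for empty input).
#' @export
vdwEnergy <- function(conformer, selection = "*", k = 1, scale = 1) {
  idx <- selectAtoms(conformer, selection)
  if (length(idx) < 2) return(0)
  a <- atoms(conformer)[idx, , drop = FALSE]
  X <- cbind(a$x, a$y, a$z)
  rad <- .vdwRadius(a$element)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  Rmin <- outer(rad, rad, `+`) * scale
  # bonded-neighbour exclusion: same or adjacent residue in same chain
  same_chain <- outer(a$chain_id, a$chain_id, `==`)
  dres <- abs(outer(a$residue_number, a$residue_number, `-`))
  excl <- same_chain & dres <= 1
  viol <- D < Rmin & !excl
  viol[lower.tri(viol, diag = TRUE)] <- FALSE
  if (!any(viol)) return(0)
  sum(k * (Rmin[viol] - D[viol])^4)
}

.rotationMatrix <- function(axis, theta) {
  # right-handed rotation about unit axis (Rodrigues), row-vector convention
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  R <- matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
    nrow = 3, byrow = TRUE)
  t(R)  # for x' = x %*% R
}

.rotateAbout <- function(X, origin, axis, theta) {
  R <- .rotationMatrix(axis, theta)
  sweep(sweep(X, 2, origin) %*% R, 2, origin, `+`)
}

.atomIndex <- function(a, chain, resno, name) {
  which(a$chain_id == chain & a$residue_number == resno &
          a$atom_name == name)
}

#' Rotate linker backbone torsions
#'
#' Applies incremental phi/psi rotations (degrees, right-handed, delta from
#' the input geometry) to residues of the flexible segments. A phi rotation
#' turns about the N-CA bond and moves all atoms C-terminal of CA in the
#' same chain (plus CB of that residue); a psi rotation turns about the
#' CA-C bond and moves all later residues. Atoms in other chains are
#' unaffected; rigid-segment internal geometry is preserved exactly.
#'
#' @param conformer A [Conformer-class] with backbone atoms N, CA, C.
#' @param partition A [DomainPartition-class]; torsions may only address
#'   residues inside flexible segments.
#' @param torsions data.frame with columns `chain_id`, `residue_number`,
#'   `dphi`, `dpsi` (degrees; 0 = leave unchanged).
#' @return The rotated [Conformer-class].
#' @export
setLinkerTorsions <- function(conformer, partition, torsions) {
  a <- atoms(conformer)
  X <- coords(conformer)
  flex <- flexibleResidues(partition)
  fkey <- paste(flex$chain_id, flex$residue_number)
  torsions <- torsions[order(torsions$chain_id, torsions$residue_number), ,
                       drop = FALSE]
  for (i in seq_len(nrow(torsions))) {
    ch <- torsions$chain_id[i]; rn <- torsions$residue_number[i]
    if (!(paste(ch, rn) %in% fkey))
      stop(sprintf("domain violation: residue %s:%d is not flexible", ch, rn))
    dphi <- torsions$dphi[i] * pi / 180
    dpsi <- torsions$dpsi[i] * pi / 180
    iN <- .atomIndex(a, ch, rn, "N"); iCA <- .atomIndex(a, ch, rn, "CA")
    iC <- .atomIndex(a, ch, rn, "C")
    if (length(iN) != 1 || length(iCA) != 1 || length(iC) != 1)
      stop(sprintf("residue %s:%d lacks backbone atoms N/CA/C", ch, rn))
    if (dphi != 0) {
      axis <- X[iCA, ] - X[iN, ]
      move <- a$chain_id == ch &
        (a$residue_number > rn |
           (a$residue_number == rn & !(a$atom_name %in% c("N", "CA"))))
      X[move, ] <- .rotateAbout(X[move, , drop = FALSE], X[iCA, ], axis, dphi)
    }
    if (dpsi != 0) {
      axis <- X[iC, ] - X[iCA, ]
      move <- a$chain_id == ch &
        (a$residue_number > rn |
           (a$residue_number == rn & a$atom_name == "O"))
      if (any(move))
        X[move, ] <- .rotateAbout(X[move, , drop = FALSE], X[iC, ], axis, dpsi)
    }
  }
  coords(conformer) <- X
  conformer
}

#' Radius of gyration from coordinates
#' @param conformer A [Conformer-class].
#' @param selection Atom selection (default all), equal weights.
#' @return Rg in Angstrom.
#' @export
coordinateRg <- function(conformer, selection = "*") {
  X <- coords(conformer)[selectAtoms(conformer, selection), , drop = FALSE]
  ctr <- colMeans(X)
  sqrt(mean(rowSums(sweep(X, 2, ctr)^2)))
}

# max bonded backbone gap in flexible+all chain: used as geometry sanity
.backboneBondLengths <- function(conformer, chain_id) {
  a <- atoms(conformer)
  X <- coords(conformer)
  sel <- a$chain_id == chain_id & a$atom_name %in% c("N", "CA", "C")
  ai <- which(sel)
  ord <- ai[order(a$residue_number[ai],
                  match(a$atom_name[ai], c("N", "CA", "C")))]
  if (length(ord) < 2) return(numeric())
  sqrt(rowSums((X[ord[-1], , drop = FALSE] -
                  X[ord[-length(ord)], , drop = FALSE])^2))
}

#' Check backbone connectivity of a conformer
#'
#' Sanity check used by the sampler: every consecutive backbone bond
#' (N-CA, CA-C, C-N) in each protein chain must be shorter than `max_bond`.
#'
#' @param conformer A [Conformer-class].
#' @param chains Chains to check; default all chains containing CA atoms.
#' @param max_bond Maximum tolerated bonded distance in Angstrom
#'   (default 3.0).
#' @return Logical.
#' @export
geometrySane <- function(conformer, chains = NULL, max_bond = 3.0) {
  a <- atoms(conformer)
  if (is.null(chains))
    chains <- unique(a$chain_id[a$atom_name == "CA"])
  for (ch in chains) {
    b <- .backboneBondLengths(conformer, ch)
    if (length(b) && max(b) > max_bond) return(FALSE)
  }
  TRUE
}
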