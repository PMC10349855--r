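#' @import methods
NULL

REQUIRED_ATOM_COLS <- c("atom_name", "residue_name", "chain_id",
                        "residue_number", "element", "x", "y", "z")

#' Conformer: an atomic or pseudo-atomic coordinate model
#'
#' A `Conformer` holds an ordered atom table (one row per atom) with chain,
#' residue and atom labels and Cartesian coordinates in Angstrom. It is the
#' object sampled, scored and refined throughout the modeling pipeline.
#'
#' @slot atoms A `data.frame` with columns `atom_name`, `residue_name`,
#'   `chain_id`, `residue_number` (integer), `element` and coordinates
#'   `x`, `y`, `z` (Angstrom).
#'
#' @details Atom identity within a conformer is the triple
#'   `(chain_id, residue_number, atom_name)`, which must be unique.
#'   Residue numbering must be non-decreasing within a chain (PDB-style,
#'   1-based numbering is conventional but not enforced).
#'
#' @seealso [readStructure()], [writeStructure()], [superpose()],
#'   [vdwEnergy()], [setLinkerTorsions()]
#' @export
setClass("Conformer", representation(atoms = "data.frame"))

setValidity("Conformer", function(object) {
  a <- object@atoms
  msg <- character()
  if (!all(REQUIRED_ATOM_COLS %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(REQUIRED_ATOM_COLS, collapse = ", ")))
  if (nrow(a) > 0 && all(c("x", "y", "z") %in% names(a))) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      msg <- c(msg, "coordinates must be finite")
    key <- paste(a$chain_id, a$residue_number, a$atom_name)
    if (anyDuplicated(key))
      msg <- c(msg, "(chain_id, residue_number, atom_name) must be unique")
    for (ch in unique(a$chain_id)) {
      rn <- a$residue_number[a$chain_id == ch]
      if (is.unsorted(rn))
        msg <- c(msg, sprintf("residue numbering not monotone in chain %s", ch))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Conformer from an atom table
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `chain_id`, `residue_number`, `element`, `x`, `y`, `z`.
#' @return A [Conformer-class] object.
#' @examples
#' Conformer(data.frame(atom_name = "CA", residue_name = "GLY",
#'   chain_id = "A", residue_number = 1L, element = "C",
#'   x = 0, y = 0, z = 0))
#' @export
Conformer <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$residue_number <- as.integer(atoms$residue_number)
  rownames(atoms) <- NULL
  new("Conformer", atoms = atoms)
}

#' @describeIn Conformer-class number of atoms
#' @param x,object A `Conformer`.
#' @export
setMethod("length", "Conformer", function(x) nrow(x@atoms))

setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Atom table of a Conformer
#' @param x A [Conformer-class].
#' @return The atom `data.frame`.
#' @export
setMethod("atoms", "Conformer", function(x) x@atoms)

setGeneric("coords", function(x) standardGeneric("coords"))
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Coordinate matrix of a Conformer
#' @param x A [Conformer-class].
#' @return An n-by-3 numeric matrix (Angstrom).
#' @export
setMethod("coords", "Conformer", function(x)
  cbind(x = x@atoms$x, y = x@atoms$y, z = x@atoms$z))

#' @rdname coords-Conformer-method
#' @param value n-by-3 matrix of replacement coordinates.
#' @export
setMethod("coords<-", "Conformer", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms), ncol(value) == 3)
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  x
})

setMethod("show", "Conformer", function(object) {
  a <- object@atoms
  cat(sprintf("Conformer: %d atoms, %d chains (%s), %d residues\n",
              nrow(a), length(unique(a$chain_id)),
              paste(unique(a$chain_id), collapse = ","),
              length(unique(paste(a$chain_id, a$residue_number)))))
})

#' DomainPartition: rigid/flexible segmentation of a chain system
#'
#' Describes which residue ranges move as rigid bodies and which are
#' flexible linkers whose backbone torsions are sampled.
#'
#' @slot segments `data.frame` with columns `name`, `chain_id`,
#'   `start`, `end` (residue numbers, inclusive) and
#'   `role` (`"rigid"` or `"flexible"`).
#' @export
setClass("DomainPartition", representation(segments = "data.frame"))

setValidity("DomainPartition", function(object) {
  s <- object@segments
  msg <- character()
  need <- c("name", "chain_id", "start", "end", "role")
  if (!all(need %in% names(s)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (!all(s$role %in% c("rigid", "flexible")))
    msg <- c(msg, "role must be 'rigid' or 'flexible'")
  if (any(s$end < s$start)) msg <- c(msg, "segment end < start")
  for (ch in unique(s$chain_id)) {
    ss <- s[s$chain_id == ch, , drop = FALSE]
    ss <- ss[order(ss$start), , drop = FALSE]
    if (nrow(ss) > 1 && any(ss$start[-1] <= ss$end[-nrow(ss)]))
      msg <- c(msg, sprintf("overlapping segments in chain %s", ch))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DomainPartition
#'
#' @param segments data.frame with columns `name`, `chain_id`, `start`,
#'   `end`, `role` ("rigid"/"flexible").
#' @return A [DomainPartition-class].
#' @examples
#' domainPartition(data.frame(
#'   name = c("D1", "L1", "D2"), chain_id = "A",
#'   start = c(1, 21, 41), end = c(20, 40, 60),
#'   role = c("rigid", "flexible", "rigid")))
#' @export
domainPartition <- function(segments) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  new("DomainPartition", segments = segments)
}

setGeneric("domainSegments", function(x) standardGeneric("domainSegments"))

#' Segment table of a DomainPartition
#' @param x A [DomainPartition-class].
#' @return The segment `data.frame`.
#' @export
setMethod("domainSegments", "DomainPartition", function(x) x@segments)

setMethod("show", "DomainPartition", function(object) {
  s <- object@segments
  cat(sprintf("DomainPartition: %d segments (%d rigid, %d flexible)\n",
              nrow(s), sum(s$role == "rigid"), sum(s$role == "flexible")))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %s:%d-%d  %s\n", s$name[i], s$chain_id[i],
                s$start[i], s$end[i], s$role[i]))
})

#' Residues of the flexible segments
#' @param partition A [DomainPartition-class].
#' @param chain_id Optional chain filter.
#' @return data.frame with columns `chain_id`, `residue_number`, `segment`.
#' @export
flexibleResidues <- function(partition, chain_id = NULL) {
  s <- domainSegments(partition)
  s <- s[s$role == "flexible", , drop = FALSE]
  if (!is.null(chain_id)) s <- s[s$chain_id %in% chain_id, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(s)), function(i)
    data.frame(chain_id = s$chain_id[i],
               residue_number = seq(s$start[i], s$end[i]),
               segment = s$name[i], stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- data.frame(chain_id = character(), residue_number = integer(),
                      segment = character())
  out
}

#' ScatteringCurve: a 1D small-angle scattering curve
#'
#' @slot q Scattering vector modulus, 1/Angstrom, strictly increasing.
#' @slot I Intensity (arbitrary units).
#' @slot sigma Intensity error, same units as `I`.
#' @export
setClass("ScatteringCurve",
         representation(q = "numeric", I = "numeric", sigma = "numeric"))

setValidity("ScatteringCurve", function(object) {
  msg <- character()
  n <- length(object@q)
  if (length(object@I) != n || length(object@sigma) != n)
    msg <- c(msg, "q, I, sigma must have equal length")
  if (n > 1 && any(diff(object@q) <= 0))
    msg <- c(msg, "q must be strictly increasing")
  if (any(object@q < 0)) msg <- c(msg, "q must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ScatteringCurve
#' @param q,I,sigma Numeric vectors of equal length: scattering vector
#'   (1/Angstrom), intensity, and intensity error. `sigma` defaults to NA
#'   (unknown errors).
#' @return A [ScatteringCurve-class].
#' @export
scatteringCurve <- function(q, I, sigma = rep(NA_real_, length(q))) {
  new("ScatteringCurve", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma))
}

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve: %d points, q in [%.4g, %.4g] A^-1\n",
              length(object@q), min(object@q), max(object@q)))
})

#' @describeIn ScatteringCurve-class number of q points
#' @param x,object A `ScatteringCurve`.
#' @export
setMethod("length", "ScatteringCurve", function(x) length(x@q))

#' Convert a ScatteringCurve to a data.frame
#' @param x A [ScatteringCurve-class].
#' @param ... Ignored.
#' @return data.frame with columns q, I, sigma.
#' @export
setMethod("as.data.frame", "ScatteringCurve", function(x, ...)
  data.frame(q = x@q, I = x@I, sigma = x@sigma))

#' PairDistribution: real-space pair-distance distribution p(r)
#'
#' @slot r Distance grid, Angstrom.
#' @slot p p(r) values (arbitrary units), non-negative.
#' @slot dmax Maximum particle dimension, Angstrom.
#' @slot rg Radius of gyration derived from p(r), Angstrom.
#' @export
setClass("PairDistribution",
         representation(r = "numeric", p = "numeric",
                        dmax = "numeric", rg = "numeric"))

setValidity("PairDistribution", function(object) {
  msg <- character()
  if (length(object@r) != length(object@p))
    msg <- c(msg, "r and p must have equal length")
  if (any(object@p < -1e-9)) msg <- c(msg, "p(r) must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairDistribution", function(object) {
  cat(sprintf("PairDistribution: %d bins, Dmax = %.2f A, Rg = %.2f A\n",
              length(object@r), object@dmax, object@rg))
})

#' Dmax accessor
#' @param x A [PairDistribution-class].
#' @return Maximum dimension in Angstrom.
#' @export
dmax <- function(x) {
  stopifnot(is(x, "PairDistribution"))
  x@dmax
}

#' Rg accessor for a PairDistribution
#' @param x A [PairDistribution-class].
#' @return Radius of gyration in Angstrom.
#' @export
pofrRg <- function(x) {
  stopifnot(is(x, "PairDistribution"))
  x@rg
}

#' Isotherm: an ITC titration protocol with integrated injection heats
#'
#' @slot cellVolume Calorimeter cell volume, litres.
#' @slot cellConc Cell (macromolecule) concentration at start, mol/L.
#' @slot syringeConc Syringe (titrant) concentration, mol/L.
#' @slot injVolumes Injection volumes, litres (one per injection).
#' @slot heats Integrated heat per injection, kcal.
#' @slot temperature Kelvin.
#' @export
setClass("Isotherm",
         representation(cellVolume = "numeric", cellConc = "numeric",
                        syringeConc = "numeric", injVolumes = "numeric",
                        heats = "numeric", temperature = "numeric"))

setValidity("Isotherm", function(object) {
  msg <- character()
  if (object@cellVolume <= 0) msg <- c(msg, "cellVolume must be > 0")
  if (object@cellConc <= 0) msg <- c(msg, "cellConc must be > 0")
  if (object@syringeConc <= 0) msg <- c(msg, "syringeConc must be > 0")
  if (any(object@injVolumes <= 0)) msg <- c(msg, "injection volumes must be > 0")
  if (length(object@heats) &&
      length(object@heats) != length(object@injVolumes))
    msg <- c(msg, "heats must match injVolumes in length")
  if (length(object@heats) && any(!is.finite(object@heats)))
    msg <- c(msg, "heats must be finite")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0 K")
  if (length(msg)) msg else TRUE
})

#' Construct an Isotherm
#'
#' @param cellVolume Cell volume in litres (e.g. 200e-6 for a 200 uL cell).
#' @param cellConc Macromolecule concentration in the cell, mol/L.
#' @param syringeConc Titrant concentration in the syringe, mol/L.
#' @param injVolumes Vector of injection volumes, litres.
#' @param heats Integrated heats per injection, kcal. May be empty for a
#'   bare protocol to be filled by [simulateIsotherm()].
#' @param temperature Kelvin; default 298.15 (25 C).
#' @return An [Isotherm-class].
#' @export
isotherm <- function(cellVolume, cellConc, syringeConc, injVolumes,
                     heats = numeric(), temperature = 298.15) {
  new("Isotherm", cellVolume = cellVolume, cellConc = cellConc,
      syringeConc = syringeConc, injVolumes = as.numeric(injVolumes),
      heats = as.numeric(heats), temperature = temperature)
}

setMethod("show", "Isotherm", function(object) {
  cat(sprintf(
    "Isotherm: %d injections, cell %.3g M / syringe %.3g M, T = %.2f K\n",
    length(object@injVolumes), object@cellConc, object@syringeConc,
    object@temperature))
})

#' Injection heats accessor
#' @param x An [Isotherm-class].
#' @return Numeric vector of per-injection heats (kcal).
#' @export
heats <- function(x) {
  stopifnot(is(x, "Isotherm"))
  x@heats
}

#' Molar ratio (titrant/macromolecule in cell) after each injection
#' @param x An [Isotherm-class].
#' @return Numeric vector, one value per injection.
#' @export
molarRatio <- function(x) {
  stopifnot(is(x, "Isotherm"))
  conc <- .itcConcentrations(x)
  conc$Lt / conc$Mt
}

#' ConformerPool: accepted conformers from linker randomization
#'
#' @slot conformers List of [Conformer-class] objects (accepted members).
#' @slot provenance `data.frame` with one row per attempt: `attempt`,
#'   `accepted` (logical), `n_rotations_accepted`, `vdw_energy`.
#' @slot attempted Number of randomization runs started.
#' @slot accepted Number of accepted members.
#' @export
setClass("ConformerPool",
         representation(conformers = "list", provenance = "data.frame",
                        attempted = "numeric", accepted = "numeric"))

setValidity("ConformerPool", function(object) {
  if (object@accepted > object@attempted)
    return("accepted cannot exceed attempted")
  if (length(object@conformers) != object@accepted)
    return("conformers list must have 'accepted' members")
  TRUE
})

setMethod("show", "ConformerPool", function(object) {
  cat(sprintf("ConformerPool: %d accepted / %d attempted\n",
              object@accepted, object@attempted))
})

#' @describeIn ConformerPool-class number of accepted members
#' @param x,object A `ConformerPool`.
#' @export
setMethod("length", "ConformerPool", function(x) length(x@conformers))

#' Pool member accessor
#' @param x A [ConformerPool-class].
#' @param i Member index.
#' @return The i-th accepted [Conformer-class].
#' @export
poolMember <- function(x, i) {
  stopifnot(is(x, "ConformerPool"))
  x@conformers[[i]]
}

#' Pool provenance table
#' @param x A [ConformerPool-class].
#' @return data.frame of per-attempt provenance.
#' @export
poolProvenance <- function(x) {
  stopifnot(is(x, "ConformerPool"))
  x@provenance
}
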