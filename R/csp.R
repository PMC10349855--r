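## Chemical shift perturbation mapping and ambiguous restraint generation.

#' Read a peak table from delimited text
#'
#' Expected columns (header required): `residue_number`, `residue_name`,
#' `dH_ppm`, `dN_ppm`, `intensity`; an optional logical `excluded` column
#' flags unassigned/overlapped peaks.
#'
#' @param path Path to a whitespace- or comma-delimited text file.
#' @return data.frame (a peak table).
#' @export
readPeakTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  need <- c("residue_number", "dH_ppm", "dN_ppm")
  if (!all(need %in% names(tab)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$residue_number))
    stop("residue_number must be unique in a peak table")
  tab
}

#' Combined amide chemical shift perturbation
#'
#' Per residue shared between the free and bound peak tables,
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' with the nitrogen shift scaled by `alpha` (default 0.2) to account for
#' the wider 15N shift dispersion. Residues present in only one table (e.g.
#' broadened beyond detection in the bound state) are omitted from the
#' profile and reported in the `"omitted"` attribute.
#'
#' @param free,bound Peak tables (data.frames with `residue_number`,
#'   `dH_ppm`, `dN_ppm`; see [readPeakTable()]). Rows with a TRUE
#'   `excluded` column are dropped first.
#' @param alpha Nitrogen scaling factor (dimensionless, default 0.2).
#' @return data.frame with columns `residue_number`, `delta_delta` (ppm),
#'   sorted by residue; attribute `"alpha"` records the scaling used and
#'   `"omitted"` the residues present in only one input.
#' @examples
#' free  <- data.frame(residue_number = 1, dH_ppm = 8.00, dN_ppm = 120.0)
#' bound <- data.frame(residue_number = 1, dH_ppm = 8.03, dN_ppm = 120.2)
#' computeCsp(free, bound)$delta_delta  # 0.05 ppm
#' @export
computeCsp <- function(free, bound, alpha = 0.2) {
  drop_excluded <- function(t) {
    if ("excluded" %in% names(t)) t[!as.logical(t$excluded), , drop = FALSE]
    else t
  }
  free <- drop_excluded(free); bound <- drop_excluded(bound)
  shared <- intersect(free$residue_number, bound$residue_number)
  if (length(shared) == 0)
    stop("empty overlap: free and bound tables share no residues")
  fi <- match(shared, free$residue_number)
  bi <- match(shared, bound$residue_number)
  dH <- bound$dH_ppm[bi] - free$dH_ppm[fi]
  dN <- bound$dN_ppm[bi] - free$dN_ppm[fi]
  out <- data.frame(residue_number = shared,
                    delta_delta = sqrt(dH^2 + (alpha * dN)^2))
  out <- out[order(out$residue_number), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "omitted") <- sort(c(setdiff(free$residue_number, shared),
                                 setdiff(bound$residue_number, shared)))
  out
}

#' Select residues above a CSP threshold
#'
#' Returns residues whose combined perturbation is strictly greater than
#' the threshold (boundary values excluded), sorted ascending. These are
#' the binding-site residues used to build ambiguous protein-RNA
#' restraints.
#'
#' @param profile CSP profile from [computeCsp()].
#' @param threshold ppm; default 0.08.
#' @return Sorted integer vector of residue numbers (possibly empty).
#' @export
selectAboveThreshold <- function(profile, threshold = 0.08) {
  stopifnot(nrow(profile) > 0)
  sort(profile$residue_number[profile$delta_delta > threshold])
}

#' Build ambiguous protein-RNA distance restraints from CSP hits
#'
#' One ambiguous restraint per selected protein residue: a flat-bottom
#' target of `target` +/- `halfwidth` Angstrom between the heavy atoms of
#' that residue and the heavy atoms of any of the listed RNA nucleotides
#' (hydrogens excluded; ambiguity is resolved at evaluation time with an
#' r^-6-summed effective distance).
#'
#' @param residues Integer vector of protein residue numbers (non-empty).
#' @param rna_positions Integer vector of RNA nucleotide positions
#'   (non-empty), e.g. `6:12`.
#' @param target Target distance, Angstrom (default 4).
#' @param halfwidth Half-width of the flat bottom, Angstrom (default 1).
#' @param weight Restraint weight (default 1).
#' @param protein_chain,rna_chain Chain identifiers (defaults "A" and "R").
#' @return data.frame with one row per restraint: `residue_number`,
#'   `protein_chain`, `rna_chain`, `rna_positions` (comma-joined),
#'   `target`, `lower`, `upper`, `halfwidth`, `weight`,
#'   `type = "ambiguous"`.
#' @export
buildAmbiguousRestraints <- function(residues, rna_positions, target = 4,
                                     halfwidth = 1, weight = 1,
                                     protein_chain = "A", rna_chain = "R") {
  if (length(residues) == 0) stop("empty input: no residues selected")
  if (length(rna_positions) == 0) stop("empty input: no RNA positions")
  stopifnot(halfwidth > 0)
  data.frame(
    residue_number = as.integer(residues),
    protein_chain = protein_chain, rna_chain = rna_chain,
    rna_positions = paste(as.integer(rna_positions), collapse = ","),
    target = target, lower = target - halfwidth, upper = target + halfwidth,
    halfwidth = halfwidth, weight = weight, type = "ambiguous",
    stringsAsFactors = FALSE)
}
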