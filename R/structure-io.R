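#' Read a PDB file into a Conformer
#'
#' Parses ATOM/HETATM records of a fixed-column PDB file. Parsing is done
#' with \pkg{bio3d}; alternate locations are reduced to the first occurrence
#' and insertion codes are rejected. Only the first MODEL of a multi-model
#' file is read.
#'
#' @param path Path to a PDB file.
#' @return A [Conformer-class] with coordinates in Angstrom.
#' @seealso [writeStructure()]
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_lines) == 0)
    stop("empty model: no ATOM/HETATM records in ", path)
  # cheap format validation with line numbers (bio3d reports no line info)
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        is.na(suppressWarnings(as.numeric(substr(ln, 31, 38)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 39, 46)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 47, 54)))))
      stop(sprintf("unparsable PDB coordinate record at line %d", i))
    if (substr(ln, 27, 27) != " ")
      stop(sprintf("insertion code at line %d not supported", i))
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  # altloc: keep first occurrence per (chain, resno, atom)
  keep <- !duplicated(paste(a$chain, a$resno, a$elety))
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <- substr(trimws(a$elety), 1, 1)[
    is.na(elem) | elem == ""]
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  Conformer(data.frame(
    atom_name = trimws(a$elety), residue_name = trimws(a$resid),
    chain_id = chain, residue_number = as.integer(a$resno),
    element = trimws(elem), x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE))
}

.pdbAtomLine <- function(serial, atom_name, residue_name, chain_id,
                         residue_number, x, y, z, element) {
  # PDB v3.3 alignment: 1-3 char names start in column 14
  name_fmt <- if (nchar(atom_name) < 4) sprintf(" %-3s", atom_name)
              else sprintf("%-4s", atom_name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, residue_name, chain_id, residue_number,
          x, y, z, 1.0, 0.0, element)
}

#' Write a Conformer (or list of Conformers) as a PDB file
#'
#' Writes fixed-column ATOM records with TER between chains and END at the
#' end. A list of conformers is written as a multi-model file
#' (MODEL/ENDMDL), e.g. for conformer pools and ensembles.
#'
#' @param conformer A [Conformer-class] or a list of them.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeStructure <- function(conformer, path) {
  models <- if (is(conformer, "Conformer")) list(conformer) else conformer
  stopifnot(length(models) >= 1, all(vapply(models, is, TRUE, "Conformer")))
  if (any(vapply(models, length, 1L) == 0))
    stop("cannot write an empty conformer")
  if (any(vapply(models, length, 1L) > 99999))
    stop("capacity error: PDB format limited to 99999 atoms")
  multi <- length(models) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- atoms(models[[m]])
    serial <- 0L
    for (ch in unique(a$chain_id)) {
      rows <- which(a$chain_id == ch)
      for (i in rows) {
        serial <- serial + 1L
        writeLines(.pdbAtomLine(serial, a$atom_name[i], a$residue_name[i],
                                a$chain_id[i], a$residue_number[i],
                                a$x[i], a$y[i], a$z[i], a$element[i]), con)
      }
      writeLines("TER", con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Parse an atom selection expression
#'
#' Selection mini-language: `"chain:resstart-resend[:atomname]"`, e.g.
#' `"A:1-20"` or `"A:1-20:CA"`. Several expressions may be combined with
#' `","`. The empty string or `"*"` selects everything.
#'
#' @param conformer A [Conformer-class].
#' @param selection Selection string, or a logical/integer vector already
#'   indexing atoms (passed through).
#' @return Integer vector of atom row indices.
#' @export
selectAtoms <- function(conformer, selection = "*") {
  a <- atoms(conformer)
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  stopifnot(is.character(selection), length(selection) == 1)
  if (selection %in% c("", "*")) return(seq_len(nrow(a)))
  idx <- integer()
  for (expr in strsplit(selection, ",", fixed = TRUE)[[1]]) {
    parts <- strsplit(trimws(expr), ":", fixed = TRUE)[[1]]
    if (length(parts) < 2 || length(parts) > 3)
      stop("bad selection expression: ", expr)
    ch <- parts[1]
    rr <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
    r1 <- as.integer(rr[1]); r2 <- as.integer(rr[length(rr)])
    hit <- a$chain_id == ch & a$residue_number >= r1 & a$residue_number <= r2
    if (length(parts) == 3) hit <- hit & a$atom_name == parts[3]
    idx <- union(idx, which(hit))
  }
  sort(idx)
}
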