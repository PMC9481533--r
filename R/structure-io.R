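#' Read a coordinate file into a FibrilStructure
#'
#' Reads PDB or mmCIF atom records (ATOM and HETATM) via bio3d. Elements are
#' inferred from atom names when the file carries none; ligand residues are
#' flagged via a configurable residue-name set; mmCIF author (auth_) numbering
#' is used, matching the tau core residue numbers 306-378 used throughout.
#'
#' @param path file path.
#' @param format "pdb", "cif" or "auto" (by file extension).
#' @param ligandNames residue names flagged as ligand
#'   (default \code{\link{ligandResidueNames}}).
#' @param radii element-keyed vdW radius set (default \code{\link{vdwRadii}}).
#' @return a \code{\link{FibrilStructure}} (layers unassigned).
#' @export
#' @examples
#' fib <- makeFibril(fixtureSpec(nLayers = 2))
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(fib, f)
#' nAtoms(readStructure(f))
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          ligandNames = ligandResidueNames(),
                          radii = vdwRadii()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- withCallingHandlers(
    tryCatch(
      if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
      error = function(e) stop("cannot parse ", format, " file '", path,
                               "': ", conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      # bio3d::read.cif tags itself beta and skips helix/sheet records
      # unconditionally; neither is actionable here
      if (grepl("beta version|helix/sheet", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  a <- parsed$atom
  if (is.null(a) || !nrow(a)) stop("empty structure: zero atoms in ", path)
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = if (!is.null(a$elesy)) trimws(a$elesy) else NA_character_,
    resname = trimws(a$resid),
    resno = a$resno,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE)
  atoms <- atoms[toupper(atoms$resname) != "HOH", , drop = FALSE]
  fibrilStructure(atoms, ligandNames = ligandNames, radii = radii)
}

#' Write a FibrilStructure to PDB or mmCIF
#'
#' @param x a \code{FibrilStructure}.
#' @param path output path; extension decides the format unless given.
#' @param format "pdb", "cif" or "auto".
#' @param b optional numeric vector (one per atom) written to the
#'   temperature-factor field; defaults to 0.
#' @return invisibly, \code{path}.
#' @export
writeStructure <- function(x, path, format = c("auto", "pdb", "cif"),
                           b = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  a <- x@atoms
  if (is.null(b)) b <- rep(0, nrow(a))
  stopifnot(length(b) == nrow(a))
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(coords(x))),
      type = ifelse(a$ligand, "HETATM", "ATOM"),
      resno = a$resno, resid = a$resname, eleno = a$serial,
      elety = a$name, chain = substr(a$chain, 1, 1),
      o = rep(1, nrow(a)), b = round(b, 2), elesy = a$element)
  } else {
    .writeMinimalCif(a, b, path)
  }
  invisible(path)
}

# Minimal mmCIF atom_site writer using the canonical wwPDB column ordering
# (readers commonly assume it); auth_ and label_ numbering written
# identically.
.writeMinimalCif <- function(a, b, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_fibrilstab", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  rec <- sprintf(
    "%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s %s 1",
    ifelse(a$ligand, "HETATM", "ATOM"), a$serial, a$element, a$name,
    a$resname, a$chain, a$resno, a$x, a$y, a$z, b,
    a$resno, a$resname, a$chain, a$name)
  writeLines(rec, con)
  writeLines("#", con)
}
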