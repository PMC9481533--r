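#' @include AllClasses.R
NULL

# ---- vdW radii and element handling ------------------------------------

#' Default van der Waals radius set
#'
#' Single element-keyed radius table (Bondi-type values, Angstrom) used for
#' every area-dependent quantity in the package, so that all results are
#' reproducible under one declared set. Pass a modified copy to
#' \code{\link{readStructure}} or \code{\link{assignRadii}} to override.
#'
#' @return named numeric vector, Angstrom.
#' @export
#' @examples
#' vdwRadii()[["C"]]
vdwRadii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

# Infer the element from a PDB atom name when the element column is absent.
.elementFromName <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "SE"), two, substr(nm, 1, 1))
  out[!nzchar(out)] <- NA_character_
  out
}

.backboneNames <- c("N", "CA", "C", "O", "OXT")

#' Assign van der Waals radii to all atoms
#'
#' @param x a \code{FibrilStructure}.
#' @param radii named numeric vector keyed by element symbol
#'   (default \code{\link{vdwRadii}}).
#' @return \code{x} with the \code{vdw} column filled.
#' @export
assignRadii <- function(x, radii = vdwRadii()) {
  el <- toupper(x@atoms$element)
  r <- radii[el]
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    stop("no vdW radius for element(s): ", paste(bad, collapse = ", "))
  }
  x@atoms$vdw <- unname(r)
  validObject(x)
  x
}

# ---- Constructors -------------------------------------------------------

#' Construct a FibrilStructure from an atom table
#'
#' @param atoms data.frame with at least \code{name}, \code{resname},
#'   \code{resno}, \code{chain}, \code{x}, \code{y}, \code{z}; \code{element},
#'   \code{serial}, \code{backbone}, \code{ligand}, \code{vdw} are filled when
#'   absent (element inferred from the atom name).
#' @param layers named integer vector (chain -> layer) or NULL.
#' @param protofilaments named character vector (chain -> label) or NULL.
#' @param axis numeric(3), fibril axis direction (normalized).
#' @param ligandNames residue names treated as ligands
#'   (default \code{\link{ligandResidueNames}}).
#' @param radii element-keyed radius set used to fill \code{vdw}.
#' @return a \code{FibrilStructure}.
#' @export
fibrilStructure <- function(atoms, layers = NULL, protofilaments = NULL,
                            axis = c(0, 0, 1),
                            ligandNames = ligandResidueNames(),
                            radii = vdwRadii()) {
  atoms <- as.data.frame(atoms)
  if (!nrow(atoms)) stop("empty structure: zero atoms")
  if (is.null(atoms$element) || all(is.na(atoms$element)))
    atoms$element <- .elementFromName(atoms$name)
  miss <- is.na(atoms$element) | !nzchar(atoms$element)
  if (any(miss)) atoms$element[miss] <- .elementFromName(atoms$name[miss])
  if (anyNA(atoms$element))
    stop("cannot infer element for atom(s): ",
         paste(utils::head(atoms$name[is.na(atoms$element)], 3), collapse = ", "))
  atoms$element <- toupper(atoms$element)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$ligand)) atoms$ligand <- atoms$resname %in% ligandNames
  if (is.null(atoms$backbone))
    atoms$backbone <- !atoms$ligand & atoms$name %in% .backboneNames
  if (is.null(atoms$vdw)) {
    r <- radii[atoms$element]
    if (anyNA(r))
      stop("no vdW radius for element(s): ",
           paste(unique(atoms$element[is.na(r)]), collapse = ", "))
    atoms$vdw <- unname(r)
  }
  keep <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z", "vdw", "backbone", "ligand")
  atoms <- atoms[, keep]
  new("FibrilStructure", atoms = atoms,
      layers = if (is.null(layers)) integer(0) else layers,
      protofilaments = if (is.null(protofilaments)) character(0)
                       else protofilaments,
      axis = .unit(axis))
}

#' Default ligand residue-name set
#'
#' Deposited EGCG uses chemical component IDs KDH/EGC; the synthetic mock
#' ligand uses LIG. Extend via the \code{extra} argument.
#'
#' @param extra additional residue names to treat as ligands.
#' @return character vector.
#' @export
ligandResidueNames <- function(extra = character(0)) {
  unique(c("KDH", "EGC", "LIG", extra))
}

#' Helical symmetry constructor
#' @param rise Angstrom per layer (> 0).
#' @param twist degrees per layer, in (-180, 180].
#' @return a \code{HelicalSymmetry}.
#' @export
#' @examples
#' helicalSymmetry(4.8, -1.2)
helicalSymmetry <- function(rise, twist = 0) {
  new("HelicalSymmetry", rise = as.numeric(rise), twist = as.numeric(twist))
}

# ---- Accessors ----------------------------------------------------------

#' @rdname FibrilStructure-class
#' @param x a \code{FibrilStructure}.
#' @return \code{atoms}: the atom data.frame.
#' @export
atoms <- function(x) x@atoms

#' @rdname FibrilStructure-class
#' @return \code{nAtoms}: number of atoms.
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' @rdname FibrilStructure-class
#' @return \code{chains}: unique chain IDs, in order of appearance.
#' @export
chains <- function(x) unique(x@atoms$chain)

#' @rdname FibrilStructure-class
#' @return \code{proteinChains}: chain IDs containing non-ligand atoms.
#' @export
proteinChains <- function(x) unique(x@atoms$chain[!x@atoms$ligand])

#' @rdname FibrilStructure-class
#' @return \code{layers}: named integer vector chain -> layer index.
#' @export
layers <- function(x) x@layers

#' @rdname FibrilStructure-class
#' @return \code{protofilaments}: named character vector chain -> label.
#' @export
protofilaments <- function(x) x@protofilaments

#' @rdname FibrilStructure-class
#' @return \code{fibrilAxis}: unit axis vector.
#' @export
fibrilAxis <- function(x) x@axis

#' @rdname FibrilStructure-class
#' @return \code{coords}: n x 3 coordinate matrix, Angstrom.
#' @export
coords <- function(x) as.matrix(x@atoms[, c("x", "y", "z")])

#' Select atom indices by attribute
#'
#' Conjunctive (AND) filter over atom attributes; NULL arguments are ignored.
#'
#' @param x a \code{FibrilStructure}.
#' @param chain,resno,resname,name,element vectors of allowed values.
#' @param ligand,backbone logical filters.
#' @return integer vector of atom row indices.
#' @export
#' @examples
#' fib <- makeFibril(fixtureSpec(nLayers = 2))
#' length(atomSelect(fib, name = "CA"))
atomSelect <- function(x, chain = NULL, resno = NULL, resname = NULL,
                       name = NULL, element = NULL, ligand = NULL,
                       backbone = NULL) {
  a <- x@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
  if (!is.null(ligand)) keep <- keep & a$ligand == ligand
  if (!is.null(backbone)) keep <- keep & a$backbone == backbone
  which(keep)
}

#' Apply a rigid transform to a structure
#'
#' Rotates and translates all atom coordinates and rotates the stored fibril
#' axis, so that axis-dependent analyses (stacking metrics, spacing profiles)
#' are invariant under the transform.
#'
#' @param x a \code{FibrilStructure}.
#' @param R 3 x 3 rotation matrix.
#' @param t numeric(3) translation, Angstrom.
#' @return transformed \code{FibrilStructure}.
#' @export
transformStructure <- function(x, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(x) %*% t(R)
  x@atoms$x <- xyz[, 1] + t[1]
  x@atoms$y <- xyz[, 2] + t[2]
  x@atoms$z <- xyz[, 3] + t[3]
  x@axis <- as.numeric(R %*% x@axis)
  x
}

# ---- show methods -------------------------------------------------------

setMethod("show", "FibrilStructure", function(object) {
  a <- object@atoms
  cat("FibrilStructure:", nrow(a), "atoms,",
      length(unique(a$chain)), "chains",
      sprintf("(%d ligand atoms)\n", sum(a$ligand)))
  if (length(object@layers))
    cat("  layers:", paste(range(object@layers), collapse = ".."),
        " protofilaments:",
        paste(unique(object@protofilaments), collapse = "/"), "\n")
  cat("  axis: [", paste(sprintf("%.3f", object@axis), collapse = ", "), "]\n")
})

setMethod("show", "HelicalSymmetry", function(object) {
  cat(sprintf("HelicalSymmetry: rise %.3f A, twist %.3f deg per layer\n",
              object@rise, object@twist))
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf(
    "SasaResult: %d atoms, total %.1f A^2 (probe %.2f A, %d points)\n",
    length(object@area), sum(object@area), object@probe, object@nPoints))
})

setMethod("show", "SolvationEnergyMap", function(object) {
  cat("SolvationEnergyMap:", nrow(object@atoms), "atoms,",
      nrow(object@residues), "residues\n")
  for (i in seq_len(nrow(object@chains)))
    cat(sprintf("  chain %s (%s): %.2f kcal/mol\n",
                object@chains$chain[i], object@chains$protofilament[i],
                object@chains$total[i]))
  if (!is.null(object@metadata$meanChainTotal))
    cat(sprintf("  mean per chain: %.2f kcal/mol\n",
                object@metadata$meanChainTotal))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid: %d x %d x %d voxels, voxel %.2f A\n",
              d[1], d[2], d[3], object@voxel[1]))
})

setMethod("show", "VoxelMask", function(object) {
  cat(sprintf("VoxelMask (%s): %d voxels set\n",
              object@label, sum(object@values)))
})

# ---- SasaResult / map accessors ----------------------------------------

#' @rdname SasaResult-class
#' @param x a \code{SasaResult}.
#' @return \code{sasa}: the per-atom area vector.
#' @export
sasa <- function(x) x@area

#' @rdname SolvationEnergyMap-class
#' @param x a \code{SolvationEnergyMap}.
#' @return \code{atomEnergies}: per-atom table.
#' @export
atomEnergies <- function(x) x@atoms

#' @rdname SolvationEnergyMap-class
#' @return \code{residueEnergies}: per-residue table.
#' @export
residueEnergies <- function(x) x@residues

#' @rdname SolvationEnergyMap-class
#' @return \code{chainEnergies}: per-chain totals.
#' @export
chainEnergies <- function(x) x@chains

#' @rdname DensityGrid-class
#' @param x a \code{DensityGrid} or \code{VoxelMask}.
#' @return \code{gridValues}: the 3-D array.
#' @export
gridValues <- function(x) x@values
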