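#' @import methods
NULL

#' Hierarchical coordinate model of a fibril
#'
#' An atom-level coordinate model with fibril-specific annotations: a per-chain
#' layer index (rung along the helical axis), a per-chain protofilament label,
#' and an estimate of the fibril axis direction. The axis is stored as a unit
#' vector and, by package convention, the helical axis line passes through the
#' coordinate origin (the synthetic generator and \code{\link{expandHelical}}
#' both use this convention).
#'
#' @slot atoms data.frame with one row per atom and columns \code{serial},
#'   \code{name}, \code{element}, \code{resname}, \code{resno}, \code{chain},
#'   \code{x}, \code{y}, \code{z}, \code{vdw} (van der Waals radius, Angstrom),
#'   \code{backbone} (logical), \code{ligand} (logical).
#' @slot layers named integer vector mapping protein chain ID to layer index;
#'   may be empty until \code{\link{assignLayers}} is called. Ligand-only
#'   chains are exempt.
#' @slot protofilaments named character vector mapping protein chain ID to a
#'   protofilament label (typically "A"/"B").
#' @slot axis numeric(3) unit vector, the fibril axis direction.
#'
#' @seealso \code{\link{readStructure}}, \code{\link{makeFibril}},
#'   \code{\link{assignLayers}}
#' @export
setClass("FibrilStructure",
  representation(
    atoms = "data.frame",
    layers = "integer",
    protofilaments = "character",
    axis = "numeric"
  ),
  prototype(
    layers = integer(0),
    protofilaments = character(0),
    axis = c(0, 0, 1)
  )
)

.validFibrilStructure <- function(object) {
  msg <- character(0)
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z", "vdw", "backbone", "ligand")
  miss <- setdiff(need, names(a))
  if (length(miss))
    msg <- c(msg, paste("atoms is missing columns:", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(a)) {
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
      msg <- c(msg, "non-finite atom coordinates")
    if (any(!nzchar(a$element)))
      msg <- c(msg, "empty element symbols")
    if (any(!is.na(a$vdw) & a$vdw <= 0))
      msg <- c(msg, "non-positive vdW radii")
  }
  if (length(object@axis) != 3 || abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
    msg <- c(msg, "axis must be a unit 3-vector")
  if (length(object@layers)) {
    pc <- proteinChains(object)
    if (!all(pc %in% names(object@layers)))
      msg <- c(msg, "layers must cover every protein chain")
  }
  if (length(msg)) msg else TRUE
}
setValidity("FibrilStructure", .validFibrilStructure)

#' Helical symmetry operator
#'
#' Rise (axial translation, Angstrom) and twist (rotation, degrees) applied per
#' fibril layer. Cross-beta amyloids stack at a rise of about 4.8 Angstrom with
#' a small twist.
#'
#' @slot rise numeric(1), Angstrom per layer, > 0.
#' @slot twist numeric(1), degrees per layer, in (-180, 180].
#' @export
setClass("HelicalSymmetry",
  representation(rise = "numeric", twist = "numeric"))

setValidity("HelicalSymmetry", function(object) {
  msg <- character(0)
  if (length(object@rise) != 1 || !is.finite(object@rise) || object@rise <= 0)
    msg <- c(msg, "rise must be a single positive number")
  if (length(object@twist) != 1 || !is.finite(object@twist) ||
      object@twist <= -180 || object@twist > 180)
    msg <- c(msg, "twist must be in (-180, 180] degrees")
  if (length(msg)) msg else TRUE
})

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley areas for a selection of atoms, aligned to the order of the
#' selection they were computed for.
#'
#' @slot area numeric vector of areas (Angstrom^2), one per computed atom.
#' @slot atoms data.frame identifying the computed atoms
#'   (\code{chain}, \code{resno}, \code{resname}, \code{name}, \code{vdw}).
#' @slot probe numeric(1), probe radius in Angstrom.
#' @slot nPoints integer(1), sphere sample points per atom.
#' @slot fallback character vector of residue keys for which an extended
#'   rebuild fell back to the as-posed chain (reference mode only).
#' @export
setClass("SasaResult",
  representation(area = "numeric", atoms = "data.frame",
                 probe = "numeric", nPoints = "integer",
                 fallback = "character"),
  prototype(fallback = character(0)))

setValidity("SasaResult", function(object) {
  msg <- character(0)
  if (length(object@area) != nrow(object@atoms))
    msg <- c(msg, "area length must match atoms rows")
  if (any(object@area < -1e-9))
    msg <- c(msg, "negative areas")
  lim <- 4 * pi * (object@atoms$vdw + object@probe)^2
  if (length(lim) && any(object@area > lim + 1e-6))
    msg <- c(msg, "area exceeds the isolated-sphere bound")
  if (length(msg)) msg else TRUE
})

#' Per-atom solvation energy map
#'
#' Atom-wise solvation free energies for the scored (central) chains of a
#' fibril, with residue and chain aggregations. The chain total is exactly the
#' sum of its atom energies plus the sum of its residue ordering-entropy
#' penalties. Also the container for pairwise difference maps
#' (\code{\link{differenceMap}}), in which case entropy terms are differences.
#'
#' @slot atoms data.frame: \code{chain}, \code{protofilament}, \code{resno},
#'   \code{resname}, \code{name}, \code{element}, \code{class},
#'   \code{sasaFold}, \code{sasaRef}, \code{energy} (kcal/mol).
#' @slot residues data.frame: per-residue atom-energy sum, entropy penalty and
#'   total.
#' @slot chains data.frame: per-chain totals (kcal/mol/chain).
#' @slot metadata list: ASP table identity, entropy table identity, SASA
#'   settings, sign convention, pairing diagnostics for difference maps.
#' @export
setClass("SolvationEnergyMap",
  representation(atoms = "data.frame", residues = "data.frame",
                 chains = "data.frame", metadata = "list"))

setValidity("SolvationEnergyMap", function(object) {
  msg <- character(0)
  for (ch in object@chains$chain) {
    at <- sum(object@atoms$energy[object@atoms$chain == ch])
    en <- sum(object@residues$entropy[object@residues$chain == ch])
    tot <- object@chains$total[object@chains$chain == ch]
    if (abs(tot - (at + en)) > 1e-9)
      msg <- c(msg, sprintf("chain %s total != atoms + entropy", ch))
  }
  if (length(msg)) msg else TRUE
})

#' Regular 3-D density grid
#'
#' Voxel values on a regular orthogonal grid in the canonical x,y,z axis
#' order: \code{values[i, j, k]} is the density at Cartesian position
#' \code{origin + (c(i, j, k) - 1) * voxel} (voxel centers).
#'
#' @slot values 3-D numeric array.
#' @slot voxel numeric(3) voxel edge lengths, Angstrom.
#' @slot origin numeric(3) position of the first voxel center, Angstrom.
#' @export
setClass("DensityGrid",
  representation(values = "array", voxel = "numeric", origin = "numeric"))

setValidity("DensityGrid", function(object) {
  msg <- character(0)
  d <- dim(object@values)
  if (length(d) != 3 || any(d < 2))
    msg <- c(msg, "values must be a 3-D array with >= 2 voxels per axis")
  if (length(object@voxel) != 3 || any(object@voxel <= 0))
    msg <- c(msg, "voxel must be positive numeric(3)")
  if (length(object@origin) != 3)
    msg <- c(msg, "origin must be numeric(3)")
  if (length(msg)) msg else TRUE
})

#' Boolean voxel mask over a density grid
#'
#' @slot values 3-D logical array, congruent with its \code{DensityGrid}.
#' @slot label character(1), one of "site", "reference", "solvent".
#' @export
setClass("VoxelMask",
  representation(values = "array", label = "character"))

setValidity("VoxelMask", function(object) {
  msg <- character(0)
  if (length(dim(object@values)) != 3 || !is.logical(object@values))
    msg <- c(msg, "values must be a 3-D logical array")
  if (!any(object@values))
    msg <- c(msg, "mask is empty")
  if (!object@label %in% c("site", "reference", "solvent"))
    msg <- c(msg, "label must be site/reference/solvent")
  if (length(msg)) msg else TRUE
})

#' Synthetic fixture specification
#'
#' All tunable parameters of the synthetic fibril / ligand-column / density-map
#' generator, with the seed that makes every output a pure function of the
#' spec. Defaults emulate a PHF-like geometry: two C2-related protofilaments,
#' 4.8 Angstrom rise, -1.2 degree/layer twist, 5 layers (10 chains), residue
#' numbering in the tau PHF core range.
#'
#' @slot params named list, see \code{\link{fixtureSpec}}.
#' @export
setClass("FixtureSpec", representation(params = "list"))
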