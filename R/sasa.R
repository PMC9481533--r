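#' @useDynLib fibrilstab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Shrake-Rupley solvent accessible surface area
#'
#' Computes per-atom SASA for a selection of atoms, with all (heavy) atoms of
#' the structure acting as occluders. For each atom, quasi-uniform points on
#' its solvent-expanded sphere (radius vdW + probe) are tested against every
#' neighbour's expanded sphere; the accessible fraction is scaled by the
#' sphere area. The sphere point set is a deterministic generalized spiral, so
#' results are bit-reproducible. Hydrogens are ignored (heavy-atom SASA).
#'
#' @param x a \code{FibrilStructure}.
#' @param subset integer atom indices to compute areas for (default: all
#'   heavy atoms). All heavy atoms always occlude.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param nPoints sphere sample points per atom (>= 100; default 960).
#' @return a \code{\link{SasaResult}} aligned to \code{subset} order.
#' @export
#' @examples
#' one <- fibrilStructure(data.frame(name = "CA", resname = "ALA", resno = 1,
#'                                   chain = "A", x = 0, y = 0, z = 0))
#' sasa(computeSasa(one))  # 4*pi*(1.7+1.4)^2
computeSasa <- function(x, subset = NULL, probe = 1.4, nPoints = 960L) {
  stopifnot(is(x, "FibrilStructure"))
  if (nPoints < 100) stop("nPoints must be >= 100")
  a <- x@atoms
  heavy <- which(toupper(a$element) != "H")
  if (is.null(subset)) subset <- heavy
  subset <- as.integer(subset)
  if (!length(subset)) stop("empty atom selection")
  if (any(subset < 1 | subset > nrow(a))) stop("subset out of range")
  subset <- subset[toupper(a$element[subset]) != "H"]
  bad <- which(is.na(a$vdw[heavy]) | a$vdw[heavy] <= 0)
  if (length(bad))
    stop("atom without vdW radius: ",
         paste(a$name[heavy][utils::head(bad, 3)], collapse = ", "),
         " (assign radii first)")
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  pts <- .spherePoints(as.integer(nPoints))
  idxInHeavy <- match(subset, heavy)
  area <- .sasaCpp(xyz, a$vdw[heavy], probe, pts, idxInHeavy)
  new("SasaResult", area = area,
      atoms = a[subset, c("chain", "resno", "resname", "name", "vdw")],
      probe = probe, nPoints = as.integer(nPoints))
}

#' Reference-state SASA of a single chain
#'
#' The reference state for solvation-energy maps: either the chain re-posed
#' as an ideal extended strand (phi = -120, psi = 120, omega = 180 degrees;
#' side chains transferred rigidly on each residue's local backbone frame) and
#' taken in isolation, or simply the chain as-posed with every other chain
#' removed. Ligand atoms are excluded. Residues that cannot be rebuilt
#' (missing N/CA/C) fall back to as-posed isolated-chain areas, with the
#' affected residues recorded in the result's \code{fallback} slot.
#'
#' @param x a \code{FibrilStructure}.
#' @param chain single chain ID.
#' @param mode "extended-rebuild" (default) or "isolated-chain".
#' @param probe,nPoints SASA settings, see \code{\link{computeSasa}}.
#' @return a \code{\link{SasaResult}} aligned to the chain's protein atoms in
#'   structure order.
#' @export
referenceSasa <- function(x, chain,
                          mode = c("extended-rebuild", "isolated-chain"),
                          probe = 1.4, nPoints = 960L) {
  mode <- match.arg(mode)
  idx <- atomSelect(x, chain = chain, ligand = FALSE)
  if (!length(idx)) stop("chain ", chain, " has no protein atoms")
  a <- x@atoms[idx, ]
  iso <- fibrilStructure(a)
  if (mode == "isolated-chain")
    return(computeSasa(iso, probe = probe, nPoints = nPoints))
  rb <- .extendedRebuild(a)
  ext <- fibrilStructure(rb$atoms)
  res <- computeSasa(ext, probe = probe, nPoints = nPoints)
  if (length(rb$failed)) {
    warning("extended rebuild fell back to isolated-chain for residue(s): ",
            paste(rb$failed, collapse = ", "))
    isoRes <- computeSasa(iso, probe = probe, nPoints = nPoints)
    hit <- as.character(a$resno) %in% rb$failed
    # computeSasa drops hydrogens identically for both paths
    res@area[hit[toupper(a$element) != "H"]] <-
      isoRes@area[hit[toupper(a$element) != "H"]]
    res@fallback <- rb$failed
  }
  res
}
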