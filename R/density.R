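#' Construct a DensityGrid
#'
#' @param values 3-D numeric array in canonical x,y,z axis order.
#' @param voxel voxel edge length(s), Angstrom (scalar or numeric(3)).
#' @param origin position of the first voxel center, Angstrom.
#' @return a \code{\link{DensityGrid}}.
#' @export
densityGrid <- function(values, voxel = 1, origin = c(0, 0, 0)) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  new("DensityGrid", values = values, voxel = as.numeric(voxel),
      origin = as.numeric(origin))
}

# Voxel-center Cartesian coordinates along one axis.
.axisCoords <- function(grid, k) {
  grid@origin[k] + (seq_len(dim(grid@values)[k]) - 1) * grid@voxel[k]
}

# ---- MRC2014 I/O --------------------------------------------------------

#' Read an MRC/CCP4 density map
#'
#' Minimal MRC2014 reader: modes 0 (int8), 1 (int16), 2 (float32); axis order
#' (mapc/mapr/maps) is normalized to canonical x,y,z; the origin is taken
#' from the ORIGIN header words when set, otherwise from nxstart/nystart/
#' nzstart times the voxel size. Non-orthogonal cells are rejected (cryoEM
#' maps are orthogonal).
#'
#' @param path MRC/CCP4 file.
#' @return a \code{\link{DensityGrid}}.
#' @export
readMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdrFlt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nc <- hdrInt[1]; nr <- hdrInt[2]; ns <- hdrInt[3]
  mode <- hdrInt[4]
  if (any(c(nc, nr, ns) <= 0) || any(c(nc, nr, ns) > 4096))
    stop("corrupt MRC header: bad dimensions ",
         paste(c(nc, nr, ns), collapse = "x"))
  nstart <- hdrInt[5:7]
  mxyz <- hdrInt[8:10]
  cella <- hdrFlt[11:13]
  cellb <- hdrFlt[14:16]
  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal cell (angles ", paste(cellb, collapse = ", "),
         "); only orthogonal maps are supported")
  mapcrs <- hdrInt[17:19]
  if (!all(sort(mapcrs) == 1:3))
    stop("corrupt MRC header: bad axis order ", paste(mapcrs, collapse = ","))
  originWords <- hdrFlt[50:52]
  nsymbt <- hdrInt[24]
  seek(con, 1024 + max(0, nsymbt))
  nvox <- nc * nr * ns
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode))
  if (length(vals) != nvox) stop("truncated MRC data block")
  arr <- array(vals, dim = c(nc, nr, ns))
  # permute from file (column, row, section) order to canonical x, y, z
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  mxyz[mxyz <= 0] <- c(nc, nr, ns)
  voxel <- (cella / mxyz)[perm]   # to canonical x, y, z order
  voxel[!is.finite(voxel) | voxel <= 0] <- 1
  nstartXYZ <- nstart[perm]
  origin <- if (any(abs(originWords) > 1e-6)) originWords
            else nstartXYZ * voxel
  densityGrid(arr, voxel = voxel, origin = origin)
}

#' Write a DensityGrid as MRC2014 (mode 2)
#'
#' @param grid a \code{\link{DensityGrid}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMap <- function(grid, path) {
  stopifnot(is(grid, "DensityGrid"))
  d <- dim(grid@values)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  v <- grid@values
  wInt(d)                   # nx, ny, nz
  wInt(2)                   # mode: float32
  wInt(c(0, 0, 0))          # nstart
  wInt(d)                   # mx, my, mz
  wFlt(d * grid@voxel)      # cell a, b, c
  wFlt(c(90, 90, 90))       # cell angles
  wInt(1:3)                 # mapc, mapr, maps: canonical
  wFlt(c(min(v), max(v), mean(v)))
  wInt(1)                   # ispg
  wInt(0)                   # nsymbt
  wInt(rep(0, 25))          # extra (words 26-49, incl. exttyp/nversion zeros)
  wFlt(grid@origin)         # origin x, y, z (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(stats::sd(as.numeric(v)))
  wInt(0)                   # nlabl
  writeBin(raw(800), con)   # labels
  wFlt(as.numeric(v))
  invisible(path)
}

# ---- Gaussian-atom map simulation --------------------------------------

# Accumulate isotropic Gaussian atoms (sigma = resolution/3, amplitude
# proportional to atomic number) on a grid; ligand atom amplitudes are
# multiplied by `ligandScale`.
.atomicNumber <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                   F = 9, CL = 17, BR = 35, I = 53, SE = 34)

.gaussianField <- function(x, grid, resolution, subset, scale = 1) {
  sig <- resolution / 3
  arr <- array(0, dim(grid@values))
  if (!length(subset)) return(arr)
  a <- x@atoms[subset, ]
  z <- .atomicNumber[toupper(a$element)]
  z[is.na(z)] <- 6
  gx <- .axisCoords(grid, 1); gy <- .axisCoords(grid, 2)
  gz <- .axisCoords(grid, 3)
  cut <- 4 * sig
  for (i in seq_len(nrow(a))) {
    ix <- which(abs(gx - a$x[i]) <= cut)
    iy <- which(abs(gy - a$y[i]) <= cut)
    iz <- which(abs(gz - a$z[i]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    ex <- exp(-(gx[ix] - a$x[i])^2 / (2 * sig^2))
    ey <- exp(-(gy[iy] - a$y[i])^2 / (2 * sig^2))
    ez <- exp(-(gz[iz] - a$z[i])^2 / (2 * sig^2))
    arr[ix, iy, iz] <- arr[ix, iy, iz, drop = FALSE] +
      (scale * z[i]) * (ex %o% ey %o% ez)
  }
  arr
}

#' Simulate a Gaussian-atom density map with known ligand occupancy
#'
#' One isotropic Gaussian per heavy atom (sigma = resolution/3, amplitude
#' proportional to atomic number). The ligand contribution is calibrated so
#' that at full occupancy its site peak equals the protein reference peak --
#' the normalization the three-mask occupancy estimator assumes -- and is then
#' scaled by the spec's \code{ligandFraction}, which thereby encodes the
#' ground-truth occupancy. Optional i.i.d. Gaussian voxel noise is drawn with
#' the spec seed, so equal specs give identical maps.
#'
#' @param x a \code{FibrilStructure} (ligand atoms flagged).
#' @param spec a \code{\link{fixtureSpec}} (voxel, resolution, ligand
#'   fraction, noise sd, seed).
#' @param pad box padding beyond the model extent, Angstrom (default 14,
#'   enough for the default 6-12 Angstrom solvent shell).
#' @return a \code{\link{DensityGrid}}.
#' @export
simulateMap <- function(x, spec, pad = 14) {
  stopifnot(is(x, "FibrilStructure"), is(spec, "FixtureSpec"))
  p <- spec@params
  if (p$mapVoxel >= p$mapResolution / 2)
    stop("voxel too coarse: need voxel < resolution/2")
  xyz <- coords(x)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  n <- pmax(2L, as.integer(ceiling((hi - lo) / p$mapVoxel)) + 1L)
  grid <- densityGrid(array(0, n), voxel = p$mapVoxel, origin = lo)
  heavy <- toupper(x@atoms$element) != "H"
  protIdx <- which(!x@atoms$ligand & heavy)
  ligIdx <- which(x@atoms$ligand & heavy)
  P <- .gaussianField(x, grid, p$mapResolution, protIdx)
  out <- P
  if (length(ligIdx) && p$ligandFraction > 0 && !length(protIdx)) {
    # ligand-only structure: no reference to calibrate against
    out <- p$ligandFraction * .gaussianField(x, grid, p$mapResolution, ligIdx)
  } else if (length(ligIdx) && p$ligandFraction > 0) {
    L <- .gaussianField(x, grid, p$mapResolution, ligIdx)
    # calibrate the full-occupancy ligand peak (over the default 2 A site
    # region) to the protein peak -- the estimator's reference-normalization
    # assumption, making ligandFraction the ground-truth occupancy
    siteRegion <- .withinMask(x, grid, ligIdx, 2.0)
    lSite <- L[siteRegion]
    pSite <- P[siteRegion]
    refPeak <- max(P)
    beta <- refPeak / max(lSite)
    for (it in 1:4)
      beta <- beta * refPeak / max(beta * lSite + pSite)
    out <- P + (p$ligandFraction * beta) * L
  }
  if (p$noiseSd > 0) {
    out <- out + withr::with_seed(p$seed,
      array(stats::rnorm(length(out), 0, p$noiseSd), dim(out)))
  }
  grid@values <- out
  grid
}

# ---- Masks and occupancy ------------------------------------------------

# Logical array of voxels within `radius` of any atom in `sel`.
.withinMask <- function(x, grid, sel, radius) {
  d <- dim(grid@values)
  m <- array(FALSE, d)
  gx <- .axisCoords(grid, 1); gy <- .axisCoords(grid, 2)
  gz <- .axisCoords(grid, 3)
  a <- x@atoms[sel, ]
  r2 <- radius^2
  for (i in seq_len(nrow(a))) {
    ix <- which(abs(gx - a$x[i]) <= radius)
    iy <- which(abs(gy - a$y[i]) <= radius)
    iz <- which(abs(gz - a$z[i]) <= radius)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - a$x[i])^2
    dy2 <- (gy[iy] - a$y[i])^2
    dz2 <- (gz[iz] - a$z[i])^2
    dd <- outer(outer(dx2, dy2, "+"), dz2, "+")
    m[ix, iy, iz] <- m[ix, iy, iz, drop = FALSE] | (dd <= r2)
  }
  m
}

#' Build site, reference and solvent voxel masks
#'
#' The three masks of the occupancy estimator: \emph{site} = voxels within
#' \code{siteR} of any site-selection atom (the ligand density); \emph{reference}
#' = voxels within \code{refR} of backbone atoms (N, CA, C, O) of the
#' reference selection (residues 345-352 of the protein in the original
#' analysis); \emph{solvent} = voxels between \code{solventNear} and
#' \code{solventFar} of \emph{any} model atom. The solvent construction makes
#' the three masks pairwise disjoint; overlapping site and reference masks are
#' an error.
#'
#' @param x a \code{FibrilStructure}.
#' @param grid the \code{\link{DensityGrid}} the masks apply to.
#' @param siteSel,refSel atom index vectors (see \code{\link{atomSelect}}).
#' @param siteR,refR atom-mask radii, Angstrom (defaults 2.0).
#' @param solventNear,solventFar solvent shell bounds, Angstrom
#'   (defaults 6 and 12); must satisfy
#'   \code{solventFar > solventNear > max(siteR, refR)}.
#' @return named list of three \code{\link{VoxelMask}} objects
#'   (\code{site}, \code{reference}, \code{solvent}).
#' @export
buildMasks <- function(x, grid, siteSel, refSel, siteR = 2.0, refR = 2.0,
                       solventNear = 6.0, solventFar = 12.0) {
  if (!length(siteSel) || !length(refSel)) stop("empty mask selection")
  if (length(intersect(siteSel, refSel)))
    stop("site and reference selections share atoms")
  if (!(solventFar > solventNear && solventNear > max(siteR, refR)))
    stop("need solventFar > solventNear > max(siteR, refR)")
  refBB <- refSel[x@atoms$backbone[refSel]]
  if (!length(refBB)) stop("reference selection has no backbone atoms")
  site <- .withinMask(x, grid, siteSel, siteR)
  ref <- .withinMask(x, grid, refBB, refR)
  if (any(site & ref))
    stop("site and reference masks overlap; separate the selections or ",
         "shrink the radii")
  allIdx <- which(toupper(x@atoms$element) != "H")
  near <- .withinMask(x, grid, allIdx, solventNear)
  far <- .withinMask(x, grid, allIdx, solventFar)
  solvent <- far & !near
  if (!any(site)) stop("site mask is empty")
  if (!any(ref)) stop("reference mask is empty")
  if (!any(solvent)) stop("solvent mask is empty (grid too small?)")
  list(site = new("VoxelMask", values = site, label = "site"),
       reference = new("VoxelMask", values = ref, label = "reference"),
       solvent = new("VoxelMask", values = solvent, label = "solvent"))
}

#' Three-mask ligand occupancy estimate
#'
#' The masked-statistics occupancy formula:
#' \deqn{(max(site) - avg(solvent)) / (max(reference) - avg(solvent))}
#' where max is the single maximum voxel value in the mask (optionally a
#' trimmed maximum for noise robustness) and avg(solvent) is the mean over
#' the solvent mask. The value is not clamped; the three intermediate
#' statistics are returned alongside. The estimate is invariant to affine
#' rescaling of the voxel values (v -> a v + b, a > 0).
#'
#' @param grid a \code{\link{DensityGrid}}.
#' @param site,ref,solvent \code{\link{VoxelMask}}s congruent with the grid.
#' @param trim FALSE (default: literal maximum) or a quantile in (0, 1]
#'   (e.g. 0.99) used as a trimmed maximum.
#' @return list with \code{occupancy}, \code{maxSite}, \code{maxRef},
#'   \code{meanSolvent}.
#' @export
occupancy <- function(grid, site, ref, solvent, trim = FALSE) {
  for (m in list(site, ref, solvent))
    if (!identical(dim(m@values), dim(grid@values)))
      stop("mask dimensions do not match the grid")
  v <- grid@values
  mx <- function(vals) {
    if (identical(trim, FALSE)) max(vals)
    else stats::quantile(vals, probs = trim, names = FALSE, type = 7)
  }
  maxSite <- mx(v[site@values])
  maxRef <- mx(v[ref@values])
  meanSolv <- mean(v[solvent@values])
  if (maxRef <= meanSolv)
    stop("degenerate reference: max(reference) <= avg(solvent)")
  list(occupancy = (maxSite - meanSolv) / (maxRef - meanSolv),
       maxSite = maxSite, maxRef = maxRef, meanSolvent = meanSolv)
}

#' Masked real-space model-map correlation
#'
#' Pearson correlation, over the masked voxels, between the observed map and
#' a Gaussian-atom map simulated from the selected atoms at the stated
#' resolution. Used to compare candidate ligand poses against the density.
#'
#' @param x a \code{FibrilStructure}.
#' @param grid observed \code{\link{DensityGrid}}.
#' @param mask a \code{\link{VoxelMask}}.
#' @param resolution simulation resolution, Angstrom.
#' @param subset atom indices to simulate (default: all heavy atoms).
#' @return correlation in [-1, 1].
#' @export
realSpaceCC <- function(x, grid, mask, resolution = 3.8, subset = NULL) {
  if (!identical(dim(mask@values), dim(grid@values)))
    stop("mask dimensions do not match the grid")
  if (is.null(subset)) subset <- which(toupper(x@atoms$element) != "H")
  sim <- .gaussianField(x, grid, resolution, subset)
  obs <- grid@values[mask@values]
  mod <- sim[mask@values]
  if (stats::sd(obs) < 1e-12 || stats::sd(mod) < 1e-12)
    stop("undefined correlation: constant values inside the mask")
  stats::cor(obs, mod)
}
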