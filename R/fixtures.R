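#' Synthetic fixture specification
#'
#' Collects every tunable of the synthetic-data generator. The defaults are
#' the package's study conditions: a PHF-like fibril of two C2-related
#' protofilaments, 5 layers at 4.8 Angstrom rise and -1.2 degree/layer twist
#' (10 chains), chains numbered in the tau PHF core range around the
#' inter-protofilament cleft (338-348 by default), a planar tri-ring mock
#' ligand column in the cleft, and Gaussian-atom maps at 3.8 Angstrom nominal
#' resolution on a 1 Angstrom grid.
#'
#' @param nLayers number of fibril layers (>= 1).
#' @param rise helical rise, Angstrom/layer.
#' @param twist helical twist, degrees/layer. The -1.2 default is a typical
#'   PHF-scale fixture convention, not a measured value.
#' @param protofilaments 1 or 2.
#' @param template "poly-ala", "poly-gly", "cleft" (poly-Ala with
#'   Glu338/Lys340/Ser341/Glu342/Lys343 where in range) or "user"
#'   (supply \code{sequence}).
#' @param sequence character vector of 3-letter codes for template "user".
#' @param resStart first residue number (default 338).
#' @param nResidues residues per chain (default 11: 338-348).
#' @param ligandCount mock-ligand copies in the cleft column (0 = none;
#'   must be <= nLayers).
#' @param ligandSpacing axial spacing of ligand copies, Angstrom.
#' @param ligandCompression target solvent-face edge separation, Angstrom
#'   (NULL = flat stack; e.g. 3.5 reproduces the curved-stack signature).
#' @param ligandAnchor numeric(3) position of the fibril-facing ring center
#'   of ligand copy 0. The default (0, 0, 1.5) sits in the inter-protofilament
#'   cleft in polar contact with both chains and clash-free.
#' @param mapVoxel voxel edge, Angstrom.
#' @param mapResolution nominal map resolution, Angstrom (Gaussian sigma =
#'   resolution / 3).
#' @param ligandFraction ground-truth ligand occupancy encoded in the map,
#'   in [0, 1.5].
#' @param noiseSd voxel Gaussian noise sd, map units.
#' @param seed integer seed; equal specs give bit-identical outputs.
#' @return a \code{FixtureSpec}.
#' @export
#' @examples
#' sp <- fixtureSpec(nLayers = 5, ligandCount = 5)
#' fib <- makeLigandColumn(makeFibril(sp), sp)
fixtureSpec <- function(nLayers = 5L, rise = 4.8, twist = -1.2,
                        protofilaments = 2L,
                        template = c("poly-ala", "poly-gly", "cleft", "user"),
                        sequence = NULL, resStart = 338L, nResidues = 11L,
                        ligandCount = 0L, ligandSpacing = 4.8,
                        ligandCompression = NULL,
                        ligandAnchor = c(0, 0, 1.5),
                        mapVoxel = 1.0, mapResolution = 3.8,
                        ligandFraction = 1.0, noiseSd = 0, seed = 1L) {
  template <- match.arg(template)
  p <- list(nLayers = as.integer(nLayers), rise = rise, twist = twist,
            protofilaments = as.integer(protofilaments), template = template,
            sequence = sequence, resStart = as.integer(resStart),
            nResidues = as.integer(nResidues),
            ligandCount = as.integer(ligandCount),
            ligandSpacing = ligandSpacing,
            ligandCompression = ligandCompression,
            ligandAnchor = ligandAnchor,
            mapVoxel = mapVoxel, mapResolution = mapResolution,
            ligandFraction = ligandFraction, noiseSd = noiseSd,
            seed = as.integer(seed))
  if (p$nLayers < 1) stop("nLayers must be >= 1")
  if (p$rise <= 0 || p$ligandSpacing <= 0 || p$mapVoxel <= 0 ||
      p$mapResolution <= 0)
    stop("all lengths must be > 0")
  if (!p$protofilaments %in% 1:2) stop("protofilaments must be 1 or 2")
  if (p$ligandFraction < 0 || p$ligandFraction > 1.5)
    stop("ligandFraction must be in [0, 1.5]")
  if (p$ligandCount > p$nLayers)
    stop("ligandCount must be <= nLayers")
  if (p$nResidues < 2) stop("nResidues must be >= 2")
  if (p$template == "user" && is.null(p$sequence))
    stop("template 'user' requires a sequence")
  new("FixtureSpec", params = p)
}

setMethod("show", "FixtureSpec", function(object) {
  p <- object@params
  cat(sprintf(
    "FixtureSpec: %d layer(s) x %d protofilament(s), rise %.2f A, twist %.2f deg\n",
    p$nLayers, p$protofilaments, p$rise, p$twist))
  cat(sprintf("  template %s, residues %d-%d; %d ligand copies; seed %d\n",
              p$template, p$resStart, p$resStart + p$nResidues - 1,
              p$ligandCount, p$seed))
})

.fixtureSequence <- function(p) {
  if (p$template == "user") {
    if (length(p$sequence) != p$nResidues)
      stop("sequence length must equal nResidues")
    return(toupper(p$sequence))
  }
  seqv <- rep(switch(p$template, "poly-gly" = "GLY", "ALA"), p$nResidues)
  if (p$template == "cleft") {
    resno <- p$resStart + seq_len(p$nResidues) - 1L
    special <- c("338" = "GLU", "340" = "LYS", "341" = "SER",
                 "342" = "GLU", "343" = "LYS")
    hit <- match(as.character(resno), names(special))
    seqv[!is.na(hit)] <- special[hit[!is.na(hit)]]
  }
  seqv
}

#' Build a synthetic two-protofilament fibril
#'
#' Builds one template layer (an extended strand per protofilament, the
#' second protofilament C2-related to the first about the fibril axis, with a
#' polar cleft at the inter-protofilament junction around the origin) and
#' stacks it with \code{\link{expandHelical}}. Deterministic given the spec.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return a \code{FibrilStructure} with layers, protofilaments and axis set.
#' @export
#' @examples
#' fib <- makeFibril(fixtureSpec())
#' length(chains(fib))  # 5 layers x 2 protofilaments = 10
makeFibril <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  p <- spec@params
  ch <- .buildChain(.fixtureSequence(p), resStart = p$resStart)
  # align the strand axis with +x, centre y/z, start at the cleft edge
  ca <- as.matrix(ch[ch$name == "CA", c("x", "y", "z")])
  xyz <- as.matrix(ch[, c("x", "y", "z")])
  sv <- svd(sweep(ca, 2, colMeans(ca)))
  ax <- sv$v[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  R <- .kabsch(rbind(colMeans(ca), colMeans(ca) + ax),
               rbind(c(0, 0, 0), c(1, 0, 0)))$R
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, c(min(xyz[, 1]) - 2.5, mean(xyz[, 2]), mean(xyz[, 3])))
  ch$x <- xyz[, 1]; ch$y <- xyz[, 2]; ch$z <- xyz[, 3]
  ch$chain <- "A"
  layerAtoms <- ch
  proto <- c(A = "A")
  if (p$protofilaments == 2L) {
    chB <- ch
    chB$x <- -ch$x; chB$y <- -ch$y  # C2 about the fibril (z) axis
    chB$chain <- "B"
    layerAtoms <- rbind(ch, chB)
    proto <- c(A = "A", B = "B")
  }
  layer <- fibrilStructure(layerAtoms,
                           layers = stats::setNames(rep(0L, length(proto)),
                                                    names(proto)),
                           protofilaments = proto, axis = c(0, 0, 1))
  expandHelical(layer, helicalSymmetry(p$rise, p$twist), p$nLayers)
}

# Template coordinates of the planar tri-ring mock ligand: three hexagonal
# carbon rings (fibril-facing D analog, middle C analog, solvent-facing A
# analog) in the x-y plane, stacked along z, plus exocyclic hydroxyl oxygens
# (two on ring D pointing at the C2-related protofilaments, one each on
# rings C and A) so the ligand engages polar contacts like a polyphenol.
.mockLigandTemplate <- function() {
  ring <- function(tag, cy) {
    th <- (seq_len(6) - 1) * pi / 3
    data.frame(name = sprintf("C%d%s", seq_len(6), tag), element = "C",
               x = 1.39 * cos(th), y = cy + 1.39 * sin(th), z = 0,
               ring = tag, stringsAsFactors = FALSE)
  }
  oh <- function(name, tag, cy, angleDeg) {
    th <- angleDeg * pi / 180
    data.frame(name = name, element = "O",
               x = 2.75 * cos(th), y = cy + 2.75 * sin(th), z = 0,
               ring = tag, stringsAsFactors = FALSE)
  }
  rbind(ring("D", 0), oh("O1D", "D", 0, 0), oh("O2D", "D", 0, 180),
        ring("C", 2.8), oh("O1C", "C", 2.8, 60),
        ring("A", 5.6), oh("O1A", "A", 5.6, 90))
}

#' Ring definitions of the mock ligand
#'
#' @return named list of atom-name vectors (rings A, C, D), for use with
#'   \code{\link{stackingMetrics}}.
#' @export
mockLigandRings <- function() {
  tpl <- .mockLigandTemplate()
  split(tpl$name, tpl$ring)[c("A", "C", "D")]
}

#' Add a mock-ligand column in the inter-protofilament cleft
#'
#' Places \code{ligandCount} copies of a rigid planar tri-ring mock ligand
#' stacked along the fibril axis, starting in the plane of layer 0. With
#' \code{ligandCompression} set, copies are placed on a circular arc whose
#' centre lies beyond the solvent-facing ring, compressing the solvent-face
#' edge separation to the requested value and widening the fibril-face
#' separation (the curved-stack signature); the per-copy plane tilt follows
#' from the arc. Without it the stack is a pure translation.
#'
#' @param x a \code{FibrilStructure} from \code{\link{makeFibril}}.
#' @param spec the same \code{\link{fixtureSpec}}.
#' @return \code{x} with ligand atoms appended (one ligand chain, one residue
#'   number per copy, residue name "LIG").
#' @export
makeLigandColumn <- function(x, spec) {
  stopifnot(is(x, "FibrilStructure"), is(spec, "FixtureSpec"))
  p <- spec@params
  if (p$ligandCount < 1) stop("spec has ligandCount < 1")
  if (p$ligandCount > p$nLayers) stop("ligandCount must be <= nLayers")
  tpl <- .mockLigandTemplate()
  tpl$x <- tpl$x + p$ligandAnchor[1]
  tpl$y <- tpl$y + p$ligandAnchor[2]
  tpl$z <- tpl$z + p$ligandAnchor[3]
  s <- p$ligandSpacing
  copies <- vector("list", p$ligandCount)
  if (is.null(p$ligandCompression)) {
    for (i in seq_len(p$ligandCount) - 1L) {
      ci <- tpl
      ci$z <- ci$z + i * s
      ci$resno <- i + 1L
      copies[[i + 1]] <- ci
    }
  } else {
    cmp <- p$ligandCompression
    if (cmp <= 0 || cmp >= s)
      stop("ligandCompression must be in (0, spacing)")
    yMax <- max(tpl$y)
    yCen <- mean(tpl$y)
    y0 <- (s * yMax - cmp * yCen) / (s - cmp)  # arc centre, beyond solvent edge
    dphi <- s / (y0 - yCen)                     # radians per copy
    for (i in seq_len(p$ligandCount) - 1L) {
      th <- i * dphi
      ci <- tpl
      r <- y0 - tpl$y
      ci$y <- y0 - r * cos(th)
      ci$z <- p$ligandAnchor[3] + r * sin(th)
      ci$resno <- i + 1L
      copies[[i + 1]] <- ci
    }
  }
  lig <- do.call(rbind, copies)
  ligChain <- setdiff(rev(.chainAlphabet), chains(x))[1]
  lig <- data.frame(name = lig$name, element = lig$element, resname = "LIG",
                    resno = lig$resno, chain = ligChain,
                    x = lig$x, y = lig$y, z = lig$z,
                    stringsAsFactors = FALSE)
  all <- rbind(x@atoms[, c("name", "element", "resname", "resno", "chain",
                           "x", "y", "z")], lig)
  fibrilStructure(all, layers = x@layers,
                  protofilaments = x@protofilaments, axis = x@axis)
}

#' Hinge a fibril fixture: displace selected residues of the top layer
#'
#' Translates the atoms of \code{residues} in the highest layer by
#' \code{shift} Angstrom along the fibril axis, emulating local inter-layer
#' separation (e.g. +4.2 on residues 340-343 turns a 4.8 Angstrom spacing
#' into ~9 Angstrom at those residues only).
#'
#' @param x a \code{FibrilStructure} with layers assigned.
#' @param residues residue numbers to displace.
#' @param shift axial displacement, Angstrom.
#' @param layer layer index to displace (default: the top layer).
#' @return the hinged \code{FibrilStructure}.
#' @export
applyHinge <- function(x, residues = 340:343, shift = 4.2, layer = NULL) {
  if (!length(x@layers)) stop("layers must be assigned")
  if (is.null(layer)) layer <- max(x@layers)
  chainsHit <- names(x@layers)[x@layers == layer]
  idx <- atomSelect(x, chain = chainsHit, resno = residues, ligand = FALSE)
  if (!length(idx)) stop("no atoms in the requested layer/residues")
  d <- shift * x@axis
  x@atoms$x[idx] <- x@atoms$x[idx] + d[1]
  x@atoms$y[idx] <- x@atoms$y[idx] + d[2]
  x@atoms$z[idx] <- x@atoms$z[idx] + d[3]
  x
}

#' Synthetic docking-score table with planted strong binders
#'
#' Generates a compound x engine score table in which background compounds are
#' drawn from a truncated normal (|z| < 1.8 before planting) so that the
#' planted strong binders (placed at \code{strongZ} engine standard deviations
#' below the engine mean) are unambiguous ground-truth hits for any seed. A
#' positive-control compound ("EGCG", library tag "control") is placed 2.5 sd
#' below the mean in every engine.
#'
#' @param nCompounds background library size (default 100).
#' @param nStrong planted strong binders (default 5).
#' @param strongZ planted depth in pre-planting sd units (default -3).
#' @param engines named list of engine score scales:
#'   \code{list(engine = c(mean, sd))}.
#' @param seed integer seed.
#' @return data.frame with columns compound, library, engine, score
#'   (lower = stronger binding, both engines).
#' @export
#' @examples
#' head(makeScreenScores(seed = 7))
makeScreenScores <- function(nCompounds = 100L, nStrong = 5L, strongZ = -3,
                             engines = list(vina = c(-6, 1),
                                            rosetta = c(-10, 2)),
                             seed = 1L) {
  stopifnot(nStrong < nCompounds)
  ids <- sprintf("CNS-%03d", seq_len(nCompounds))
  strongIds <- sprintf("HIT-%02d", seq_len(nStrong))
  withr::with_seed(as.integer(seed), {
    out <- lapply(names(engines), function(eng) {
      mu <- engines[[eng]][1]; sd <- engines[[eng]][2]
      lim <- stats::pnorm(c(-1.8, 1.8))
      zBg <- stats::qnorm(stats::runif(nCompounds, lim[1], lim[2]))
      data.frame(
        compound = c(ids, strongIds, "EGCG"),
        library = c(rep("cns-set", nCompounds), rep("planted", nStrong),
                    "control"),
        engine = eng,
        score = c(mu + sd * zBg, rep(mu + sd * strongZ, nStrong),
                  mu - 2.5 * sd),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
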