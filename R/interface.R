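#' Buried surface area of a ligand-receptor complex
#'
#' SASA lost on complex formation, by the Shrake-Rupley engine with settings
#' inherited from \code{\link{computeSasa}}. Receptor side (the default,
#' matching "area buried on the fibril surface"): SASA of the receptor alone
#' minus receptor SASA in the complex. Ligand side: the analogous quantity
#' for the ligand selection. Average: the mean of both. When several ligand
#' copies are present, pass one copy as \code{ligandSel}; the remaining
#' copies count as receptor, so the value is per single ligand buried by the
#' fibril and its axial ligand neighbours.
#'
#' @param x the complex, a \code{FibrilStructure}.
#' @param ligandSel atom indices of the ligand copy.
#' @param side "receptor" (default), "ligand" or "average".
#' @param probe,nPoints SASA settings.
#' @return buried area, Angstrom^2.
#' @export
buriedArea <- function(x, ligandSel, side = c("receptor", "ligand", "average"),
                       probe = 1.4, nPoints = 960L) {
  side <- match.arg(side)
  if (!length(ligandSel)) stop("empty ligand selection")
  a <- x@atoms
  recSel <- setdiff(seq_len(nrow(a)), ligandSel)
  if (!length(recSel)) stop("ligand selection covers the whole structure")
  lig <- fibrilStructure(a[ligandSel, ])
  rec <- fibrilStructure(a[recSel, ])
  # restrict to atoms near the interface; distant atoms cancel exactly
  cut <- 2 * (max(a$vdw) + probe)
  lxyz <- as.matrix(a[ligandSel, c("x", "y", "z")])
  near <- function(sel) {
    xyz <- as.matrix(a[sel, c("x", "y", "z")])
    keep <- vapply(seq_len(nrow(xyz)), function(i) {
      min(sqrt(colSums((t(lxyz) - xyz[i, ])^2))) < cut + 10
    }, logical(1))
    sel[keep]
  }
  recSide <- function() {
    sub <- near(recSel)
    if (!length(sub)) return(0)
    alone <- computeSasa(rec, subset = match(sub, recSel), probe = probe,
                         nPoints = nPoints)
    inCpx <- computeSasa(x, subset = sub, probe = probe, nPoints = nPoints)
    sum(alone@area) - sum(inCpx@area)
  }
  ligSide <- function() {
    alone <- computeSasa(lig, probe = probe, nPoints = nPoints)
    inCpx <- computeSasa(x, subset = ligandSel[
      toupper(a$element[ligandSel]) != "H"], probe = probe,
      nPoints = nPoints)
    sum(alone@area) - sum(inCpx@area)
  }
  switch(side,
         receptor = recSide(),
         ligand = ligSide(),
         average = (recSide() + ligSide()) / 2)
}

#' Find hydrogen bonds between two selections
#'
#' Heavy-atom geometric criterion: N/O donor-acceptor pairs across the two
#' selections, in different residues, within \code{distCut}. When explicit
#' hydrogens bonded to the donor are present (within 1.25 Angstrom), the
#' D-H...A angle must also reach \code{angCut}; deposited heavy-atom models
#' carry no hydrogens and are assessed on distance alone. Donor/acceptor
#' roles are evaluated both ways, so the result is symmetric in
#' \code{sel1}/\code{sel2}.
#'
#' @param x a \code{FibrilStructure}.
#' @param sel1,sel2 disjoint atom index vectors.
#' @param distCut heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angCut D-H...A angle cutoff, degrees (default 120; applied only
#'   when hydrogens exist).
#' @return data.frame: donor/acceptor atom descriptors, distance, angle
#'   (NA without hydrogens) and partner residue labels; zero rows when no
#'   bonds are found.
#' @export
findHBonds <- function(x, sel1, sel2, distCut = 3.5, angCut = 120) {
  if (length(intersect(sel1, sel2))) stop("selections must be disjoint")
  a <- x@atoms
  polar <- function(sel) sel[toupper(a$element[sel]) %in% c("N", "O")]
  s1 <- polar(sel1); s2 <- polar(sel2)
  empty <- data.frame(donor = character(0), acceptor = character(0),
                      distance = numeric(0), angle = numeric(0),
                      donorResidue = character(0),
                      acceptorResidue = character(0),
                      stringsAsFactors = FALSE)
  if (!length(s1) || !length(s2)) return(empty)
  hIdx <- which(toupper(a$element) == "H")
  hxyz <- as.matrix(a[hIdx, c("x", "y", "z")])
  lab <- function(i) paste0(a$resname[i], a$resno[i], ":", a$name[i],
                            "/", a$chain[i])
  resLab <- function(i) paste0(a$resname[i], a$resno[i], "/", a$chain[i])
  rows <- list()
  for (i in s1) {
    posI <- c(a$x[i], a$y[i], a$z[i])
    for (j in s2) {
      if (a$resno[i] == a$resno[j] && a$chain[i] == a$chain[j]) next
      posJ <- c(a$x[j], a$y[j], a$z[j])
      d <- sqrt(sum((posI - posJ)^2))
      if (d > distCut) next
      # angle check for whichever direction has an explicit H on the donor
      ang <- NA_real_
      ok <- TRUE
      if (length(hIdx)) {
        angleFor <- function(don, acc) {
          dp <- c(a$x[don], a$y[don], a$z[don])
          hd <- sqrt(colSums((t(hxyz) - dp)^2))
          hs <- which(hd < 1.25)
          if (!length(hs)) return(NA_real_)
          ap <- c(a$x[acc], a$y[acc], a$z[acc])
          max(vapply(hs, function(h) {
            hp <- hxyz[h, ]
            v1 <- dp - hp; v2 <- ap - hp
            acos(pmin(1, pmax(-1, sum(v1 * v2) /
              (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
          }, numeric(1)))
        }
        a12 <- angleFor(i, j)
        a21 <- angleFor(j, i)
        cand <- c(a12, a21)
        if (all(is.na(cand))) ok <- TRUE
        else {
          ang <- max(cand, na.rm = TRUE)
          ok <- ang >= angCut
        }
      }
      if (!ok) next
      rows[[length(rows) + 1]] <- data.frame(
        donor = lab(i), acceptor = lab(j), distance = d, angle = ang,
        donorResidue = resLab(i), acceptorResidue = resLab(j),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Ring-stacking profile of a ligand column
#'
#' Orders the ligand copies along the fibril axis and reports, for each
#' adjacent pair: the all-atom centroid separation, the tilt between the
#' least-squares ring planes, and, per named ring, the separation of the
#' solvent-facing versus fibril-facing ring edges. Edge atoms are identified
#' by their projection onto the solvent direction (from the fibril axis
#' towards the ligand-column centroid, perpendicular to the axis), with a
#' name-ordered tie-break so the choice is frame-independent; separations are
#' measured between same-named atoms of the two copies. A curved stack shows
#' the signature solvent-face < fibril-face.
#'
#' @param x a \code{FibrilStructure} whose ligand atoms form >= 2 copies
#'   (distinct ligand residue numbers within a chain).
#' @param rings named list of atom-name vectors (default
#'   \code{\link{mockLigandRings}}; see \code{\link{ringDefinitions}} for
#'   real components).
#' @return data.frame with one row per (adjacent pair, ring): \code{pair},
#'   \code{ring}, \code{centroidSep}, \code{tilt} (degrees, in [0, 90]),
#'   \code{solventSep}, \code{fibrilSep} (Angstrom).
#' @export
stackingMetrics <- function(x, rings = mockLigandRings()) {
  lidx <- which(x@atoms$ligand)
  if (!length(lidx)) stop("no ligand atoms")
  a <- x@atoms[lidx, ]
  copyKey <- paste(a$chain, a$resno)
  copies <- unique(copyKey)
  if (length(copies) < 2)
    stop("need >= 2 ligand copies to profile a stack")
  axis <- x@axis
  axPos <- vapply(copies, function(k) {
    mean(as.matrix(a[copyKey == k, c("x", "y", "z")]) %*% axis)
  }, numeric(1))
  copies <- copies[order(axPos)]
  xyzOf <- function(k, names = NULL) {
    sub <- a[copyKey == k & (is.null(names) | a$name %in% names), ,
             drop = FALSE]
    as.matrix(sub[, c("x", "y", "z")])
  }
  # solvent direction: from the axis towards the ligand-column centroid,
  # perpendicular to the axis (well-defined for a cleft-bound column)
  cenAll <- colMeans(as.matrix(a[, c("x", "y", "z")]))
  sd0 <- cenAll - sum(cenAll * axis) * axis
  if (sqrt(sum(sd0^2)) < 1e-6)
    stop("cannot define a solvent direction: ligand column centred on the axis")
  solvDir <- sd0 / sqrt(sum(sd0^2))
  rows <- list()
  for (i in seq_len(length(copies) - 1)) {
    k1 <- copies[i]; k2 <- copies[i + 1]
    x1 <- xyzOf(k1); x2 <- xyzOf(k2)
    cenSep <- sqrt(sum((colMeans(x1) - colMeans(x2))^2))
    n1 <- .planeNormal(x1); n2 <- .planeNormal(x2)
    tilt <- acos(pmin(1, abs(sum(n1 * n2)))) * 180 / pi
    for (rg in names(rings)) {
      nm <- rings[[rg]]
      s1 <- a[copyKey == k1 & a$name %in% nm, , drop = FALSE]
      s2 <- a[copyKey == k2 & a$name %in% nm, , drop = FALSE]
      if (!nrow(s1) || !nrow(s2)) next
      proj <- vapply(seq_len(nrow(s1)), function(q)
        sum(c(s1$x[q], s1$y[q], s1$z[q]) * solvDir), numeric(1))
      # name-ordered tie-break keeps the choice frame-independent
      pick <- function(p) {
        cand <- s1$name[abs(p - max(p)) < 1e-6]
        sort(cand)[1]
      }
      solvAtom <- pick(proj)
      fibAtom <- pick(-proj)
      sep <- function(nmAt) {
        p1 <- s1[s1$name == nmAt, c("x", "y", "z")]
        p2 <- s2[s2$name == nmAt, c("x", "y", "z")]
        sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
      }
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste(k1, k2, sep = " - "), ring = rg,
        centroidSep = cenSep, tilt = tilt,
        solventSep = sep(solvAtom), fibrilSep = sep(fibAtom),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("ring definitions match no ligand atoms")
  do.call(rbind, rows)
}

#' Ring definitions from a data file
#'
#' Reads a TSV with columns \code{ring}, \code{atom} into the named-list form
#' \code{\link{stackingMetrics}} expects. The shipped
#' \code{egcg_rings_synthetic.tsv} carries a generic flavan-3-ol gallate
#' (EGCG-like) naming convention -- verify atom names against the chemical
#' component of your model and override as needed.
#'
#' @param path TSV path; default: the shipped EGCG-like convention file.
#' @return named list of atom-name vectors.
#' @export
ringDefinitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "egcg_rings_synthetic.tsv",
                        package = "fibrilstab")
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  split(tb$atom, tb$ring)
}

# Heavy-atom clash count: pairs across selections closer than
# 0.6 x (sum of vdW radii).
.clashCount <- function(x, sel1, sel2) {
  a <- x@atoms
  x1 <- as.matrix(a[sel1, c("x", "y", "z")])
  x2 <- as.matrix(a[sel2, c("x", "y", "z")])
  n <- 0L
  for (i in seq_along(sel1)) {
    d <- sqrt(colSums((t(x2) - x1[i, ])^2))
    lim <- 0.6 * (a$vdw[sel1[i]] + a$vdw[sel2])
    n <- n + sum(d < lim)
  }
  n
}

# Simplified surface-complementarity score: the fraction of the ligand's
# exposed vdW-surface points whose gap to the receptor vdW surface lies in
# [0, band] Angstrom. A documented stand-in, not the Lawrence-Colman Sc.
.complementarity <- function(x, ligandSel, band = 1.0, nPoints = 240L) {
  a <- x@atoms
  recSel <- setdiff(seq_len(nrow(a)), ligandSel)
  pts <- .spherePoints(as.integer(nPoints))
  lxyz <- as.matrix(a[ligandSel, c("x", "y", "z")])
  rxyz <- as.matrix(a[recSel, c("x", "y", "z")])
  rv <- a$vdw[recSel]
  good <- 0L; tot <- 0L
  for (i in seq_along(ligandSel)) {
    ri <- a$vdw[ligandSel[i]]
    sp <- sweep(pts * ri, 2, lxyz[i, ], "+")
    # keep points on the ligand's own exposed surface
    keep <- rep(TRUE, nrow(sp))
    for (j in seq_along(ligandSel)) {
      if (j == i) next
      keep <- keep & (colSums((t(sp) - lxyz[j, ])^2) >
                        a$vdw[ligandSel[j]]^2)
    }
    sp <- sp[keep, , drop = FALSE]
    if (!nrow(sp)) next
    gap <- vapply(seq_len(nrow(sp)), function(q) {
      min(sqrt(colSums((t(rxyz) - sp[q, ])^2)) - rv)
    }, numeric(1))
    good <- good + sum(gap >= 0 & gap <= band)
    tot <- tot + nrow(sp)
  }
  if (!tot) return(0)
  good / tot
}

#' Compare candidate ligand poses
#'
#' Scores each pose of a shared receptor by masked real-space correlation
#' (when a map is supplied), receptor-side buried area, hydrogen-bond count,
#' heavy-atom clash count (pairs closer than 0.6 x radius sum) and a
#' simplified surface-complementarity fraction, then ranks them
#' lexicographically: cc (desc, if available), buried area (desc), H-bonds
#' (desc), clashes (asc), complementarity (desc). The rule is recorded in the
#' \code{rankingRule} attribute of the result.
#'
#' @param poses list of \code{FibrilStructure} complexes differing only in
#'   their ligand atoms.
#' @param grid optional observed \code{\link{DensityGrid}}.
#' @param mask \code{\link{VoxelMask}} for the correlation (required with
#'   \code{grid}).
#' @param resolution simulation resolution for the correlation, Angstrom.
#' @param probe,nPoints SASA settings.
#' @return data.frame, one row per pose, ranked best-first.
#' @export
poseReport <- function(poses, grid = NULL, mask = NULL, resolution = 3.8,
                       probe = 1.4, nPoints = 960L) {
  if (length(poses) < 2) stop("need >= 2 poses")
  ligSels <- lapply(poses, function(p) which(p@atoms$ligand))
  recOf <- function(p) p@atoms[!p@atoms$ligand,
                               c("name", "resno", "chain", "x", "y", "z")]
  rec0 <- recOf(poses[[1]])
  for (p in poses[-1]) {
    if (!isTRUE(all.equal(recOf(p), rec0, tolerance = 1e-6,
                          check.attributes = FALSE)))
      stop("poses do not share the receptor")
  }
  useCC <- !is.null(grid)
  if (useCC && is.null(mask)) stop("a mask is required with a map")
  rows <- lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    ls <- ligSels[[i]]
    rs <- setdiff(seq_len(nrow(p@atoms)), ls)
    data.frame(
      pose = if (!is.null(names(poses))) names(poses)[i]
             else paste0("pose", i),
      cc = if (useCC) {
        # a pose with no density in the mask is a worst-case fit, not an error
        tryCatch(realSpaceCC(p, grid, mask, resolution, subset = ls),
                 error = function(e) NA_real_)
      } else NA_real_,
      buriedArea = buriedArea(p, ls, side = "receptor", probe = probe,
                              nPoints = nPoints),
      hbonds = nrow(findHBonds(p, ls, rs)),
      clashes = .clashCount(p, ls, rs),
      complementarity = .complementarity(p, ls),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(if (useCC) -out$cc else rep(0, nrow(out)),
               -out$buriedArea, -out$hbonds, out$clashes,
               -out$complementarity)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "rankingRule") <-
    "lexicographic: cc desc (if map), buriedArea desc, hbonds desc, clashes asc, complementarity desc"
  out
}
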