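# Pool of deterministic single-character chain IDs used when minting chains.
.chainAlphabet <- c(LETTERS, letters, 0:9)

#' Expand one fibril layer by helical symmetry
#'
#' Generates \code{nLayers} copies of a single-layer template: layer k equals
#' layer 0 rotated by \code{k * twist} degrees about the fibril axis (a line
#' through the origin along \code{fibrilAxis(x)}) and translated by
#' \code{k * rise} along it. New chain IDs are minted deterministically in
#' layer-major order from a fixed alphabet, so expansion is reproducible.
#' Ligand atoms, if present in the template, are expanded with their layer.
#'
#' @param x a \code{FibrilStructure} containing exactly one layer.
#' @param sym a \code{\link{helicalSymmetry}} operator.
#' @param nLayers integer >= 1.
#' @return a \code{FibrilStructure} with \code{nLayers} x (chains per layer)
#'   chains, layers and protofilament labels propagated.
#' @export
#' @examples
#' layer <- makeFibril(fixtureSpec(nLayers = 1))
#' fib <- expandHelical(layer, helicalSymmetry(4.8, -1.2), 5)
#' length(chains(fib))
expandHelical <- function(x, sym, nLayers) {
  stopifnot(is(x, "FibrilStructure"), is(sym, "HelicalSymmetry"))
  if (length(nLayers) != 1 || is.na(nLayers) || nLayers < 1)
    stop("nLayers must be an integer >= 1")
  nLayers <- as.integer(nLayers)
  if (length(x@layers) && length(unique(x@layers)) > 1)
    stop("expandHelical requires a single-layer template")
  baseChains <- chains(x)
  nPer <- length(baseChains)
  if (nLayers * nPer > length(.chainAlphabet))
    stop("too many chains to mint unique single-character IDs")
  if (nLayers == 1) {
    out <- x
    if (!length(out@layers)) {
      out@layers <- stats::setNames(rep(0L, length(proteinChains(x))),
                                    proteinChains(x))
    }
    return(out)
  }
  axis <- .unit(x@axis)
  xyz0 <- coords(x)
  pieces <- vector("list", nLayers)
  layerOf <- character(0)
  protoOf <- character(0)
  baseProto <- x@protofilaments
  layersOut <- integer(0)
  for (k in seq_len(nLayers) - 1L) {
    R <- .rotationMatrix(axis, k * sym@twist)
    xyz <- xyz0 %*% t(R) + matrix(k * sym@rise * axis, nrow(xyz0), 3,
                                  byrow = TRUE)
    a <- x@atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    newID <- .chainAlphabet[k * nPer + seq_len(nPer)]
    names(newID) <- baseChains
    a$chain <- unname(newID[a$chain])
    pieces[[k + 1]] <- a
    pc <- baseChains[baseChains %in% proteinChains(x)]
    layersOut <- c(layersOut,
                   stats::setNames(rep(k, length(pc)), unname(newID[pc])))
    if (length(baseProto))
      protoOf <- c(protoOf, stats::setNames(unname(baseProto[pc]),
                                            unname(newID[pc])))
  }
  a <- do.call(rbind, pieces)
  a$serial <- seq_len(nrow(a))
  new("FibrilStructure", atoms = a, layers = layersOut,
      protofilaments = protoOf, axis = axis)
}

#' Assign layer indices (and protofilament labels) to chains
#'
#' Estimates the fibril axis as the principal axis of the chain centroids when
#' not supplied, projects each protein chain's centroid onto it, and clusters
#' the axial positions into consecutive integer layer indices (0-based, from
#' the axis-minimal layer). Within layers, protofilament labels are propagated
#' greedily layer-to-layer by matching each chain to the angularly nearest
#' chain of the previous layer, which tolerates small per-layer twist.
#'
#' @param x a \code{FibrilStructure} with >= 1 protein chain.
#' @param axis optional numeric(3) axis direction; estimated when NULL.
#' @param gap axial gap (Angstrom) above which two chains belong to different
#'   layers; default 1.0 (cross-beta rises are >= ~2.4 Angstrom).
#' @return \code{x} with \code{layers} and \code{protofilaments} filled and
#'   \code{axis} updated.
#' @export
assignLayers <- function(x, axis = NULL, gap = 1.0) {
  pc <- proteinChains(x)
  if (!length(pc)) stop("no protein chains to assign")
  cen <- t(vapply(pc, function(ch) {
    idx <- atomSelect(x, chain = ch)
    colMeans(coords(x)[idx, , drop = FALSE])
  }, numeric(3)))
  if (is.null(axis)) {
    # candidate directions: the stored axis plus the principal directions of
    # the chain centroids; keep the candidate that separates the most layers
    # (the inter-protofilament direction clusters chains into few groups)
    cand <- list(x@axis)
    if (length(pc) >= 3) {
      sv <- svd(sweep(cen, 2, colMeans(cen)))
      for (k in 1:3) cand <- c(cand, list(sv$v[, k]))
    } else if (length(pc) == 2) {
      d <- cen[2, ] - cen[1, ]
      if (sqrt(sum(d^2)) > 1e-9) cand <- c(cand, list(.unit(d)))
    }
    # chains lie in the layer plane, so the fibril axis is the direction
    # that minimizes the chains' own axial extents
    xyzAll <- coords(x)
    chainIdx <- lapply(pc, function(ch) atomSelect(x, chain = ch))
    ext <- vapply(cand, function(ax) {
      max(vapply(chainIdx, function(ii) {
        pr <- xyzAll[ii, , drop = FALSE] %*% ax
        diff(range(pr))
      }, numeric(1)))
    }, numeric(1))
    axis <- cand[[which.min(ext)]]
    if (sum(axis * x@axis) < 0) axis <- -axis
  } else axis <- .unit(axis)
  proj <- as.numeric(cen %*% axis)
  ord <- order(proj)
  lay <- integer(length(pc))
  lev <- 0L
  for (i in seq_along(ord)[-1]) {
    if (proj[ord[i]] - proj[ord[i - 1]] > gap) lev <- lev + 1L
    lay[ord[i]] <- lev
  }
  names(lay) <- pc
  # ambiguity check: a chain's own axial extent must not span >1.5 rise
  if (max(lay) >= 1) {
    layerPos <- tapply(proj, lay, mean)
    rise <- stats::median(diff(sort(layerPos)))
    for (ch in pc) {
      # register along the axis is a backbone property; side chains may
      # legitimately extend towards neighbouring layers
      idx <- atomSelect(x, chain = ch, backbone = TRUE)
      if (!length(idx)) idx <- atomSelect(x, chain = ch)
      ext <- range(coords(x)[idx, , drop = FALSE] %*% axis)
      if (diff(ext) > 1.5 * rise)
        stop("chain ", ch, " spans more than 1.5 layer rises along the axis; ",
             "layer assignment is ambiguous")
    }
  }
  # protofilament labels: match chains across layers by azimuth
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  perp <- function(v) v - sum(v * axis) * axis
  ang <- vapply(seq_along(pc), function(i) {
    p <- perp(cen[i, ])
    atan2(sum(p * e2), sum(p * e1))
  }, numeric(1))
  proto <- character(length(pc))
  l0 <- which(lay == 0L)
  proto[l0[order(ang[l0])]] <- .chainAlphabet[seq_along(l0)]
  if (max(lay) >= 1) {
    for (k in seq_len(max(lay))) {
      prev <- which(lay == k - 1L)
      cur <- which(lay == k)
      for (i in cur) {
        dd <- abs(atan2(sin(ang[i] - ang[prev]), cos(ang[i] - ang[prev])))
        proto[i] <- proto[prev[which.min(dd)]]
      }
    }
  }
  names(proto) <- pc
  x@layers <- lay
  x@protofilaments <- proto
  x@axis <- axis
  x
}
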