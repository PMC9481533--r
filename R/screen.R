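#' Docking site box derived from a bound ligand
#'
#' Emits the search-box parameters a docking engine needs, centred on the
#' bound-ligand centroid. With an explicit \code{padding}, the extents are the
#' ligand bounding box plus 2 x padding per axis; otherwise the shipped
#' defaults are used: a 20 x 16 x 12 Angstrom box ("vina"-style engines) or a
#' 7 Angstrom edge ("rosetta"-style engines).
#'
#' @param x a \code{FibrilStructure}.
#' @param ligandSel non-empty atom index vector of the bound ligand.
#' @param engine "vina" or "rosetta".
#' @param padding optional Angstrom padding (>= 0) activating the
#'   bounding-box rule.
#' @param extents default vina box extents, Angstrom.
#' @param edge default rosetta box edge, Angstrom.
#' @return list: \code{engine}, \code{center} (numeric(3)), and either
#'   \code{extents} (numeric(3)) or \code{edge}.
#' @export
#' @examples
#' sp <- fixtureSpec(ligandCount = 1)
#' cpx <- makeLigandColumn(makeFibril(sp), sp)
#' siteBoxFromLigand(cpx, atomSelect(cpx, ligand = TRUE))$extents
siteBoxFromLigand <- function(x, ligandSel, engine = c("vina", "rosetta"),
                              padding = NULL, extents = c(20, 16, 12),
                              edge = 7) {
  engine <- match.arg(engine)
  if (!length(ligandSel)) stop("empty ligand selection")
  xyz <- coords(x)[ligandSel, , drop = FALSE]
  center <- colMeans(xyz)
  if (!is.null(padding)) {
    if (padding < 0) stop("padding must be >= 0")
    ext <- apply(xyz, 2, function(v) diff(range(v))) + 2 * padding
  } else ext <- extents
  if (any(ext <= 0)) stop("box extents must be > 0")
  if (engine == "vina")
    list(engine = engine, center = unname(center), extents = unname(ext))
  else
    list(engine = engine, center = unname(center),
         edge = if (!is.null(padding)) max(ext) else edge)
}

#' Write an engine-specific docking configuration file
#'
#' @param box output of \code{\link{siteBoxFromLigand}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeDockingConfig <- function(box, path) {
  lines <- if (box$engine == "vina") {
    c(sprintf("center_x = %.3f", box$center[1]),
      sprintf("center_y = %.3f", box$center[2]),
      sprintf("center_z = %.3f", box$center[3]),
      sprintf("size_x = %.3f", box$extents[1]),
      sprintf("size_y = %.3f", box$extents[2]),
      sprintf("size_z = %.3f", box$extents[3]))
  } else {
    c("-parser:script_vars",
      sprintf("  grid_center=%.3f,%.3f,%.3f", box$center[1], box$center[2],
              box$center[3]),
      sprintf("  box_edge=%.3f", box$edge))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-engine z-scores and consensus ranking of a docking-score table
#'
#' Standardizes scores within each engine (z = (score - mean) / sd; lower =
#' stronger binding for every engine), averages the available engine z-scores
#' per compound into a consensus z, and ranks compounds ascending by
#' consensus (most negative first), breaking ties lexicographically by
#' compound ID.
#'
#' @param scores data.frame with columns \code{compound}, \code{engine},
#'   \code{score} (optionally \code{library}).
#' @return the input with added \code{z}, plus \code{consensusZ} and
#'   \code{rank} columns (consensus values repeated across a compound's
#'   rows).
#' @export
#' @examples
#' zscoreRank(makeScreenScores(seed = 3))[1:3, ]
zscoreRank <- function(scores) {
  need <- c("compound", "engine", "score")
  if (!all(need %in% names(scores)))
    stop("scores needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(scores[, c("compound", "engine")]))
    stop("more than one score per (compound, engine)")
  scores$z <- NA_real_
  for (eng in unique(scores$engine)) {
    i <- scores$engine == eng
    if (sum(i) < 3)
      stop("engine ", eng, " has fewer than 3 scores; cannot standardize")
    s <- stats::sd(scores$score[i])
    if (s < 1e-12)
      stop("degenerate score distribution (zero sd) for engine ", eng)
    scores$z[i] <- (scores$score[i] - mean(scores$score[i])) / s
  }
  cons <- stats::aggregate(z ~ compound, data = scores, FUN = mean)
  names(cons)[2] <- "consensusZ"
  cons <- cons[order(cons$consensusZ, cons$compound), ]
  cons$rank <- seq_len(nrow(cons))
  m <- match(scores$compound, cons$compound)
  scores$consensusZ <- cons$consensusZ[m]
  scores$rank <- cons$rank[m]
  scores
}

#' Select screening hits by consensus z-score
#'
#' @param table output of \code{\link{zscoreRank}}.
#' @param zThreshold keep compounds with consensus z <= this (default -2,
#'   i.e. binding predicted > 2 standard deviations stronger than the
#'   average compound).
#' @param topN truncate to the best \code{topN} compounds (default Inf).
#' @return one row per selected compound: \code{compound}, \code{library}
#'   (if present), \code{consensusZ}, \code{rank}, and \code{isControl}
#'   flagging control-library compounds.
#' @export
selectHits <- function(table, zThreshold = -2, topN = Inf) {
  if (!"consensusZ" %in% names(table))
    stop("table must come from zscoreRank()")
  keep <- c("compound", intersect("library", names(table)),
            "consensusZ", "rank")
  one <- unique(table[, keep])
  one <- one[order(one$rank), ]
  hits <- one[one$consensusZ <= zThreshold, , drop = FALSE]
  if (nrow(hits) > topN) hits <- hits[seq_len(topN), , drop = FALSE]
  hits$isControl <- if ("library" %in% names(hits))
    hits$library == "control" else FALSE
  rownames(hits) <- NULL
  hits
}
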