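#' Atomic solvation parameter table
#'
#' Loads an atom-class -> ASP table (cal/mol/A^2). The shipped default is the
#' Eisenberg-McLachlan five-class scale (carbon, neutral N/O, charged O-,
#' charged N+, sulfur). The file basename is stamped into every result's
#' metadata as the table identity.
#'
#' @param path TSV with columns \code{class}, \code{asp}; default: the
#'   shipped table.
#' @return data.frame with attribute \code{id}.
#' @export
#' @examples
#' aspTable()
aspTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "asp_eisenberg_mclachlan.tsv",
                        package = "fibrilstab")
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("class", "asp") %in% names(tb)))
  if (anyDuplicated(tb$class)) stop("duplicate atom classes in ASP table")
  attr(tb, "id") <- basename(path)
  tb
}

#' Residue ordering-entropy table
#'
#' Per-residue entropy penalty (kcal/mol, >= 0) added to each scored residue.
#' Set \code{enabled = FALSE} in \code{\link{stabilityMap}} to isolate the
#' surface-area term.
#'
#' @param path TSV with columns \code{residue}, \code{penalty}; default: the
#'   shipped table.
#' @return data.frame with attribute \code{id}.
#' @export
entropyTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residue_entropy.tsv",
                        package = "fibrilstab")
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "penalty") %in% names(tb)))
  if (any(tb$penalty < 0)) stop("entropy penalties must be >= 0")
  attr(tb, "id") <- basename(path)
  tb
}

#' Classify atoms into solvation classes
#'
#' Deterministic heavy-atom rule, no pKa calculation: carbon -> "C"; sulfur ->
#' "S"; side-chain carboxylate oxygens of Asp/Glu and C-terminal OXT -> "O-";
#' Lys NZ and Arg NH1/NH2/NE -> "N+" under the default protonation
#' ("lys-arg", physiological pH); His ND1/NE2 join "N+" only under
#' protonation "all"; every other N/O -> "N/O".
#'
#' @param x a \code{FibrilStructure}.
#' @param subset atom indices (default all).
#' @param protonation "lys-arg" (default), "all" or "none".
#' @return character vector of classes aligned to \code{subset}.
#' @export
classifyAtoms <- function(x, subset = NULL,
                          protonation = c("lys-arg", "all", "none")) {
  protonation <- match.arg(protonation)
  a <- x@atoms
  if (is.null(subset)) subset <- seq_len(nrow(a))
  a <- a[subset, ]
  el <- toupper(a$element)
  cls <- rep(NA_character_, nrow(a))
  cls[el == "C"] <- "C"
  cls[el == "S"] <- "S"
  isO <- el == "O"
  isN <- el == "N"
  cls[isO | isN] <- "N/O"
  om <- isO & ((a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
               (a$resname == "GLU" & a$name %in% c("OE1", "OE2")) |
               a$name == "OXT")
  cls[om] <- "O-"
  if (protonation != "none") {
    np <- isN & ((a$resname == "LYS" & a$name == "NZ") |
                 (a$resname == "ARG" & a$name %in% c("NH1", "NH2", "NE")))
    if (protonation == "all")
      np <- np | (isN & a$resname == "HIS" & a$name %in% c("ND1", "NE2"))
    cls[np] <- "N+"
  }
  if (anyNA(cls)) {
    bad <- unique(el[is.na(cls)])
    stop("no solvation class for element(s): ", paste(bad, collapse = ", "))
  }
  cls
}

#' Per-atom solvation energy from folded and reference areas
#'
#' The stability metric for one atom: the buried area
#' (SASA_ref - SASA_fold, Angstrom^2) times the atomic solvation parameter
#' (cal/mol/A^2), converted to kcal/mol, with the output sign flipped so that
#' burial of a hydrophobic (positive-ASP) atom is negative (stabilizing) and
#' burial of a charged-class (negative-ASP) atom is positive (destabilizing).
#' The flip is recorded in \code{stabilityMap} metadata as
#' \code{signConvention}.
#'
#' @param sasaRef,sasaFold reference and folded areas, Angstrom^2 (>= 0).
#' @param asp atomic solvation parameter(s), cal/mol/A^2.
#' @return energy in kcal/mol (vectorized).
#' @export
#' @examples
#' atomEnergy(60, 50, 16)  # -0.16 kcal/mol: hydrophobic burial stabilizes
atomEnergy <- function(sasaRef, sasaFold, asp) {
  if (any(sasaRef < 0) || any(sasaFold < 0))
    stop("areas must be >= 0")
  -asp * (sasaRef - sasaFold) / 1000
}

# Pick the chain at median axial position for each protofilament.
.centralChains <- function(x) {
  pc <- proteinChains(x)
  proj <- vapply(pc, function(ch) {
    idx <- atomSelect(x, chain = ch)
    mean(coords(x)[idx, , drop = FALSE] %*% x@axis)
  }, numeric(1))
  proto <- x@protofilaments[pc]
  vapply(split(seq_along(pc), proto), function(ii) {
    ord <- ii[order(proj[ii])]
    pc[ord[(length(ord) + 1) %/% 2]]
  }, character(1))
}

#' Solvation-energy stability map of a fibril
#'
#' Scores the central chain of each protofilament (median axial position) in
#' the full-fibril context: folded SASA is computed with every other chain
#' (and, by default, any ligand atoms) present as occluders; reference SASA is
#' the isolated extended strand (see \code{\link{referenceSasa}}); the
#' difference is scaled per atom by its solvation class ASP, and a per-residue
#' ordering-entropy penalty is added. Chain totals are reported per
#' protofilament and averaged (metadata \code{meanChainTotal}), the
#' kcal/mol/chain figure of a C2-symmetric fibril.
#'
#' @param x a \code{FibrilStructure} with >= 3 layers (a central strand needs
#'   both axial neighbours); layers are assigned automatically if absent.
#' @param asp an \code{\link{aspTable}}.
#' @param entropy an \code{\link{entropyTable}}.
#' @param chains explicit chain IDs to score instead of the central chains.
#' @param referenceMode passed to \code{\link{referenceSasa}}.
#' @param includeEntropy logical; FALSE isolates the surface-area term.
#' @param scoreLigands logical; score ligand atoms of the selected chains with
#'   the same classes (default FALSE: ligands are environment only).
#' @param protonation see \code{\link{classifyAtoms}}.
#' @param probe,nPoints SASA settings.
#' @return a \code{\link{SolvationEnergyMap}}.
#' @export
stabilityMap <- function(x, asp = aspTable(), entropy = entropyTable(),
                         chains = NULL,
                         referenceMode = c("extended-rebuild",
                                           "isolated-chain"),
                         includeEntropy = TRUE, scoreLigands = FALSE,
                         protonation = "lys-arg",
                         probe = 1.4, nPoints = 960L) {
  referenceMode <- match.arg(referenceMode)
  if (!length(x@layers)) x <- assignLayers(x)
  nLay <- length(unique(x@layers))
  if (nLay < 3 && is.null(chains))
    stop("a central strand requires both axial neighbours: need >= 3 layers, ",
         "got ", nLay)
  if (is.null(chains)) chains <- .centralChains(x)
  aspMap <- stats::setNames(asp$asp, asp$class)
  entMap <- stats::setNames(entropy$penalty, entropy$residue)
  atomsList <- list(); resList <- list(); chainList <- list()
  for (ch in chains) {
    idxP <- atomSelect(x, chain = ch, ligand = FALSE)
    idxP <- idxP[toupper(x@atoms$element[idxP]) != "H"]
    idxL <- if (scoreLigands) {
      il <- atomSelect(x, chain = ch, ligand = TRUE)
      il[toupper(x@atoms$element[il]) != "H"]
    } else integer(0)
    idx <- c(idxP, idxL)
    fold <- computeSasa(x, subset = idx, probe = probe, nPoints = nPoints)
    refArea <- numeric(0)
    if (length(idxP)) {
      ref <- referenceSasa(x, ch, mode = referenceMode, probe = probe,
                           nPoints = nPoints)
      if (length(ref@area) != length(idxP))
        stop("folded/reference atom sets differ for chain ", ch)
      refArea <- ref@area
    }
    if (length(idxL)) {
      # ligand reference state: the isolated ligand copy, as-posed
      ligIso <- fibrilStructure(x@atoms[idxL, ])
      refArea <- c(refArea,
                   computeSasa(ligIso, probe = probe, nPoints = nPoints)@area)
    }
    cls <- classifyAtoms(x, idx, protonation = protonation)
    av <- aspMap[cls]
    if (anyNA(av))
      stop("ASP table lacks class(es): ",
           paste(unique(cls[is.na(av)]), collapse = ", "))
    en <- atomEnergy(refArea, fold@area, unname(av))
    a <- x@atoms[idx, ]
    proto <- if (ch %in% names(x@protofilaments)) x@protofilaments[[ch]]
             else NA_character_
    at <- data.frame(chain = ch, protofilament = proto, resno = a$resno,
                     resname = a$resname, name = a$name, element = a$element,
                     class = cls, sasaFold = fold@area, sasaRef = refArea,
                     energy = en, stringsAsFactors = FALSE)
    atomsList[[ch]] <- at
    resAgg <- stats::aggregate(energy ~ resno + resname, data = at, FUN = sum)
    entPen <- if (includeEntropy) {
      p <- entMap[resAgg$resname]
      p[is.na(p)] <- 0
      unname(p)
    } else rep(0, nrow(resAgg))
    resList[[ch]] <- data.frame(chain = ch, protofilament = proto,
                                resno = resAgg$resno,
                                resname = resAgg$resname,
                                atomEnergy = resAgg$energy,
                                entropy = entPen,
                                energy = resAgg$energy + entPen,
                                stringsAsFactors = FALSE)
    chainList[[ch]] <- data.frame(chain = ch, protofilament = proto,
                                  total = sum(en) + sum(entPen),
                                  stringsAsFactors = FALSE)
  }
  chainsDf <- do.call(rbind, chainList)
  new("SolvationEnergyMap",
      atoms = do.call(rbind, c(atomsList, make.row.names = FALSE)),
      residues = do.call(rbind, c(resList, make.row.names = FALSE)),
      chains = `rownames<-`(chainsDf, NULL),
      metadata = list(aspId = attr(asp, "id"), entropyId = attr(entropy, "id"),
                      probe = probe, nPoints = as.integer(nPoints),
                      referenceMode = referenceMode,
                      includeEntropy = includeEntropy,
                      protonation = protonation,
                      signConvention = "negative = stabilizing",
                      meanChainTotal = mean(chainsDf$total)))
}

#' Atom-wise difference of two solvation-energy maps
#'
#' Pairs atoms of maps \code{a} and \code{b} by (protofilament, residue
#' number, atom name) -- or chain ID when protofilament labels are absent --
#' and reports a - b per atom, with residue sums and chain totals recomputed.
#' Unpaired atoms are excluded and counted in the metadata; more than 5%
#' unpaired is an error (the structures likely differ in construct).
#'
#' @param a,b \code{\link{SolvationEnergyMap}}s over the same construct.
#' @return a \code{\link{SolvationEnergyMap}} of differences (entropy column
#'   holds entropy differences).
#' @export
differenceMap <- function(a, b) {
  stopifnot(is(a, "SolvationEnergyMap"), is(b, "SolvationEnergyMap"))
  key <- function(df) {
    grp <- if (all(!is.na(df$protofilament))) df$protofilament else df$chain
    paste(grp, df$resno, df$name, sep = "|")
  }
  ka <- key(a@atoms); kb <- key(b@atoms)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicate atom keys; cannot pair maps")
  common <- intersect(ka, kb)
  nUn <- (length(ka) - length(common)) + (length(kb) - length(common))
  if (nUn > 0.05 * max(length(ka), length(kb)))
    stop("more than 5% unpaired atoms (", nUn,
         "); the two maps likely cover different constructs")
  ia <- match(common, ka); ib <- match(common, kb)
  at <- a@atoms[ia, ]
  at$energy <- a@atoms$energy[ia] - b@atoms$energy[ib]
  at$sasaFold <- a@atoms$sasaFold[ia] - b@atoms$sasaFold[ib]
  at$sasaRef <- a@atoms$sasaRef[ia] - b@atoms$sasaRef[ib]
  rkey <- function(df) {
    grp <- if (all(!is.na(df$protofilament))) df$protofilament else df$chain
    paste(grp, df$resno, sep = "|")
  }
  ra <- rkey(a@residues); rb <- rkey(b@residues)
  rcommon <- intersect(ra, rb)
  ja <- match(rcommon, ra); jb <- match(rcommon, rb)
  res <- a@residues[ja, ]
  res$entropy <- a@residues$entropy[ja] - b@residues$entropy[jb]
  # residue atom-energy sums from the paired atoms only
  agg <- stats::aggregate(energy ~ chain + resno, data = at, FUN = sum)
  m <- match(paste(res$chain, res$resno), paste(agg$chain, agg$resno))
  res$atomEnergy <- agg$energy[m]
  res <- res[!is.na(res$atomEnergy), ]
  res$energy <- res$atomEnergy + res$entropy
  chTot <- stats::aggregate(energy ~ chain + protofilament, data = res,
                            FUN = sum)
  chains <- data.frame(chain = chTot$chain, protofilament = chTot$protofilament,
                       total = chTot$energy, stringsAsFactors = FALSE)
  new("SolvationEnergyMap", atoms = `rownames<-`(at, NULL),
      residues = `rownames<-`(res, NULL), chains = chains,
      metadata = list(kind = "difference", unpaired = nUn,
                      aspId = a@metadata$aspId,
                      meanChainTotal = mean(chains$total)))
}

#' Write a structure with per-atom energies in the B-factor field
#'
#' Writes PDB (or minimal mmCIF) coordinates with each scored atom's solvation
#' energy (kcal/mol) in the temperature-factor column, for stability-map
#' coloring in standard viewers. Atoms not covered by the map get 0.
#'
#' @param x the \code{FibrilStructure} the map was computed from.
#' @param map a \code{\link{SolvationEnergyMap}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeStabilityStructure <- function(x, map, path) {
  keyX <- paste(x@atoms$chain, x@atoms$resno, x@atoms$name, sep = "|")
  keyM <- paste(map@atoms$chain, map@atoms$resno, map@atoms$name, sep = "|")
  b <- map@atoms$energy[match(keyX, keyM)]
  b[is.na(b)] <- 0
  writeStructure(x, path, b = b)
}
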