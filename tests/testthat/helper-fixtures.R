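# Shared fixtures (built once per test run) and small independent oracles.

# plain 5-layer two-protofilament fibril, poly-Ala, default twist
fixFibril <- makeFibril(fixtureSpec())

# cleft-template fibril with charged residues lining the ligand site
fixCleft <- makeFibril(fixtureSpec(template = "cleft"))

# cleft fibril + 5-copy flat ligand column at the default cleft anchor
fixHoloSpec <- fixtureSpec(template = "cleft", ligandCount = 5)
fixHolo <- makeLigandColumn(makeFibril(fixHoloSpec), fixHoloSpec)

# ligand column offset from the protein, for clean occupancy ground truth
occSpec <- function(fraction, noiseSd = 0, seed = 1L)
  fixtureSpec(template = "cleft", ligandCount = 5,
              ligandAnchor = c(0, 6, 0), ligandFraction = fraction,
              noiseSd = noiseSd, seed = seed)

occCase <- function(fraction, noiseSd = 0, seed = 1L, trim = FALSE) {
  sp <- occSpec(fraction, noiseSd, seed)
  cpx <- makeLigandColumn(makeFibril(sp), sp)
  g <- simulateMap(cpx, sp)
  m <- buildMasks(cpx, g,
                  siteSel = atomSelect(cpx, ligand = TRUE),
                  refSel = atomSelect(cpx, resno = 345:348, ligand = FALSE))
  occupancy(g, m$site, m$reference, m$solvent, trim = trim)
}

# analytic SASA of each of two equal spheres (radius r, probe p) at
# separation d: full sphere minus the buried spherical cap
twoSphereArea <- function(d, r = 1.7, p = 1.4) {
  R <- r + p
  if (d >= 2 * R) return(4 * pi * R^2)
  4 * pi * R^2 - 2 * pi * R * (R - d / 2)
}

# minimal single-atom structure builder
atomsDf <- function(...) data.frame(..., stringsAsFactors = FALSE)

oneAtom <- function(x = 0, y = 0, z = 0, element = "C", name = "CA",
                    resname = "ALA", resno = 1L, chain = "A") {
  fibrilStructure(atomsDf(name = name, element = element, resname = resname,
                          resno = resno, chain = chain, x = x, y = y, z = z))
}

# full deposited-structure analysis; exercised by the acceptance suite when
# the wwPDB/EMDB files are present in `dir` (7upe.cif, 7upg.cif,
# emd_26665.map), never downloaded by the package itself
depositedAnalysis <- function(dir) {
  p7upe <- file.path(dir, "7upe.cif")
  p7upg <- file.path(dir, "7upg.cif")
  pmap <- file.path(dir, "emd_26665.map")
  apo <- assignLayers(readStructure(p7upe))
  holo <- assignLayers(readStructure(p7upg))
  mapApo <- stabilityMap(apo)
  mapHolo <- stabilityMap(holo)
  dm <- differenceMap(mapHolo, mapApo)
  rr <- residueEnergies(dm)
  lys340 <- mean(rr$energy[rr$resno == 340 & rr$resname == "LYS"])
  lig <- atomSelect(holo, ligand = TRUE)
  ligCopies <- split(lig, paste(atoms(holo)$chain[lig], atoms(holo)$resno[lig]))
  axPos <- vapply(ligCopies, function(ii)
    mean(coords(holo)[ii, , drop = FALSE] %*% fibrilAxis(holo)), numeric(1))
  central <- ligCopies[[which.min(abs(axPos - stats::median(axPos)))]]
  ba <- buriedArea(holo, central, side = "receptor")
  grid <- readMap(pmap)
  masks <- buildMasks(holo, grid,
                      siteSel = lig,
                      refSel = atomSelect(holo, resno = 345:352,
                                          ligand = FALSE))
  occ <- occupancy(grid, masks$site, masks$reference, masks$solvent)
  stack <- stackingMetrics(holo, rings = ringDefinitions())
  list(apoTotal = mapApo@metadata$meanChainTotal,
       holoTotal = mapHolo@metadata$meanChainTotal,
       lys340 = lys340, buried = ba, occupancy = occ$occupancy,
       stackSep = mean(stack$centroidSep))
}
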