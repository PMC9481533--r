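test_that("atomEnergy does the ASP x buried-area arithmetic", {
  expect_equal(abs(atomEnergy(60, 50, 16)), 0.16, tolerance = 1e-12)
  expect_lt(atomEnergy(60, 50, 16), 0)        # hydrophobic burial stabilizes
  expect_gt(atomEnergy(60, 50, -50), 0)       # charged burial destabilizes
  expect_equal(atomEnergy(42.5, 42.5, 16), 0)
  expect_error(atomEnergy(-1, 0, 16), ">= 0")
})

test_that("a toy 3-atom chain total equals the hand-summed value", {
  # hand spreadsheet: areas and classes fixed, energies summed by hand
  ref <- c(100, 80, 60); fold <- c(40, 70, 10)
  aspv <- c(16, -6, -50)
  hand <- -sum(aspv * (ref - fold)) / 1000    # = -(960 - 60 - 2500)/1000
  expect_equal(hand, 1.6)
  expect_equal(sum(atomEnergy(ref, fold, aspv)), hand, tolerance = 1e-12)
})

test_that("atoms classify by the deterministic heavy-atom rule", {
  df <- atomsDf(
    name = c("CA", "SD", "OD1", "OXT", "NZ", "NH1", "ND1", "O", "N"),
    element = c("C", "S", "O", "O", "N", "N", "N", "O", "N"),
    resname = c("ALA", "MET", "ASP", "GLY", "LYS", "ARG", "HIS", "ALA", "ALA"),
    resno = 1:9, chain = "A", x = as.numeric(1:9) * 5, y = 0, z = 0)
  s <- fibrilStructure(df)
  expect_equal(classifyAtoms(s),
               c("C", "S", "O-", "O-", "N+", "N+", "N/O", "N/O", "N/O"))
  expect_equal(classifyAtoms(s, protonation = "all")[7], "N+")
  expect_equal(classifyAtoms(s, protonation = "none")[5], "N/O")
})

test_that("chain totals are exactly atoms plus entropy", {
  m <- stabilityMap(fixCleft)
  for (ch in chainEnergies(m)$chain) {
    at <- sum(atomEnergies(m)$energy[atomEnergies(m)$chain == ch])
    en <- sum(residueEnergies(m)$entropy[residueEnergies(m)$chain == ch])
    tot <- chainEnergies(m)$total[chainEnergies(m)$chain == ch]
    expect_equal(tot, at + en, tolerance = 1e-9)
    rsum <- sum(residueEnergies(m)$energy[residueEnergies(m)$chain == ch])
    expect_equal(tot, rsum, tolerance = 1e-9)
  }
  expect_identical(m@metadata$aspId, "asp_eisenberg_mclachlan.tsv")
})

test_that("fewer than 3 layers is a context error for the central strand", {
  thin <- makeFibril(fixtureSpec(nLayers = 2))
  expect_error(stabilityMap(thin), "3 layers")
})

test_that("a fully solvent-exposed central chain scores ~0 plus entropy", {
  spread <- makeFibril(fixtureSpec(rise = 40, nResidues = 5,
                                   template = "cleft", protofilaments = 1L))
  m <- stabilityMap(spread)
  # the reference conformer sits in a different frame, so finite sphere
  # sampling leaves ~0.03 kcal/mol of noise per atom
  expect_lt(max(abs(atomEnergies(m)$energy)), 0.05)
  entr <- sum(residueEnergies(m)$entropy)   # single scored chain
  expect_equal(chainEnergies(m)$total[1], entr, tolerance = 0.1)
})

test_that("burial direction follows atom class sign", {
  # an apolar and a charged-class probe atom, buried by growing neighbours
  mkProbe <- function(el, nm, rn) {
    base <- atomsDf(name = c(nm, "C9", "C8"), element = c(el, "C", "C"),
                    resname = c(rn, "LIG", "LIG"), resno = c(1L, 9L, 8L),
                    chain = c("A", "B", "B"),
                    x = c(0, 3.2, -3.2), y = 0, z = 0)
    more <- atomsDf(name = c("C7", "C6"), element = "C", resname = "LIG",
                    resno = 7:6, chain = "B", x = c(0, 0), y = c(3.2, -3.2),
                    z = 0)
    list(small = fibrilStructure(base), big = fibrilStructure(rbind(base, more)))
  }
  energyOf <- function(s, cls) {
    fold <- sasa(computeSasa(s, subset = 1L))
    ref <- 4 * pi * (atoms(s)$vdw[1] + 1.4)^2
    aspv <- stats::setNames(aspTable()$asp, aspTable()$class)[[cls]]
    atomEnergy(ref, fold, aspv)
  }
  apo <- mkProbe("C", "CB", "ALA")
  expect_lt(energyOf(apo$big, "C"), energyOf(apo$small, "C"))  # more stable
  chg <- mkProbe("N", "NZ", "LYS")
  expect_gt(energyOf(chg$big, "N+"), energyOf(chg$small, "N+"))  # less stable
})

test_that("difference of a map with itself is identically zero", {
  m <- stabilityMap(fixCleft)
  d <- differenceMap(m, m)
  expect_true(all(atomEnergies(d)$energy == 0))
  expect_true(all(chainEnergies(d)$total == 0))
})

test_that("difference maps are antisymmetric and flag renamed atoms", {
  mApo <- stabilityMap(fixCleft)
  mHolo <- stabilityMap(fixHolo)
  d1 <- differenceMap(mHolo, mApo)
  d2 <- differenceMap(mApo, mHolo)
  expect_equal(atomEnergies(d1)$energy, -atomEnergies(d2)$energy,
               tolerance = 1e-12)
  # rename one atom: flagged unpaired, remainder unchanged
  mRen <- mApo
  mRen@atoms$name[5] <- "XX1"
  dr <- differenceMap(mRen, mApo)
  expect_equal(dr@metadata$unpaired, 2L)
  expect_equal(nrow(atomEnergies(dr)), nrow(atomEnergies(mApo)) - 1)
  expect_true(all(atomEnergies(dr)$energy == 0))
})

test_that("ligand environment destabilizes charged cleft residues", {
  mApo <- stabilityMap(fixCleft)
  mHolo <- stabilityMap(fixHolo)
  d <- differenceMap(mHolo, mApo)
  rr <- residueEnergies(d)
  worst <- rr[which.max(rr$energy), ]
  expect_true(worst$resname %in% c("GLU", "LYS"))
  expect_gt(worst$energy, 0)
})

test_that("pairing refuses maps over different constructs", {
  mApo <- stabilityMap(fixCleft)
  other <- makeFibril(fixtureSpec(template = "cleft", resStart = 500L))
  mOther <- stabilityMap(other)
  expect_error(differenceMap(mApo, mOther), "unpaired")
})

test_that("energies round-trip through the temperature-factor field", {
  m <- stabilityMap(fixCleft)
  f <- tempfile(fileext = ".pdb")
  writeStabilityStructure(fixCleft, m, f)
  back <- bio3d::read.pdb(f)
  key <- paste(back$atom$chain, back$atom$resno, trimws(back$atom$elety))
  mkey <- paste(atomEnergies(m)$chain, atomEnergies(m)$resno,
                atomEnergies(m)$name)
  hit <- match(mkey, key)
  expect_false(anyNA(hit))
  expect_equal(back$atom$b[hit], round(atomEnergies(m)$energy, 2),
               tolerance = 5e-3)
  # atoms outside the scored chains carry 0.00
  expect_true(all(back$atom$b[-hit] == 0))
  # zero map -> all-zero B
  z <- m; z@atoms$energy <- 0
  writeStabilityStructure(fixCleft, z, f)
  expect_true(all(bio3d::read.pdb(f)$atom$b == 0))
})

test_that("the entropy switch isolates the surface-area term", {
  mOn <- stabilityMap(fixCleft)
  mOff <- stabilityMap(fixCleft, includeEntropy = FALSE)
  expect_equal(atomEnergies(mOn)$energy, atomEnergies(mOff)$energy)
  expect_true(all(residueEnergies(mOff)$entropy == 0))
  expect_lt(chainEnergies(mOff)$total[1], chainEnergies(mOn)$total[1])
})
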