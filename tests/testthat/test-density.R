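# local MRC writer used as an independent oracle for axis-order handling:
# writes the array in a permuted (mapc, mapr, maps) layout
writePermutedMrc <- function(grid, path, mapcrs) {
  d <- dim(grid@values)
  perm <- mapcrs                      # file axis k holds canonical axis mapcrs[k]
  arr <- aperm(grid@values, perm)
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wI(dim(arr)); wI(2); wI(c(0, 0, 0)); wI(dim(arr))
  wF(dim(arr) * grid@voxel[perm]); wF(c(90, 90, 90))
  wI(mapcrs)
  wF(c(min(arr), max(arr), mean(arr)))
  wI(1); wI(0); wI(rep(0, 25))
  wF(grid@origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wF(stats::sd(as.numeric(arr))); wI(0); writeBin(raw(800), con)
  wF(as.numeric(arr))
  invisible(path)
}

test_that("a tiny synthetic map survives the MRC round-trip", {
  set.seed(7)
  g <- densityGrid(array(rnorm(4 * 5 * 6), c(4, 5, 6)), voxel = 1.1,
                   origin = c(-3, 2, 0.5))
  f <- tempfile(fileext = ".mrc")
  writeMap(g, f)
  g2 <- readMap(f)
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-6)
  expect_equal(g2@voxel, g@voxel, tolerance = 1e-6)
  expect_equal(g2@origin, g@origin, tolerance = 1e-5)
})

test_that("permuted axis orders canonicalize to the reference layout", {
  set.seed(8)
  g <- densityGrid(array(rnorm(3 * 4 * 5), c(3, 4, 5)), voxel = 1)
  for (mapcrs in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1), c(1, 3, 2))) {
    f <- tempfile(fileext = ".mrc")
    writePermutedMrc(g, f, unlist(mapcrs))
    g2 <- readMap(f)
    expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-6,
                 info = paste(mapcrs, collapse = ","))
  }
})

test_that("corrupt headers are rejected", {
  f <- tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  writeBin(as.integer(c(0, 0, 0, 2)), con, size = 4, endian = "little")
  writeBin(raw(1024 - 16), con)
  close(con)
  expect_error(readMap(f), "dimensions")
  g <- densityGrid(array(1:8 + 0, c(2, 2, 2)))
  f2 <- tempfile(fileext = ".mrc")
  writeMap(g, f2)
  # flip a cell angle to 120 degrees: non-orthogonal must be refused
  con <- file(f2, "r+b"); seek(con, 13 * 4, rw = "write")
  writeBin(120, con, size = 4, endian = "little"); close(con)
  expect_error(readMap(f2), "orthogonal")
})

test_that("an atom-centred site mask is the discrete ball around it", {
  s <- oneAtom(x = 5, y = 5, z = 5)
  g <- densityGrid(array(0, c(11, 11, 11)), voxel = 1)
  m <- fibrilstab:::.withinMask(s, g, 1L, 2.0)
  idx <- which(m, arr.ind = TRUE)
  dd <- sqrt(rowSums((sweep(idx, 2, c(6, 6, 6)))^2))
  expect_true(all(dd <= 2.0 + 1e-9))
  # brute-force count over the full grid
  all <- as.matrix(expand.grid(1:11, 1:11, 1:11))
  nBall <- sum(sqrt(rowSums(sweep(all, 2, c(6, 6, 6))^2)) <= 2.0)
  expect_equal(sum(m), nBall)
})

test_that("mask construction enforces selections and disjointness", {
  sp <- occSpec(1.0)
  cpx <- makeLigandColumn(makeFibril(sp), sp)
  g <- simulateMap(cpx, sp)
  lig <- atomSelect(cpx, ligand = TRUE)
  refSel <- atomSelect(cpx, resno = 345:348, ligand = FALSE)
  expect_error(buildMasks(cpx, g, integer(0), refSel), "empty")
  expect_error(buildMasks(cpx, g, lig, c(refSel, lig[1])), "share atoms")
  expect_error(buildMasks(cpx, g, lig, refSel, solventNear = 1),
               "solventFar")
  masks <- buildMasks(cpx, g, lig, refSel)
  expect_false(any(masks$site@values & masks$reference@values))
  expect_false(any(masks$site@values & masks$solvent@values))
  expect_false(any(masks$reference@values & masks$solvent@values))
  # mask voxel counts match a brute-force distance scan
  a <- atoms(cpx)[lig, ]
  gx <- fibrilstab:::.axisCoords(g, 1)
  gy <- fibrilstab:::.axisCoords(g, 2)
  gz <- fibrilstab:::.axisCoords(g, 3)
  vox <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dmin <- rep(Inf, nrow(vox))
  for (i in seq_len(nrow(a)))
    dmin <- pmin(dmin, sqrt((vox[, 1] - a$x[i])^2 + (vox[, 2] - a$y[i])^2 +
                              (vox[, 3] - a$z[i])^2))
  # expand.grid runs x fastest, matching R array layout
  expect_equal(sum(masks$site@values), sum(dmin <= 2.0))
})

test_that("occupancy hits 0 and 1 exactly on degenerate maps", {
  g <- densityGrid(array(0, c(8, 8, 8)), voxel = 1)
  mk <- function(cells, label) {
    v <- array(FALSE, c(8, 8, 8)); v[cells] <- TRUE
    new("VoxelMask", values = v, label = label)
  }
  site <- mk(1:8, "site"); ref <- mk(65:72, "reference")
  solv <- mk(200:300, "solvent")
  v <- array(0, c(8, 8, 8))
  v[65:72] <- c(2, 5, 5, 5, 2, 1, 1, 1)   # reference peak 5, solvent 0
  g@values <- v
  expect_equal(occupancy(g, site, ref, solv)$occupancy, 0)   # site == solvent
  v[1:8] <- 5                                             # site peak == ref
  g@values <- v
  expect_equal(occupancy(g, site, ref, solv)$occupancy, 1)
  # degenerate reference
  g@values <- array(1, c(8, 8, 8))
  expect_error(occupancy(g, site, ref, solv), "degenerate")
})

test_that("occupancy is invariant under affine voxel rescaling", {
  set.seed(11)
  g <- densityGrid(array(runif(10^3), c(10, 10, 10)), voxel = 1)
  mk <- function(cells, label) {
    v <- array(FALSE, c(10, 10, 10)); v[cells] <- TRUE
    new("VoxelMask", values = v, label = label)
  }
  site <- mk(1:50, "site"); ref <- mk(301:400, "reference")
  solv <- mk(601:900, "solvent")
  o1 <- occupancy(g, site, ref, solv)$occupancy
  for (ab in list(c(2.5, 0), c(1, 7), c(0.3, -4))) {
    g2 <- g; g2@values <- ab[1] * g@values + ab[2]
    expect_equal(occupancy(g2, site, ref, solv)$occupancy, o1,
                 tolerance = 1e-12)
  }
})

test_that("generator occupancies are recovered within 0.05 noise-free", {
  for (alpha in c(0.25, 0.5, 0.75, 1.0)) {
    occ <- occCase(alpha)
    expect_lt(abs(occ$occupancy - alpha), 0.05)
  }
})

test_that("estimated occupancy is monotone in ligand amplitude", {
  vals <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0),
                 function(a) occCase(a)$occupancy, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the trimmed maximum stabilizes noisy estimates", {
  plain <- vapply(1:5, function(s)
    occCase(0.5, noiseSd = 2.0, seed = s)$occupancy, numeric(1))
  trimmed <- vapply(1:5, function(s)
    occCase(0.5, noiseSd = 2.0, seed = s, trim = 0.99)$occupancy, numeric(1))
  expect_lt(stats::sd(trimmed), stats::sd(plain))
})

test_that("real-space correlation identifies the generating model", {
  sp <- occSpec(1.0)
  cpx <- makeLigandColumn(makeFibril(sp), sp)
  lig <- atomSelect(cpx, ligand = TRUE)
  g0 <- densityGrid(fibrilstab:::.gaussianField(
    cpx, simulateMap(cpx, sp), 3.8, lig), voxel = 1,
    origin = simulateMap(cpx, sp)@origin)
  masks <- buildMasks(cpx, g0, lig,
                      atomSelect(cpx, resno = 345:348, ligand = FALSE))
  cc <- realSpaceCC(cpx, g0, masks$site, subset = lig)
  expect_gte(cc, 0.999)
  # uniform observed map is undefined
  gu <- g0; gu@values <- array(1, dim(g0@values))
  expect_error(realSpaceCC(cpx, gu, masks$site, subset = lig), "constant")
  # a perturbed pose correlates worse than the generating pose
  shifted <- cpx
  shifted@atoms$x[lig] <- shifted@atoms$x[lig] + 1.2
  expect_lt(realSpaceCC(shifted, g0, masks$site, subset = lig), cc)
})
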