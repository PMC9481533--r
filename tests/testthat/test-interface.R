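test_that("a distant ligand buries nothing", {
  sp <- fixtureSpec(ligandCount = 1, ligandAnchor = c(0, 50, 0))
  cpx <- makeLigandColumn(makeFibril(sp), sp)
  expect_equal(buriedArea(cpx, atomSelect(cpx, ligand = TRUE)), 0,
               tolerance = 1e-6)
})

test_that("a two-atom toy complex matches the spherical-cap oracle", {
  for (d in c(2.5, 3.5, 4.5)) {
    s <- fibrilStructure(atomsDf(
      name = c("CA", "C1"), element = "C", resname = c("ALA", "LIG"),
      resno = 1:2, chain = c("A", "X"), x = c(0, d), y = 0, z = 0))
    free <- 4 * pi * (1.7 + 1.4)^2
    expected <- free - twoSphereArea(d)     # area lost by one sphere
    rec <- buriedArea(s, 2L, side = "receptor")
    lig <- buriedArea(s, 2L, side = "ligand")
    expect_equal(rec, expected, tolerance = 0.01 * free, info = paste(d))
    expect_equal(lig, expected, tolerance = 0.01 * free)
    expect_equal(buriedArea(s, 2L, side = "average"), (rec + lig) / 2,
                 tolerance = 1e-12)
  }
})

test_that("buried-area errors on empty selections", {
  expect_error(buriedArea(fixHolo, integer(0)), "empty")
})

test_that("constructed O-H...O geometry yields exactly one hydrogen bond", {
  H <- c(0.96, 0, 0)
  A <- H + 1.94 * c(cos(15 * pi / 180), sin(15 * pi / 180), 0)  # 165 degrees
  s <- fibrilStructure(atomsDf(
    name = c("OG", "HG", "OE1"), element = c("O", "H", "O"),
    resname = c("SER", "SER", "GLU"), resno = c(1, 1, 2),
    chain = c("A", "A", "B"),
    x = c(0, H[1], A[1]), y = c(0, H[2], A[2]), z = 0))
  hb <- findHBonds(s, atomSelect(s, chain = "A"), atomSelect(s, chain = "B"))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, sqrt(sum(A^2)), tolerance = 1e-6)
  expect_equal(hb$angle, 165, tolerance = 0.1)
  # swapping the selections re-evaluates roles symmetrically
  hb2 <- findHBonds(s, atomSelect(s, chain = "B"), atomSelect(s, chain = "A"))
  expect_equal(nrow(hb2), 1)
  expect_equal(hb2$distance, hb$distance)
  # a 100-degree approach fails the angular criterion
  A2 <- H + 1.94 * c(cos(80 * pi / 180), sin(80 * pi / 180), 0)
  s2 <- s; s2@atoms$x[3] <- A2[1]; s2@atoms$y[3] <- A2[2]
  expect_equal(nrow(findHBonds(s2, atomSelect(s2, chain = "A"),
                               atomSelect(s2, chain = "B"))), 0)
})

test_that("atoms 10 Angstrom apart make no hydrogen bond", {
  s <- fibrilStructure(atomsDf(
    name = c("OG", "OE1"), element = "O", resname = c("SER", "GLU"),
    resno = 1:2, chain = c("A", "B"), x = c(0, 10), y = 0, z = 0))
  expect_equal(nrow(findHBonds(s, 1L, 2L)), 0)
  expect_error(findHBonds(s, 1:2, 2L), "disjoint")
})

test_that("the mock ligand hydrogen-bonds the charged cleft residues", {
  hb <- findHBonds(fixHolo, atomSelect(fixHolo, ligand = TRUE),
                   atomSelect(fixHolo, ligand = FALSE))
  expect_gt(nrow(hb), 0)
  partners <- unique(sub("[0-9]+/.*$", "", c(hb$donorResidue,
                                             hb$acceptorResidue)))
  expect_true(any(partners %in% c("GLU", "LYS", "SER")))
})

test_that("an ideal coplanar column has uniform spacing and zero tilt", {
  sp <- fixtureSpec(nLayers = 5, ligandCount = 5, twist = 0)
  cpx <- makeLigandColumn(makeFibril(sp), sp)
  sm <- stackingMetrics(cpx)
  expect_equal(sm$centroidSep, rep(4.8, nrow(sm)), tolerance = 1e-9)
  expect_equal(sm$tilt, rep(0, nrow(sm)), tolerance = 1e-9)
  expect_equal(sm$solventSep, rep(4.8, nrow(sm)), tolerance = 1e-9)
  expect_equal(sm$fibrilSep, rep(4.8, nrow(sm)), tolerance = 1e-9)
})

test_that("the curved stack compresses the solvent face as specified", {
  sp <- fixtureSpec(nLayers = 5, ligandCount = 5, twist = 0,
                    ligandCompression = 3.5)
  cpx <- makeLigandColumn(makeFibril(sp), sp)
  sm <- stackingMetrics(cpx)
  solventRing <- sm[sm$ring == "A", ]
  fibrilRing <- sm[sm$ring == "D", ]
  expect_equal(mean(solventRing$solventSep), 3.5, tolerance = 0.05)
  expect_true(all(fibrilRing$fibrilSep > 4.8))
  expect_true(all(sm$solventSep < sm$fibrilSep))
  expect_true(all(sm$tilt > 0 & sm$tilt <= 90))
})

test_that("a single ligand copy cannot form a stack", {
  sp <- fixtureSpec(nLayers = 5, ligandCount = 1)
  cpx <- makeLigandColumn(makeFibril(sp), sp)
  expect_error(stackingMetrics(cpx), ">= 2")
})

test_that("stacking profiles are rigid-transform invariant", {
  sp <- fixtureSpec(nLayers = 5, ligandCount = 5, ligandCompression = 3.5)
  cpx <- makeLigandColumn(makeFibril(sp), sp)
  sm0 <- stackingMetrics(cpx)
  R <- fibrilstab:::.rotationMatrix(c(2, -1, 1), 63)
  smR <- stackingMetrics(transformStructure(cpx, R, t = c(-4, 8, 1)))
  for (col in c("centroidSep", "tilt", "solventSep", "fibrilSep"))
    expect_equal(smR[[col]], sm0[[col]], tolerance = 1e-6, info = col)
})

test_that("a displaced pose loses to the bound pose on every metric", {
  sp <- fixtureSpec(template = "cleft", ligandCount = 3)
  bound <- makeLigandColumn(makeFibril(sp), sp)
  away <- bound
  i <- atomSelect(away, ligand = TRUE)
  away@atoms$y[i] <- away@atoms$y[i] + 20
  g <- simulateMap(bound, sp)
  masks <- buildMasks(bound, g, atomSelect(bound, ligand = TRUE),
                      atomSelect(bound, resno = 345:348, ligand = FALSE))
  pr <- poseReport(list(bound = bound, away = away), grid = g,
                   mask = masks$site)
  expect_equal(pr$pose[1], "bound")
  b <- pr[pr$pose == "bound", ]; aw <- pr[pr$pose == "away", ]
  expect_gt(b$buriedArea, aw$buriedArea)
  expect_gte(b$hbonds, aw$hbonds)
  expect_gt(b$complementarity, aw$complementarity)
  expect_match(attr(pr, "rankingRule"), "lexicographic")
})

test_that("the unperturbed pose ranks first by correlation", {
  sp <- fixtureSpec(template = "cleft", ligandCount = 3)
  bound <- makeLigandColumn(makeFibril(sp), sp)
  lig <- atomSelect(bound, ligand = TRUE)
  g <- simulateMap(bound, sp)
  masks <- buildMasks(bound, g, lig,
                      atomSelect(bound, resno = 345:348, ligand = FALSE))
  poses <- list(true = bound)
  set.seed(42)
  for (k in 1:5) {
    p <- bound
    p@atoms$x[lig] <- p@atoms$x[lig] + rnorm(1, 0, 0.8)
    p@atoms$y[lig] <- p@atoms$y[lig] + rnorm(1, 0, 0.8)
    p@atoms$z[lig] <- p@atoms$z[lig] + rnorm(1, 0, 0.8)
    poses[[paste0("jitter", k)]] <- p
  }
  pr <- poseReport(poses, grid = g, mask = masks$site)
  expect_equal(pr$pose[which.max(pr$cc)], "true")
})

test_that("poses with different receptors are not comparable", {
  sp <- fixtureSpec(template = "cleft", ligandCount = 2)
  a <- makeLigandColumn(makeFibril(sp), sp)
  b <- a
  b@atoms$x[1] <- b@atoms$x[1] + 3
  expect_error(poseReport(list(a, b)), "receptor")
})
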