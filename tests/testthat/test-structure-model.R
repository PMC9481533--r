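test_that("a hand-written ATOM record round-trips to identical coordinates", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A 306      11.104  -2.320   4.800  1.00  0.00           C",
    "END"), f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 1)
  expect_equal(unname(coords(s)[1, ]), c(11.104, -2.320, 4.800))
  expect_equal(atoms(s)$resno, 306)
  f2 <- tempfile(fileext = ".pdb")
  writeStructure(s, f2)
  s2 <- readStructure(f2)
  expect_equal(coords(s2), coords(s), tolerance = 1e-6)
})

test_that("synthetic structures survive PDB and mmCIF write/read round-trips", {
  for (ext in c(".pdb", ".cif")) {
    f <- tempfile(fileext = ext)
    writeStructure(fixHolo, f)
    s <- readStructure(f)
    expect_equal(nAtoms(s), nAtoms(fixHolo))
    expect_equal(atoms(s)$name, atoms(fixHolo)$name)
    expect_equal(atoms(s)$resno, atoms(fixHolo)$resno)
    # PDB fixed columns carry 3 decimals
    expect_equal(coords(s), coords(fixHolo), tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_equal(sum(atoms(s)$ligand), sum(atoms(fixHolo)$ligand))
  }
})

test_that("unreadable and empty files raise parse errors", {
  f <- tempfile(fileext = ".pdb")
  expect_error(readStructure(f), "not found")
  writeLines("REMARK nothing here", f)
  expect_error(readStructure(f), "atoms|parse")
})

test_that("expandHelical with one layer returns the template unchanged", {
  layer <- makeFibril(fixtureSpec(nLayers = 1))
  out <- expandHelical(layer, helicalSymmetry(4.8, -1.2), 1)
  expect_equal(coords(out), coords(layer))
  expect_equal(chains(out), chains(layer))
})

test_that("zero twist stacks by pure translation", {
  s <- oneAtom(x = 1)
  out <- expandHelical(s, helicalSymmetry(4.8, 0), 3)
  expect_equal(nAtoms(out), 3)
  expect_equal(atoms(out)$z, c(0, 4.8, 9.6))
  expect_equal(atoms(out)$x, rep(1, 3))
})

test_that("large-twist expansion matches a closed-form rotation oracle", {
  s <- oneAtom(x = 2.1, y = -0.7)
  rise <- 2.36; twist <- 179
  out <- expandHelical(s, helicalSymmetry(rise, twist), 4)
  xyz <- coords(out)
  p0 <- c(2.1, -0.7, 0)
  for (k in 0:3) {
    th <- k * twist * pi / 180
    Rk <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    expect_equal(unname(xyz[k + 1, ]),
                 unname(as.numeric(Rk %*% p0) + c(0, 0, k * rise)),
                 tolerance = 1e-9)
  }
})

test_that("expansion preserves intra-layer pairwise distances (rigid)", {
  spec <- fixtureSpec(nLayers = 4, twist = 3.7)
  fib <- makeFibril(spec)
  d0 <- dist(coords(fib)[atomSelect(fib, chain = c("A", "B")), ])
  for (lay in 1:3) {
    chs <- names(layers(fib))[layers(fib) == lay]
    dk <- dist(coords(fib)[atomSelect(fib, chain = chs), ])
    expect_lt(max(abs(dk - d0)), 1e-6)
  }
})

test_that("expandHelical rejects bad inputs", {
  s <- oneAtom()
  expect_error(expandHelical(s, helicalSymmetry(4.8, 0), 0), ">= 1")
  expect_error(expandHelical(fixFibril, helicalSymmetry(4.8, 0), 2),
               "single-layer")
  expect_error(helicalSymmetry(-1, 0))
  expect_error(helicalSymmetry(4.8, 200))
})

test_that("assignLayers recovers generating layers over rises and twists", {
  for (rise in c(2, 4.8, 10)) {
    for (twist in c(-5, -1.2, 0, 5)) {
      spec <- fixtureSpec(nLayers = 6, rise = rise, twist = twist,
                          nResidues = 5)
      fib <- makeFibril(spec)
      redone <- assignLayers(fib)
      expect_equal(unname(layers(redone)[names(layers(fib))]),
                   unname(layers(fib)),
                   info = sprintf("rise %.1f twist %.1f", rise, twist))
      # both chains of each rung share a layer index
      lay <- layers(redone)
      expect_true(all(table(lay) == 2))
    }
  }
})

test_that("assignLayers handles a single chain and a rotated frame", {
  single <- makeFibril(fixtureSpec(nLayers = 1, protofilaments = 1))
  out <- assignLayers(single)
  expect_equal(unname(layers(out)), 0L)
  R <- fibrilstab:::.rotationMatrix(c(1, 1, 0), 35)
  rot <- transformStructure(fixFibril, R, t = c(5, -3, 2))
  rot@axis <- c(0, 0, 1)  # discard the stored axis: force re-estimation
  redone <- assignLayers(rot)
  expect_equal(unname(layers(redone)[names(layers(fixFibril))]),
               unname(layers(fixFibril)))
})

test_that("ligand residues are flagged via the configurable name set", {
  f <- tempfile(fileext = ".pdb")
  writeStructure(fixHolo, f)
  s <- readStructure(f, ligandNames = "LIG")
  expect_equal(sum(atoms(s)$ligand), sum(atoms(fixHolo)$ligand))
  s2 <- readStructure(f, ligandNames = character(0))
  expect_equal(sum(atoms(s2)$ligand), 0)
})
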