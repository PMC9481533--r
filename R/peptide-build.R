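# Internal ideal-geometry peptide builder (NeRF chain extension).
#
# Bond lengths / angles are standard Engh-Huber-type values; side chains are
# built with trans dihedrals. Supported residue types for de novo building:
# GLY, ALA, SER, LYS, GLU (enough for the synthetic fixtures); arbitrary
# residues are handled in extended rebuilds by rigid side-chain transfer.

.bbGeom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8)

# Side-chain internal coordinates: list of atom records
# (name, element, refs = c(A, B, C), bond, angle, torsion).
.sideChainGeom <- list(
  GLY = list(),
  ALA = list(
    list("CB", "C", c("C", "N", "CA"), 1.521, 110.4, NA)),  # torsion set below
  SER = list(
    list("CB", "C", c("C", "N", "CA"), 1.521, 110.4, NA),
    list("OG", "O", c("N", "CA", "CB"), 1.417, 111.1, 180)),
  LYS = list(
    list("CB", "C", c("C", "N", "CA"), 1.521, 110.4, NA),
    list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, 180),
    list("CD", "C", c("CA", "CB", "CG"), 1.520, 111.3, 180),
    list("CE", "C", c("CB", "CG", "CD"), 1.520, 111.3, 180),
    list("NZ", "N", c("CG", "CD", "CE"), 1.489, 111.9, 180)),
  GLU = list(
    list("CB", "C", c("C", "N", "CA"), 1.521, 110.4, NA),
    list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, 180),
    list("CD", "C", c("CA", "CB", "CG"), 1.516, 112.6, 180),
    list("OE1", "O", c("CB", "CG", "CD"), 1.249, 118.4, 0),
    list("OE2", "O", c("CB", "CG", "CD"), 1.249, 118.4, 180)))

# Torsion C-N-CA-CB that yields an L-amino acid (verified by chirality sign).
.cbTorsion <- 122.6

# Build a peptide chain with uniform backbone dihedrals.
# Returns a data.frame(name, element, resname, resno, x, y, z).
.buildChain <- function(sequence, resStart = 1L,
                        phi = -120, psi = 120, omega = 180) {
  nres <- length(sequence)
  sequence <- toupper(sequence)
  unknown <- setdiff(sequence, names(.sideChainGeom))
  if (length(unknown))
    stop("no side-chain template for residue type(s): ",
         paste(unique(unknown), collapse = ", "))
  g <- .bbGeom
  rows <- list()
  # residue 1 backbone in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  C <- .placeAtom(c(0, 1, 0), N, CA, g$ca_c, g$ang_n_ca_c, 0)
  for (i in seq_len(nres)) {
    res <- sequence[i]
    resno <- resStart + i - 1L
    O <- .placeAtom(N, CA, C, g$c_o, g$ang_ca_c_o, psi + 180)
    bb <- list(N = N, CA = CA, C = C)
    add <- function(nm, el, xyz) {
      rows[[length(rows) + 1]] <<- data.frame(
        name = nm, element = el, resname = res, resno = resno,
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
    add("N", "N", N); add("CA", "C", CA); add("C", "C", C); add("O", "O", O)
    for (sc in .sideChainGeom[[res]]) {
      tor <- if (is.na(sc[[6]])) .cbTorsion else sc[[6]]
      refs <- lapply(sc[[3]], function(r) {
        if (r %in% names(bb)) bb[[r]]
        else {
          hit <- rows[[which(vapply(rows, function(x)
            x$resno == resno && x$name == r, logical(1)))[1]]]
          c(hit$x, hit$y, hit$z)
        }
      })
      add(sc[[1]], sc[[2]],
          .placeAtom(refs[[1]], refs[[2]], refs[[3]], sc[[4]], sc[[5]], tor))
    }
    if (i < nres) {
      Nn <- .placeAtom(N, CA, C, g$c_n, g$ang_ca_c_n, psi)
      CAn <- .placeAtom(CA, C, Nn, g$n_ca, g$ang_c_n_ca, omega)
      Cn <- .placeAtom(C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  do.call(rbind, rows)
}

# Rebuild a chain's backbone with ideal extended dihedrals, transferring each
# residue's side chain rigidly via its local (N, CA, C) frame. Residues
# lacking any of N/CA/C cannot be rebuilt and are reported in `failed`.
# Input/output: atom data.frame in original atom order (failed residues keep
# their original coordinates).
.extendedRebuild <- function(a, phi = -120, psi = 120, omega = 180) {
  resKeys <- unique(a$resno)
  nres <- length(resKeys)
  g <- .bbGeom
  N <- c(0, 0, 0); CA <- c(g$n_ca, 0, 0)
  C <- .placeAtom(c(0, 1, 0), N, CA, g$ca_c, g$ang_n_ca_c, 0)
  out <- a
  failed <- character(0)
  for (i in seq_len(nres)) {
    rows <- which(a$resno == resKeys[i])
    nm <- a$name[rows]
    bbIdx <- match(c("N", "CA", "C"), nm)
    if (anyNA(bbIdx)) {
      failed <- c(failed, as.character(resKeys[i]))
    } else {
      orig <- as.matrix(a[rows[bbIdx], c("x", "y", "z")])
      fit <- .kabsch(orig, rbind(N, CA, C))
      xyz <- as.matrix(a[rows, c("x", "y", "z")]) %*% t(fit$R)
      xyz <- sweep(xyz, 2, -fit$t)
      out[rows, c("x", "y", "z")] <- xyz
      # ideal carbonyl O (depends on psi, not carried by the rigid frame)
      oIdx <- match("O", nm)
      if (!is.na(oIdx))
        out[rows[oIdx], c("x", "y", "z")] <-
          .placeAtom(N, CA, C, g$c_o, g$ang_ca_c_o, psi + 180)
    }
    if (i < nres) {
      Nn <- .placeAtom(N, CA, C, g$c_n, g$ang_ca_c_n, psi)
      CAn <- .placeAtom(CA, C, Nn, g$n_ca, g$ang_c_n_ca, omega)
      Cn <- .placeAtom(C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  list(atoms = out, failed = failed)
}
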