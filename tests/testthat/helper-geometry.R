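# shared fixtures built in code: the packaged rotamer library, an
# internal-coordinate atom placer, and a tiny protein builder with known
# chi angles for structure-reading tests

testLib <- loadRotamerLibrary()

# NeRF-style placement: position a new atom at distance r from c, with
# angle theta (new-c-b) and dihedral phi (new-c-b-a), all in degrees.
# Independent of the package's dihedral code: pure vector construction.
placeAtom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  nrm <- function(v) v / sqrt(sum(v^2))
  cx <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  b1 <- nrm(b - a); b2 <- nrm(c - b)
  n <- nrm(cx(b1, b2)); m <- cx(n, b2)
  c + r * (-cos(th) * b2 + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
}

# build one residue's backbone stub + side chain with exact chi angles;
# returns a data.frame of atoms. Supported: SER, LEU, PHE, CYS, ALA.
buildResidue <- function(restype, chis, origin = c(0, 0, 0),
                         chain = "A", resno = 1L) {
  ca <- origin
  n <- origin + c(-0.52, 1.36, 0)
  cb <- origin + c(1.53, 0, 0)
  co <- origin + c(-0.60, -1.20, 0.60)  # backbone carbonyl C
  atoms <- list(N = n, CA = ca, C = co, CB = cb)
  elem <- c(N = "N", CA = "C", C = "C", CB = "C")
  addAtom <- function(name, pos, el) {
    atoms[[name]] <<- pos
    elem[name] <<- el
  }
  if (restype == "SER") {
    addAtom("OG", placeAtom(n, ca, cb, 1.41, 110.5, chis[1]), "O")
  } else if (restype == "CYS") {
    addAtom("SG", placeAtom(n, ca, cb, 1.81, 114, chis[1]), "S")
  } else if (restype == "LEU") {
    cg <- placeAtom(n, ca, cb, 1.53, 116, chis[1])
    addAtom("CG", cg, "C")
    addAtom("CD1", placeAtom(ca, cb, cg, 1.52, 111, chis[2]), "C")
    addAtom("CD2", placeAtom(ca, cb, cg, 1.52, 111, chis[2] + 120), "C")
  } else if (restype == "PHE") {
    cg <- placeAtom(n, ca, cb, 1.50, 114, chis[1])
    addAtom("CG", cg, "C")
    addAtom("CD1", placeAtom(ca, cb, cg, 1.39, 120, chis[2]), "C")
    addAtom("CD2", placeAtom(ca, cb, cg, 1.39, 120, chis[2] + 180), "C")
  } else if (restype == "ALA") {
    # no side chain beyond CB
  } else stop("unsupported test residue type: ", restype)
  nm <- names(atoms)
  data.frame(chain = chain, resno = as.integer(resno), resname = restype,
             atom = nm, element = unname(elem[nm]),
             x = vapply(atoms, `[`, numeric(1), 1),
             y = vapply(atoms, `[`, numeric(1), 2),
             z = vapply(atoms, `[`, numeric(1), 3),
             row.names = NULL, stringsAsFactors = FALSE)
}

# write an atom table as a minimal PDB with a CRYST1 record
writeTestPDB <- function(atomTable, path, cell = c(200, 200, 200, 90, 90, 90),
                         spaceGroup = "P 1", altLocs = NULL) {
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                   cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                   spaceGroup)
  alt <- if (is.null(altLocs)) rep(" ", nrow(atomTable)) else altLocs
  lines <- vapply(seq_len(nrow(atomTable)), function(i) {
    sprintf("ATOM  %5d  %-3s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, atomTable$atom[i], alt[i], atomTable$resname[i],
            atomTable$chain[i], atomTable$resno[i], atomTable$x[i],
            atomTable$y[i], atomTable$z[i], atomTable$element[i])
  }, character(1))
  writeLines(c(cryst, lines, "END"), path)
  path
}

# a two-residue test protein (SER + LEU) with exact chi angles, residues
# spaced far apart inside a large P1 cell
buildTestProtein <- function(serChi = -65, leuChis = c(-65, 175)) {
  rbind(buildResidue("SER", serChi, origin = c(0, 0, 0), resno = 1L),
        buildResidue("LEU", leuChis, origin = c(30, 0, 0), resno = 2L))
}
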