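#' Wrap angles into the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into (-180, 180].
#' @export
wrapAngle <- function(x) x - 360 * ceiling((x - 180) / 360)

#' Circular distance between angles
#'
#' Absolute angular separation in degrees, in [0, 180]; symmetric and
#' invariant to adding multiples of 360 to either argument.
#'
#' @param a,b numeric angle vectors (degrees), recycled.
#' @export
circularDistance <- function(a, b) abs(wrapAngle(a - b))

# chi dihedral atom names per residue type; the fourth atom of chi_k is the
# first moving side-chain atom, following the usual biochemical definitions
.CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1")))

# dihedrals whose terminal group is 2-fold symmetric (chemically
# indistinguishable atom labelings), folded into (-90, 90] before any
# state comparison
.SYMMETRIC_CHI <- c(PHE = 2L, TYR = 2L, ASP = 2L, GLU = 3L)

#' Dihedral angle from four points
#'
#' Signed torsion in degrees following the standard convention (trans =
#' 180); thin wrapper over [bio3d::torsion.xyz()], wrapped into (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 Cartesian coordinates.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  wrapAngle(bio3d::torsion.xyz(c(p1, p2, p3, p4)))
}

#' Fold 2-fold-symmetric terminal chi angles
#'
#' For residue types whose terminal dihedral is degenerate under a 180-degree
#' flip (PHE/TYR chi2, ASP chi2, GLU chi3), maps that angle into (-90, 90]
#' so that the two equivalent atom labelings give the same value. Other
#' angles pass through unchanged apart from wrapping.
#'
#' @param chis numeric chi vector, degrees.
#' @param residueType three-letter code.
#' @return folded chi vector, each entry in (-180, 180] (symmetric entries
#'   in (-90, 90]).
#' @export
foldSymmetricChis <- function(chis, residueType) {
  chis <- wrapAngle(chis)
  k <- .SYMMETRIC_CHI[residueType]
  if (!is.na(k) && k <= length(chis)) {
    v <- chis[k]
    v <- v - 180 * ceiling((v - 90) / 180)
    chis[k] <- v
  }
  chis
}

#' Number of chi angles defined for a residue type
#' @param residueType three-letter code (vectorized).
#' @return integer count, 0 for types without chi angles (ALA, GLY).
#' @export
chiCount <- function(residueType) {
  vapply(residueType, function(rt) {
    d <- .CHI_ATOMS[[rt]]
    if (is.null(d)) 0L else length(d)
  }, integer(1))
}

#' Compute side-chain chi angles for one residue
#'
#' Looks up the four defining atoms of each chi dihedral in a coordinate
#' table and returns the folded chi vector. Residues with missing side-chain
#' atoms yield NULL with a warning rather than an error, so a structure scan
#' can skip incomplete residues.
#'
#' @param atomTable data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `x`, `y`, `z` (one structure/frame).
#' @param chain chain identifier.
#' @param resno residue number.
#' @param fold fold 2-fold-symmetric terminal angles (default TRUE).
#' @return numeric chi vector (degrees) or NULL when the residue type has no
#'   chi angles or atoms are missing.
#' @export
computeChiAngles <- function(atomTable, chain, resno, fold = TRUE) {
  res <- atomTable[atomTable$chain == chain & atomTable$resno == resno, ,
                   drop = FALSE]
  if (nrow(res) == 0L)
    stop("residue ", chain, ":", resno, " not found")
  rt <- res$resname[1]
  defs <- .CHI_ATOMS[[rt]]
  if (is.null(defs)) return(NULL)
  chis <- numeric(length(defs))
  for (i in seq_along(defs)) {
    idx <- match(defs[[i]], res$atom)
    if (anyNA(idx)) {
      warning("residue ", chain, ":", rt, resno, " missing atom(s) ",
              paste(defs[[i]][is.na(idx)], collapse = ","),
              "; skipped", call. = FALSE)
      return(NULL)
    }
    xyz <- as.matrix(res[idx, c("x", "y", "z")])
    chis[i] <- dihedralAngle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  }
  if (fold) chis <- foldSymmetricChis(chis, rt)
  chis
}
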