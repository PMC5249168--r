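# space-group operators in fractional coordinates: list of (3x3 rotation,
# length-3 translation). Covers the groups needed for typical protein
# lattices handled here; symbols are normalized before lookup.
.SG_OPS <- list(
  P1 = list(list(R = diag(3), t = c(0, 0, 0))),
  P21 = list(list(R = diag(3), t = c(0, 0, 0)),
             list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0))),
  P212121 = list(list(R = diag(3), t = c(0, 0, 0)),
                 list(R = diag(c(-1, -1, 1)), t = c(0.5, 0, 0.5)),
                 list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0.5)),
                 list(R = diag(c(1, -1, -1)), t = c(0.5, 0.5, 0))),
  C2 = list(list(R = diag(3), t = c(0, 0, 0)),
            list(R = diag(c(-1, 1, -1)), t = c(0, 0, 0)),
            list(R = diag(3), t = c(0.5, 0.5, 0)),
            list(R = diag(c(-1, 1, -1)), t = c(0.5, 0.5, 0))))

.normalizeSpaceGroup <- function(symbol) {
  s <- toupper(gsub("[ ()]", "", symbol))
  map <- c(P1 = "P1", P121 = "P1",
           P21 = "P21", P1211 = "P21", P21_ = "P21",
           P212121 = "P212121",
           C2 = "C2", C121 = "C2")
  out <- map[s]
  if (is.na(out))
    stop("unknown or unsupported space group symbol: '", symbol, "'")
  unname(out)
}

#' Space-group symmetry operators
#'
#' @param symbol Hermann-Mauguin symbol (e.g. "P 1 21 1"); spaces and
#'   parentheses are ignored.
#' @return list of operators, each a list with 3x3 matrix `R` and length-3
#'   translation `t`, both in fractional coordinates. The identity is first.
#' @export
spaceGroupOperators <- function(symbol) .SG_OPS[[.normalizeSpaceGroup(symbol)]]

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Standard PDB convention (a along x, b in the xy plane).
#'
#' @param cell numeric length-6: a, b, c (Angstrom), alpha, beta, gamma (deg).
#' @return 3x3 matrix M such that Cartesian = M %*% fractional.
#' @export
orthogonalizationMatrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

#' Generate crystal-neighbor copies of the asymmetric unit
#'
#' Applies all space-group operators and unit-cell translations within
#' `shell` cells in each direction and returns the resulting copies in
#' Cartesian coordinates, excluding the identity copy itself.
#'
#' @param lattice a [LatticeModel-class].
#' @param shell integer, cell translations in each direction (default 1).
#' @return list of copies; each has `label` and an atom data.frame matching
#'   `atoms(lattice)` with transformed coordinates.
#' @export
expandNeighbors <- function(lattice, shell = 1) {
  ops <- spaceGroupOperators(spaceGroup(lattice))
  M <- orthogonalizationMatrix(cellParameters(lattice))
  Minv <- solve(M)
  at <- atoms(lattice)
  frac <- t(Minv %*% t(as.matrix(at[, c("x", "y", "z")])))
  shifts <- expand.grid(i = -shell:shell, j = -shell:shell, k = -shell:shell)
  out <- list()
  for (o in seq_along(ops)) {
    op <- ops[[o]]
    base <- frac %*% t(op$R)
    base <- sweep(base, 2, op$t, "+")
    for (s in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[s, ])
      if (o == 1L && all(sh == 0)) next  # identity copy
      xyz <- sweep(base, 2, sh, "+") %*% t(M)
      cp <- at
      cp$x <- xyz[, 1]; cp$y <- xyz[, 2]; cp$z <- xyz[, 3]
      out[[length(out) + 1L]] <- list(
        label = sprintf("op%d_%+d%+d%+d", o, sh[1], sh[2], sh[3]),
        atoms = cp)
    }
  }
  out
}

.heavy <- function(at) at[!(toupper(at$element) %in% c("H", "D")), ,
                          drop = FALSE]

#' Detect crystal-contacting residues
#'
#' A residue participates in a crystal contact when any of its heavy atoms
#' lies within `cutoff` (inclusive) of a heavy atom belonging to any
#' symmetry- or translation-related neighbor copy of the asymmetric unit.
#'
#' @param lattice a [LatticeModel-class].
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @param shell symmetry expansion shell passed to [expandNeighbors()].
#' @return data.frame with columns `chain`, `resno`, `resname`,
#'   `contacting`, one row per residue of the asymmetric unit.
#' @export
detectContacts <- function(lattice, cutoff = 4.0, shell = 1) {
  stopifnot(cutoff > 0)
  asu <- .heavy(atoms(lattice))
  nb <- expandNeighbors(lattice, shell = shell)
  res <- unique(asu[, c("chain", "resno", "resname")])
  res$contacting <- FALSE
  if (length(nb) == 0L) {
    warning("empty neighbor set; all residues flagged non-contacting")
    return(res)
  }
  nxyz <- do.call(rbind, lapply(nb, function(cp) {
    h <- .heavy(cp$atoms); as.matrix(h[, c("x", "y", "z")])
  }))
  axyz <- as.matrix(asu[, c("x", "y", "z")])
  # bounding-box prefilter around the asymmetric unit
  lo <- apply(axyz, 2, min) - cutoff; hi <- apply(axyz, 2, max) + cutoff
  keep <- nxyz[, 1] >= lo[1] & nxyz[, 1] <= hi[1] &
          nxyz[, 2] >= lo[2] & nxyz[, 2] <= hi[2] &
          nxyz[, 3] >= lo[3] & nxyz[, 3] <= hi[3]
  nxyz <- nxyz[keep, , drop = FALSE]
  if (nrow(nxyz) == 0L) return(res)
  cut2 <- cutoff^2
  n2 <- rowSums(nxyz^2)
  touched <- logical(nrow(asu))
  chunk <- 256L
  for (s in seq(1L, nrow(axyz), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(axyz))
    blk <- axyz[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), n2, "+") - 2 * blk %*% t(nxyz)
    touched[s:e] <- apply(d2 <= cut2 + 1e-9, 1, any)
  }
  key <- paste(asu$chain, asu$resno)
  hit <- unique(key[touched])
  res$contacting <- paste(res$chain, res$resno) %in% hit
  res
}

#' Read a lattice model from a PDB file
#'
#' Parses protein coordinates with [bio3d::read.pdb()] and the CRYST1 record
#' (which bio3d drops) for cell parameters and space group. Waters, ions and
#' other HETATM records are excluded by default; hydrogens are always
#' excluded from the atom table.
#'
#' @param path PDB file.
#' @param altLoc alternate-location policy: keep blank altLocs plus this
#'   conformer (default "A").
#' @param includeHet keep HETATM records (default FALSE).
#' @return a [LatticeModel-class].
#' @export
readLattice <- function(path, altLoc = "A", includeHet = FALSE) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr) == 0L)
    stop("no CRYST1 record in '", path,
         "'; cell and space group are required for crystal analysis")
  cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                       substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                       substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  sg <- trimws(substr(cr[1], 56, 66))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!includeHet) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[at$alt %in% c("", " ", altLoc) | is.na(at$alt), , drop = FALSE]
  elem <- at$elesy
  fix <- which(is.na(elem) | !nzchar(trimws(elem)))
  if (length(fix)) elem[fix] <- substr(gsub("[0-9']", "", at$elety[fix]), 1, 1)
  tab <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                    atom = at$elety, element = trimws(elem),
                    x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  tab <- .heavy(tab)
  new("LatticeModel", atoms = tab, spaceGroup = sg, cell = cell)
}
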