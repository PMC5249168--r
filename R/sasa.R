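# van der Waals radii (Angstrom) for SASA; Bondi-style values
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
          F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

.vdwRadius <- function(element) {
  r <- .VDW[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-spiral / Fibonacci)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA from test points on each atom's solvent-extended sphere
#' (radius = van der Waals + probe). The point count per atom targets the
#' requested surface density; points are placed on a deterministic golden
#' spiral so results are reproducible.
#'
#' @param atomTable data.frame with columns `element`, `x`, `y`, `z`
#'   (hydrogens should already be excluded).
#' @param probe probe sphere radius in Angstrom (default 1.4, a water).
#' @param pointDensity target test-point density in points per square
#'   Angstrom of extended-sphere surface (default 15).
#' @return numeric vector of per-atom SASA values (square Angstrom).
#' @export
shrakeRupleySASA <- function(atomTable, probe = 1.4, pointDensity = 15) {
  stopifnot(probe > 0, pointDensity > 0)
  n <- nrow(atomTable)
  if (n == 0L) return(numeric(0))
  xyz <- as.matrix(atomTable[, c("x", "y", "z")])
  rad <- .vdwRadius(atomTable$element) + probe
  out <- numeric(n)
  maxr <- max(rad)
  for (i in seq_len(n)) {
    ri <- rad[i]
    area <- 4 * pi * ri^2
    npts <- max(64L, as.integer(ceiling(pointDensity * area)))
    pts <- sweep(.spherePoints(npts) * ri, 2, xyz[i, ], "+")
    d2c <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2c < (ri + maxr)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2c[nb]) < ri + rad[nb]]
    if (length(nb) == 0L) { out[i] <- area; next }
    acc <- rep(TRUE, npts)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
             (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 > rad[j]^2
    }
    out[i] <- area * sum(acc) / npts
  }
  out
}

#' Reference maximum per-residue SASA table
#'
#' Theoretical maximum accessibility of residue X in an extended tripeptide
#' context, used as the denominator of relative accessibility. The packaged
#' table records its published source in the file header.
#'
#' @param path file path; defaults to the packaged table.
#' @return named numeric vector, Angstrom^2 per residue type.
#' @export
maxSasaReference <- function(path = system.file("extdata",
                               "max_sasa_ala_x_ala.tsv",
                               package = "RotamerEnsembles")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab$max_sasa, tab$residue_type)
}

#' Per-residue relative solvent accessibility
#'
#' SASA of each residue within its chain divided by the theoretical maximum
#' for that residue type. Computed per chain separately: each chain is
#' treated as an isolated molecule, so lattice neighbors and the partner
#' chain do not shadow the surface.
#'
#' @param atomTable heavy-atom data.frame (`chain`, `resno`, `resname`,
#'   `element`, `x`, `y`, `z`).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param pointDensity test-point density (default 15 per square Angstrom).
#' @param reference named numeric max-SASA vector
#'   (default [maxSasaReference()]).
#' @return data.frame `chain`, `resno`, `resname`, `sasa`, `rel_access`.
#' @export
relativeAccessibility <- function(atomTable, probe = 1.4, pointDensity = 15,
                                  reference = maxSasaReference()) {
  out <- list()
  for (ch in unique(atomTable$chain)) {
    sub <- atomTable[atomTable$chain == ch, , drop = FALSE]
    missing <- setdiff(unique(sub$resname), names(reference))
    if (length(missing))
      stop("residue type(s) absent from max-SASA reference: ",
           paste(missing, collapse = ", "))
    sasa <- shrakeRupleySASA(sub, probe = probe, pointDensity = pointDensity)
    per <- aggregate(sasa, by = list(resno = sub$resno), FUN = sum)
    rn <- sub$resname[match(per$resno, sub$resno)]
    out[[ch]] <- data.frame(chain = ch, resno = per$resno, resname = rn,
                            sasa = per$x,
                            rel_access = per$x / reference[rn],
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
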