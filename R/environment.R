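#' Combine contact flags and accessibilities into environment annotations
#'
#' A residue is solvent-exposed when its relative accessibility is strictly
#' greater than `exposureThreshold`; the contacting/non-contacting split is
#' taken from crystal-contact detection. The two inputs must describe the
#' same residue universe.
#'
#' @param contacts data.frame from [detectContacts()].
#' @param accessibilities data.frame from [relativeAccessibility()].
#' @param exposureThreshold relative-accessibility cutoff (default 0.2,
#'   strict ">").
#' @return data.frame `chain`, `resno`, `resname`, `contacting`,
#'   `rel_access`, `exposed`.
#' @export
classifyEnvironment <- function(contacts, accessibilities,
                                exposureThreshold = 0.2) {
  kc <- paste(contacts$chain, contacts$resno)
  ka <- paste(accessibilities$chain, accessibilities$resno)
  if (!setequal(kc, ka))
    stop("residue sets differ between contacts and accessibilities: ",
         paste(c(setdiff(kc, ka), setdiff(ka, kc)), collapse = ", "))
  m <- match(kc, ka)
  data.frame(chain = contacts$chain, resno = contacts$resno,
             resname = contacts$resname, contacting = contacts$contacting,
             rel_access = accessibilities$rel_access[m],
             exposed = accessibilities$rel_access[m] > exposureThreshold,
             stringsAsFactors = FALSE)
}

#' Annotate every residue of a crystal structure
#'
#' One-call wrapper: detects crystal contacts on the full lattice, computes
#' per-chain relative accessibilities, and merges them into environment
#' annotations. Also marks which residues are rotameric (have chi angles and
#' are not disulfide-bonded cysteines).
#'
#' @param lattice a [LatticeModel-class].
#' @param contactCutoff heavy-atom contact distance, Angstrom (default 4.0).
#' @param probe SASA probe radius (default 1.4).
#' @param pointDensity SASA point density (default 15 per square Angstrom).
#' @param exposureThreshold relative-accessibility cutoff (default 0.2).
#' @param shell symmetry expansion shell (default 1).
#' @param excludeDisulfides flag CYS residues whose SG atoms are within
#'   `ssCutoff` of another SG as non-rotameric (default TRUE).
#' @param ssCutoff S-S bond distance cutoff, Angstrom (default 2.3).
#' @return data.frame `chain`, `resno`, `resname`, `contacting`,
#'   `rel_access`, `exposed`, `rotameric`.
#' @export
annotateEnvironment <- function(lattice, contactCutoff = 4.0, probe = 1.4,
                                pointDensity = 15, exposureThreshold = 0.2,
                                shell = 1, excludeDisulfides = TRUE,
                                ssCutoff = 2.3) {
  at <- atoms(lattice)
  ann <- classifyEnvironment(
    detectContacts(lattice, cutoff = contactCutoff, shell = shell),
    relativeAccessibility(at, probe = probe, pointDensity = pointDensity),
    exposureThreshold = exposureThreshold)
  ann$rotameric <- chiCount(ann$resname) > 0
  if (excludeDisulfides) {
    ss <- disulfideCysteines(at, ssCutoff = ssCutoff)
    if (nrow(ss))
      ann$rotameric[paste(ann$chain, ann$resno) %in%
                      paste(ss$chain, ss$resno)] <- FALSE
  }
  ann
}

#' Find disulfide-bonded cysteines
#'
#' @param atomTable heavy-atom data.frame.
#' @param ssCutoff SG-SG distance cutoff, Angstrom (default 2.3).
#' @return data.frame `chain`, `resno` of disulfide-bonded CYS residues.
#' @export
disulfideCysteines <- function(atomTable, ssCutoff = 2.3) {
  sg <- atomTable[atomTable$resname == "CYS" & atomTable$atom == "SG", ,
                  drop = FALSE]
  if (nrow(sg) < 2)
    return(data.frame(chain = character(0), resno = integer(0)))
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  bonded <- apply(d <= ssCutoff, 1, any)
  data.frame(chain = sg$chain[bonded], resno = sg$resno[bonded],
             row.names = NULL, stringsAsFactors = FALSE)
}
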