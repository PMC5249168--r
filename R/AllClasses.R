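#' Class "RotamerLibrary"
#'
#' An ordered catalogue of discrete side-chain rotamer states. Each state is
#' a vector of modal chi angles (degrees) for one residue type; states are
#' numbered 1..N per residue type in library order so state identifiers can
#' be compared against published histogram axes. Alanine and glycine carry
#' no chi angles and are never present.
#'
#' @slot table data.frame with columns `residue_type`, `state_id`,
#'   `state_name`, `n_chi`, `chi1`..`chi4` (NA for absent angles).
#' @export
setClass("RotamerLibrary", representation(table = "data.frame"))

setValidity("RotamerLibrary", function(object) {
  tab <- object@table
  need <- c("residue_type", "state_id", "state_name", "n_chi",
            paste0("chi", 1:4))
  if (!all(need %in% names(tab)))
    return(paste("missing columns:", paste(setdiff(need, names(tab)), collapse = ", ")))
  if (any(tab$residue_type %in% c("ALA", "GLY")))
    return("ALA and GLY have no rotamers and must not appear")
  for (rt in unique(tab$residue_type)) {
    sub <- tab[tab$residue_type == rt, ]
    if (!identical(sort(sub$state_id), seq_len(nrow(sub))))
      return(sprintf("state IDs for %s are not 1..%d without gaps", rt, nrow(sub)))
    if (length(unique(sub$n_chi)) != 1L)
      return(sprintf("inconsistent n_chi within %s", rt))
    nc <- sub$n_chi[1]
    chis <- as.matrix(sub[, paste0("chi", 1:4)])
    if (any(is.na(chis[, seq_len(nc), drop = FALSE])))
      return(sprintf("%s: NA among the first %d chi columns", rt, nc))
    if (nc < 4 && !all(is.na(chis[, seq(nc + 1, 4), drop = FALSE])))
      return(sprintf("%s: values beyond n_chi = %d", rt, nc))
    ang <- chis[, seq_len(nc), drop = FALSE]
    if (any(ang <= -180 | ang > 180))
      return(sprintf("%s: modal angle outside (-180, 180]", rt))
  }
  TRUE
})

#' Class "ChiTrajectory"
#'
#' Per-frame side-chain chi angles for one residue under one condition,
#' taken from one lattice copy (or the single solution chain). Frames are
#' time-ordered; angles are degrees in (-180, 180].
#'
#' @slot chain character, pooled chain label (e.g. "A").
#' @slot resno integer residue number (author numbering).
#' @slot restype three-letter residue type.
#' @slot condition "solution" or "crystal".
#' @slot chainCopy label of the lattice copy the series came from (e.g. "A1").
#' @slot frames numeric matrix, n_frames x n_chi.
#' @export
setClass("ChiTrajectory",
  representation(chain = "character", resno = "integer", restype = "character",
                 condition = "character", chainCopy = "character",
                 frames = "matrix"))

setValidity("ChiTrajectory", function(object) {
  if (!object@condition %in% c("solution", "crystal"))
    return("condition must be 'solution' or 'crystal'")
  f <- object@frames
  if (nrow(f) > 0) {
    if (any(!is.finite(f))) return("non-finite chi angle")
    if (any(f <= -180 | f > 180)) return("chi angle outside (-180, 180]")
  }
  TRUE
})

#' Class "RotamerStateSeries"
#'
#' The discretized counterpart of a [ChiTrajectory-class]: one library
#' state identifier per frame.
#'
#' @slot chain,resno,restype,condition,chainCopy as in [ChiTrajectory-class].
#' @slot states integer vector of state IDs, one per frame.
#' @export
setClass("RotamerStateSeries",
  representation(chain = "character", resno = "integer", restype = "character",
                 condition = "character", chainCopy = "character",
                 states = "integer"))

#' Class "RotamerDistribution"
#'
#' Normalized probabilities over the N library states of one residue under
#' one condition, pooled over lattice copies and restricted to the analysis
#' window.
#'
#' @slot chain,resno,restype,condition residue identity and condition.
#' @slot probabilities numeric vector of length N, sums to 1.
#' @slot nFrames integer, number of pooled frames behind the estimate.
#' @export
setClass("RotamerDistribution",
  representation(chain = "character", resno = "integer", restype = "character",
                 condition = "character", probabilities = "numeric",
                 nFrames = "integer"))

setValidity("RotamerDistribution", function(object) {
  p <- object@probabilities
  if (any(p < 0)) return("negative probability")
  if (abs(sum(p) - 1) > 1e-9) return("probabilities do not sum to 1")
  TRUE
})

#' Class "LatticeModel"
#'
#' An asymmetric unit plus the crystallographic frame needed to rebuild its
#' environment: unit-cell parameters and the space-group symbol. Atoms are
#' heavy atoms unless hydrogens were explicitly retained.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z` (Cartesian, Angstrom).
#' @slot spaceGroup character symbol, e.g. "P 1 21 1".
#' @slot cell numeric length-6: a, b, c (Angstrom), alpha, beta, gamma (deg).
#' @export
setClass("LatticeModel",
  representation(atoms = "data.frame", spaceGroup = "character",
                 cell = "numeric"))

setValidity("LatticeModel", function(object) {
  if (length(object@cell) != 6) return("cell must have 6 parameters")
  if (any(object@cell[1:3] <= 0)) return("cell lengths must be positive")
  if (any(object@cell[4:6] <= 0 | object@cell[4:6] >= 180))
    return("cell angles must lie in (0, 180)")
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms lacks columns:",
                 paste(setdiff(need, names(object@atoms)), collapse = ", ")))
  TRUE
})
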