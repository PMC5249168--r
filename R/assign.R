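#' Assign a chi vector to its nearest rotamer state
#'
#' The nearest state minimizes the maximum per-angle circular deviation
#' between the (folded) chi vector and each state's modal angles; ties are
#' broken toward the lowest state ID. The max-deviation metric mirrors the
#' per-angle tolerance logic used for rotamer agreement, so a chi vector
#' that matches a state within a uniform tolerance is always assigned to a
#' state at least that close.
#'
#' @param chis numeric chi vector, degrees.
#' @param residueType three-letter code.
#' @param library a [RotamerLibrary-class].
#' @param fold fold 2-fold-symmetric terminal angles before matching
#'   (default TRUE; modal library values already lie in the folded range).
#' @return integer state ID (1-based, library order).
#' @examples
#' lib <- loadRotamerLibrary()
#' assignRotamer(c(-65, 175), "LEU", lib)
#' @export
assignRotamer <- function(chis, residueType, library, fold = TRUE) {
  modal <- modalChis(library, residueType)
  if (length(chis) != ncol(modal))
    stop(residueType, " expects ", ncol(modal), " chi angles, got ",
         length(chis))
  if (fold) chis <- foldSymmetricChis(chis, residueType)
  dev <- .chiDeviation(matrix(chis, nrow(modal), ncol(modal), byrow = TRUE),
                       modal, residueType)
  score <- apply(dev, 1, max)
  which.min(score)  # which.min takes the first (lowest ID) on ties
}

# per-angle circular deviation between chi rows and modal rows; 2-fold
# symmetric terminal angles are compared with period 180 so the two
# equivalent labelings are equidistant from every state
.chiDeviation <- function(chiRows, modalRows, residueType) {
  d <- matrix(circularDistance(chiRows, modalRows), nrow(chiRows))
  k <- .SYMMETRIC_CHI[residueType]
  if (!is.na(k) && k <= ncol(chiRows))
    d[, k] <- pmin(d[, k], 180 - d[, k])
  d
}

#' Discretize a chi trajectory into a rotamer state series
#'
#' @param traj a [ChiTrajectory-class].
#' @param library a [RotamerLibrary-class].
#' @return a [RotamerStateSeries-class] of the same length.
#' @export
assignSeries <- function(traj, library) {
  f <- frames(traj)
  rt <- traj@restype
  modal <- modalChis(library, rt)
  if (nrow(f) > 0 && ncol(f) != ncol(modal))
    stop(rt, " expects ", ncol(modal), " chi angles, trajectory has ",
         ncol(f))
  st <- integer(nrow(f))
  if (nrow(f) > 0) {
    folded <- wrapAngle(f)
    k <- .SYMMETRIC_CHI[rt]
    if (!is.na(k) && k <= ncol(folded)) {
      v <- folded[, k]
      folded[, k] <- v - 180 * ceiling((v - 90) / 180)
    }
    # frames x states maximum per-angle deviation, built one chi at a time
    worst <- matrix(0, nrow(folded), nrow(modal))
    for (j in seq_len(ncol(modal))) {
      d <- circularDistance(outer(folded[, j], modal[, j], "-"), 0)
      if (!is.na(k) && j == k) d <- pmin(d, 180 - d)
      worst <- pmax(worst, d)
    }
    st <- max.col(-worst, ties.method = "first")
  }
  new("RotamerStateSeries", chain = traj@chain, resno = traj@resno,
      restype = rt, condition = traj@condition, chainCopy = traj@chainCopy,
      states = as.integer(st))
}

#' Per-angle tolerance match between a chi vector and a rotamer state
#'
#' TRUE iff every chi angle lies within `tol` degrees (circular distance)
#' of the state's modal angle: each angle must match for the conformation
#' to count as the same rotamer.
#'
#' @param chis numeric chi vector, degrees.
#' @param residueType three-letter code.
#' @param stateId integer state ID.
#' @param library a [RotamerLibrary-class].
#' @param tol tolerance in degrees (default 30).
#' @param fold fold symmetric terminal angles first (default TRUE).
#' @export
matchesWithinTolerance <- function(chis, residueType, stateId, library,
                                   tol = 30, fold = TRUE) {
  modal <- modalChis(library, residueType)
  if (stateId < 1 || stateId > nrow(modal))
    stop("state ", stateId, " not defined for ", residueType)
  if (length(chis) != ncol(modal))
    stop("chi vector length mismatch for ", residueType)
  if (fold) chis <- foldSymmetricChis(chis, residueType)
  dev <- .chiDeviation(matrix(chis, nrow = 1),
                       modal[stateId, , drop = FALSE], residueType)
  all(dev <= tol)
}
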