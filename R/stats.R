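#' Build a rotamer probability distribution
#'
#' Counts library states over the selected frame window, pooled across one
#' or more state series (e.g. the two identical lattice copies A1 and A2),
#' and normalizes. States never visited keep probability zero.
#'
#' @param seriesList a [RotamerStateSeries-class] or list of them sharing
#'   residue identity and condition.
#' @param library a [RotamerLibrary-class] (defines the state count N).
#' @param window frame selection applied to each series before pooling:
#'   NULL (all frames), the string "lastHalf", or an integer index vector.
#' @param stride keep every `stride`-th frame of the window (default 1).
#' @return a [RotamerDistribution-class].
#' @export
buildDistribution <- function(seriesList, library, window = NULL,
                              stride = 1L) {
  if (is(seriesList, "RotamerStateSeries")) seriesList <- list(seriesList)
  stopifnot(length(seriesList) > 0)
  ref <- seriesList[[1]]
  for (s in seriesList)
    if (s@restype != ref@restype || s@resno != ref@resno ||
        s@chain != ref@chain || s@condition != ref@condition)
      stop("all series must share residue identity and condition")
  N <- nStates(library, ref@restype)
  counts <- numeric(N)
  pooled <- 0L
  for (s in seriesList) {
    idx <- windowFrames(length(s@states), window, stride)
    if (length(idx) == 0L) stop("empty frame window")
    st <- s@states[idx]
    counts <- counts + tabulate(st, nbins = N)
    pooled <- pooled + length(st)
  }
  new("RotamerDistribution", chain = ref@chain, resno = ref@resno,
      restype = ref@restype, condition = ref@condition,
      probabilities = counts / pooled, nFrames = as.integer(pooled))
}

#' Resolve a frame window specification
#'
#' @param n number of frames available.
#' @param window NULL (all), "lastHalf", or integer indices.
#' @param stride keep every `stride`-th selected frame.
#' @return integer frame indices.
#' @export
windowFrames <- function(n, window = NULL, stride = 1L) {
  idx <- if (is.null(window)) seq_len(n)
    else if (identical(window, "lastHalf")) seq(floor(n / 2) + 1L, n)
    else as.integer(window)
  if (any(idx < 1L | idx > n)) stop("window indices out of range")
  if (length(idx) == 0L) return(integer(0))
  idx[seq(1L, length(idx), by = as.integer(stride))]
}

#' Overlap coefficient between two discrete distributions
#'
#' OC = sum_i min(p_i, q_i); 1 for identical distributions, 0 for disjoint
#' supports. Equivalently 1 minus half the L1 distance.
#'
#' @param p,q probability vectors over the same states, or
#'   [RotamerDistribution-class] objects.
#' @export
overlapCoefficient <- function(p, q) {
  p <- .asProbs(p); q <- .asProbs(q)
  if (length(p) != length(q)) stop("distributions have different lengths")
  sum(pmin(p, q))
}

.asProbs <- function(x) if (is(x, "RotamerDistribution")) x@probabilities else x

#' Kullback-Leibler divergence KL(p || q) in nats
#'
#' A pseudocount is added to every bin of both distributions (then
#' renormalized) before taking the divergence, so finite values are
#' returned when q has empty bins. With `pseudocount = 0` the raw
#' divergence is returned and may be +Inf.
#'
#' @param p,q probability vectors or [RotamerDistribution-class] objects.
#' @param pseudocount per-bin smoothing mass (default 0).
#' @export
klDivergence <- function(p, q, pseudocount = 0) {
  p <- .asProbs(p); q <- .asProbs(q)
  if (length(p) != length(q)) stop("distributions have different lengths")
  stopifnot(pseudocount >= 0)
  if (pseudocount > 0) {
    p <- (p + pseudocount) / (1 + length(p) * pseudocount)
    q <- (q + pseudocount) / (1 + length(q) * pseudocount)
  }
  i <- p > 0
  if (any(q[i] == 0)) {
    warning("KL divergence is infinite: q has zero mass where p > 0")
    return(Inf)
  }
  sum(p[i] * log(p[i] / q[i]))
}

#' Configurational entropy of a rotamer distribution, reported as T*S
#'
#' S = -kB * sum_i p_i ln p_i over rotamer-state probabilities (0 ln 0 = 0),
#' the inter-well component of side-chain conformational entropy; the
#' intra-well thermal term is assumed identical across states and is not
#' computed, since it cancels in condition differences. Returned as T*S in
#' kcal/mol.
#'
#' @param p probability vector or [RotamerDistribution-class].
#' @param temperature Kelvin (default 300).
#' @param kB Boltzmann constant, kcal/(mol K) (default 0.0019872).
#' @export
confEntropy <- function(p, temperature = entropyConstants$temperature,
                        kB = entropyConstants$kB) {
  p <- .asProbs(p)
  i <- p > 0
  temperature * (-kB * sum(p[i] * log(p[i])))
}

#' Configurational entropy difference between conditions
#'
#' T * (S_crystal - S_solution) in kcal/mol; negative values mean the
#' side chain samples fewer/narrower rotamer states in the crystal.
#'
#' @param pSolution,pCrystal probability vectors or
#'   [RotamerDistribution-class] objects.
#' @inheritParams confEntropy
#' @export
deltaEntropy <- function(pSolution, pCrystal,
                         temperature = entropyConstants$temperature,
                         kB = entropyConstants$kB) {
  confEntropy(pCrystal, temperature, kB) -
    confEntropy(pSolution, temperature, kB)
}

#' Null-model-normalized likelihood score
#'
#' Average over residues of P_i(x_i_xray) / (1/N_i): how much more likely
#' the simulation is to show the X-ray rotamer than a null model in which
#' all N_i states of residue i are equally accessible. Scores above 1 mean
#' better-than-random correspondence with the X-ray conformations.
#'
#' @param dists list of [RotamerDistribution-class] for one condition.
#' @param xrayStates integer vector (parallel to `dists`) of X-ray state
#'   IDs; NA entries are excluded with a warning.
#' @return the average likelihood score L.
#' @export
likelihoodScore <- function(dists, xrayStates) {
  stopifnot(length(dists) == length(xrayStates))
  keep <- !is.na(xrayStates)
  if (any(!keep))
    warning(sum(!keep), " residue(s) without an X-ray state excluded")
  if (!any(keep)) stop("no residues with X-ray states")
  ratios <- mapply(function(d, x) {
    p <- .asProbs(d)
    p[x] * length(p)
  }, dists[keep], xrayStates[keep])
  mean(ratios)
}

#' Quotient of crystal and solution likelihood scores
#'
#' Values above 1 indicate that the crystal-condition ensembles match the
#' X-ray conformations more closely than the solution ensembles do.
#'
#' @param lCrystal,lSolution likelihood scores from [likelihoodScore()].
#' @export
likelihoodQuotient <- function(lCrystal, lSolution) {
  if (lSolution == 0)
    stop("solution likelihood is zero; quotient undefined")
  lCrystal / lSolution
}

#' Top sampled rotamer states of a distribution
#'
#' The `k` states with the greatest sampled probability; states tied with
#' the k-th count are all included, and never-visited (zero-probability)
#' states are never returned.
#'
#' @param dist probability vector or [RotamerDistribution-class].
#' @param k number of dominant states (default 2).
#' @return integer state IDs.
#' @export
dominantStates <- function(dist, k = 2) {
  p <- .asProbs(dist)
  pos <- which(p > 0)
  if (length(pos) <= k) return(pos)
  thr <- sort(p[pos], decreasing = TRUE)[k]
  pos[p[pos] >= thr]
}

#' Agreement between a simulated ensemble and the X-ray rotamer
#'
#' TRUE when the X-ray conformation corresponds to one of the two most
#' dominant rotamers sampled in the ensemble. By default the comparison is
#' between assigned state IDs (the X-ray chi vector having been assigned to
#' its nearest state); alternatively, with `mode = "tolerance"` and the raw
#' X-ray chi vector supplied, the X-ray conformation counts as a given state
#' only when every chi angle matches that state's modal value within `tol`.
#'
#' @param dist [RotamerDistribution-class] (or probability vector plus
#'   `residueType`).
#' @param xrayState integer X-ray state ID (mode "state").
#' @param xrayChis numeric X-ray chi vector (mode "tolerance").
#' @param library a [RotamerLibrary-class] (mode "tolerance").
#' @param residueType residue type; taken from `dist` when it is a
#'   [RotamerDistribution-class].
#' @param mode "state" (default) or "tolerance".
#' @param tol per-angle tolerance in degrees (default 30).
#' @param k number of dominant states considered (default 2).
#' @export
rotamerAgreement <- function(dist, xrayState = NA_integer_, xrayChis = NULL,
                             library = NULL, residueType = NULL,
                             mode = c("state", "tolerance"), tol = 30,
                             k = 2) {
  mode <- match.arg(mode)
  top <- dominantStates(dist, k = k)
  if (mode == "state") {
    if (is.na(xrayState)) return(NA)
    return(xrayState %in% top)
  }
  if (is.null(xrayChis) || is.null(library))
    stop("tolerance mode needs xrayChis and library")
  if (is.null(residueType)) residueType <- dist@restype
  any(vapply(top, function(s)
    matchesWithinTolerance(xrayChis, residueType, s, library, tol = tol),
    logical(1)))
}

#' Classify a residue into a conformation/dynamics region
#'
#' Quadrants of the (OC, T*dS) plane: region I, crystal has little effect
#' on conformation or dynamics (high overlap, small entropy change);
#' II, conformation changes but dynamics is similar; III, both change;
#' IV, dynamics changes while the conformation is maintained. Boundaries
#' are inclusive toward region I.
#'
#' @param oc overlap coefficient in [0, 1].
#' @param tds T*dS_conf in kcal/mol.
#' @param ocBoundary overlap boundary (default 0.5).
#' @param tdsBoundary absolute entropy-change boundary, kcal/mol
#'   (default 0.5).
#' @return factor level among "I", "II", "III", "IV" (vectorized).
#' @export
classifyRegion <- function(oc, tds, ocBoundary = 0.5, tdsBoundary = 0.5) {
  stopifnot(all(oc >= 0 & oc <= 1))
  confSame <- oc >= ocBoundary
  dynSame <- abs(tds) <= tdsBoundary
  out <- ifelse(confSame & dynSame, "I",
         ifelse(!confSame & dynSame, "II",
         ifelse(!confSame & !dynSame, "III", "IV")))
  factor(out, levels = c("I", "II", "III", "IV"))
}

#' Two-segment uncertainty estimate
#'
#' Recomputes a per-residue statistic (OC or T*dS) on two equal-length,
#' non-overlapping halves of the analysis window of every series (an odd
#' window gives the first half the extra frame) and reports the min/max of
#' the two as lower/upper bounds, plus the Pearson correlation of the
#' per-residue values between the halves as a sampling-adequacy summary.
#'
#' @param solutionSeries,crystalSeries lists (one element per residue) of
#'   [RotamerStateSeries-class] or lists of them (lattice copies).
#' @param library a [RotamerLibrary-class].
#' @param statistic "oc" or "tds".
#' @param window window applied to each series before halving.
#' @inheritParams confEntropy
#' @return list with `bounds` (data.frame `low`, `high`, `half1`, `half2`,
#'   one row per residue) and `r` (Pearson correlation across residues).
#' @export
segmentUncertainty <- function(solutionSeries, crystalSeries, library,
                               statistic = c("oc", "tds"), window = NULL,
                               temperature = entropyConstants$temperature,
                               kB = entropyConstants$kB) {
  statistic <- match.arg(statistic)
  stopifnot(length(solutionSeries) == length(crystalSeries))
  halves <- function(s, half) {
    if (is(s, "RotamerStateSeries")) s <- list(s)
    lapply(s, function(one) {
      idx <- windowFrames(length(one@states), window)
      if (length(idx) < 2L) stop("need at least 2 frames to split")
      cutp <- ceiling(length(idx) / 2)
      pick <- if (half == 1L) idx[seq_len(cutp)]
              else idx[seq(cutp + 1L, length(idx))]
      new("RotamerStateSeries", chain = one@chain, resno = one@resno,
          restype = one@restype, condition = one@condition,
          chainCopy = one@chainCopy, states = one@states[pick])
    })
  }
  evalHalf <- function(i, half) {
    ds <- buildDistribution(halves(solutionSeries[[i]], half), library)
    dc <- buildDistribution(halves(crystalSeries[[i]], half), library)
    if (statistic == "oc") overlapCoefficient(ds, dc)
    else deltaEntropy(ds, dc, temperature, kB)
  }
  n <- length(solutionSeries)
  h1 <- vapply(seq_len(n), evalHalf, numeric(1), half = 1L)
  h2 <- vapply(seq_len(n), evalHalf, numeric(1), half = 2L)
  list(bounds = data.frame(low = pmin(h1, h2), high = pmax(h1, h2),
                           half1 = h1, half2 = h2),
       r = if (n >= 3 && sd(h1) > 0 && sd(h2) > 0) cor(h1, h2) else NA_real_)
}

#' Set-level summaries of the per-residue comparisons
#'
#' Aggregates a per-residue comparison table into one row per
#' (chain, residue set), for the sets "all" (all solvent-exposed rotameric
#' residues), "cont" (the exposed contacting subset) and "non-cont" (the
#' exposed non-contacting subset): residue counts, likelihood scores and
#' their crystal/solution quotient, mean and population standard deviation
#' of OC and T*dS, and percent X-ray agreement under both conditions.
#'
#' @param comparisons data.frame with per-residue columns `chain`, `resno`,
#'   `contacting`, `exposed`, `oc`, `tds`, `agree_solution`,
#'   `agree_crystal`, `p_xray_solution`, `p_xray_crystal`, `n_states`.
#' @return data.frame, one row per (chain, set).
#' @export
summarizeSets <- function(comparisons) {
  popSD <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- list()
  for (ch in unique(comparisons$chain)) {
    sub <- comparisons[comparisons$chain == ch & comparisons$exposed, ,
                       drop = FALSE]
    for (set in c("all", "cont", "non-cont")) {
      grp <- switch(set, all = sub,
                    cont = sub[sub$contacting, , drop = FALSE],
                    `non-cont` = sub[!sub$contacting, , drop = FALSE])
      if (nrow(grp) == 0L) {
        warning("empty residue set ", ch, "/", set, " omitted")
        next
      }
      lS <- mean(grp$p_xray_solution * grp$n_states)
      lC <- mean(grp$p_xray_crystal * grp$n_states)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, residue_set = set, n_residues = nrow(grp),
        likelihood_solution = lS, likelihood_crystal = lC,
        likelihood_quotient = likelihoodQuotient(lC, lS),
        mean_oc = mean(grp$oc), sd_oc = popSD(grp$oc),
        mean_tds = mean(grp$tds), sd_tds = popSD(grp$tds),
        pct_agreement_solution = 100 * mean(grp$agree_solution),
        pct_agreement_crystal = 100 * mean(grp$agree_crystal),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Residue-type composition of residue sets
#'
#' Normalized residue-type frequencies within each annotation set
#' (contacting / non-contacting among exposed rotameric residues), ordered
#' by library state count (more rotamers first).
#'
#' @param annotations data.frame with `resname`, `contacting`, `exposed`,
#'   `rotameric`.
#' @param library a [RotamerLibrary-class] (for the ordering).
#' @return data.frame `set`, `resname`, `n`, `frequency`.
#' @export
residueComposition <- function(annotations, library) {
  sub <- annotations[annotations$exposed & annotations$rotameric, ,
                     drop = FALSE]
  counts <- vapply(residueTypes(library), function(rt)
    nStates(library, rt), integer(1))
  ord <- names(sort(counts, decreasing = TRUE))
  rows <- list()
  for (set in c("cont", "non-cont")) {
    grp <- if (set == "cont") sub[sub$contacting, , drop = FALSE]
           else sub[!sub$contacting, , drop = FALSE]
    if (nrow(grp) == 0L) next
    tab <- table(factor(grp$resname, levels = ord))
    tab <- tab[tab > 0]
    rows[[set]] <- data.frame(set = set, resname = names(tab),
                              n = as.integer(tab),
                              frequency = as.numeric(tab) / nrow(grp),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
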