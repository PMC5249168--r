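#' Specification for a synthetic side-chain ensemble
#'
#' Describes a stationary per-residue rotamer-sampling process: a
#' categorical mixture over the residue's library states with
#' wrapped-Gaussian within-well noise on each chi angle. This emulates the
#' marginal behaviour of a well-equilibrated trajectory window; it carries
#' no autocorrelation unless `stickiness > 0`, in which case frames follow
#' a sticky Markov chain whose stationary distribution is still
#' `mixtureWeights`.
#'
#' @param residueType three-letter code present in the library.
#' @param mixtureWeights probability vector over the residue's N states.
#' @param noiseSD within-well wrapped-Gaussian SD in degrees (default 8;
#'   truncated at 3 SD before wrapping so wells stay separable).
#' @param nFrames number of frames (default 1000).
#' @param condition "solution" or "crystal".
#' @param chain,chainCopy,resno labels for the emitted trajectory.
#' @param stickiness probability of copying the previous frame's state
#'   instead of redrawing (default 0, i.e. independent frames).
#' @return list of class "EnsembleSpec".
#' @export
ensembleSpec <- function(residueType, mixtureWeights, noiseSD = 8,
                         nFrames = 1000L, condition = "solution",
                         chain = "A", chainCopy = chain, resno = 1L,
                         stickiness = 0) {
  stopifnot(noiseSD >= 0, nFrames >= 1, all(mixtureWeights >= 0),
            stickiness >= 0, stickiness < 1)
  if (abs(sum(mixtureWeights) - 1) > 1e-9)
    stop("mixtureWeights must sum to 1")
  structure(list(residueType = residueType,
                 mixtureWeights = mixtureWeights, noiseSD = noiseSD,
                 nFrames = as.integer(nFrames), condition = condition,
                 chain = chain, chainCopy = chainCopy,
                 resno = as.integer(resno), stickiness = stickiness),
            class = "EnsembleSpec")
}

# truncated normal via rejection: values beyond 3 SD are redrawn
.truncNorm <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  x <- rnorm(n, 0, sd)
  bad <- which(abs(x) > 3 * sd)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > 3 * sd]
  }
  x
}

#' Generate a synthetic chi-angle trajectory
#'
#' Each frame draws a state from the mixture (or carries the previous state
#' with probability `stickiness`), then perturbs every modal chi angle with
#' truncated wrapped-Gaussian noise and wraps into (-180, 180].
#'
#' @param spec an [ensembleSpec()].
#' @param library a [RotamerLibrary-class].
#' @param seed integer seed; the generator is deterministic given
#'   (spec, seed).
#' @return list with `trajectory` (a [ChiTrajectory-class]) and `states`
#'   (the true generating state per frame).
#' @export
generateTorsionTrajectory <- function(spec, library, seed = 1L) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  modal <- modalChis(library, spec$residueType)
  N <- nrow(modal)
  if (length(spec$mixtureWeights) != N)
    stop("mixtureWeights has length ", length(spec$mixtureWeights),
         " but ", spec$residueType, " has ", N, " states")
  set.seed(as.integer(seed))
  n <- spec$nFrames
  st <- integer(n)
  draw <- sample.int(N, n, replace = TRUE, prob = spec$mixtureWeights)
  if (spec$stickiness > 0) {
    keep <- runif(n) < spec$stickiness
    st[1] <- draw[1]
    for (i in seq_len(n)[-1]) st[i] <- if (keep[i]) st[i - 1] else draw[i]
  } else st <- draw
  f <- modal[st, , drop = FALSE]
  noise <- matrix(.truncNorm(length(f), spec$noiseSD), nrow = n)
  f <- wrapAngle(f + noise)
  dimnames(f) <- NULL
  list(trajectory = new("ChiTrajectory", chain = spec$chain,
                        resno = spec$resno, restype = spec$residueType,
                        condition = spec$condition,
                        chainCopy = spec$chainCopy, frames = f),
       states = st)
}

#' Generate a matched solution/crystal trajectory pair with ground truth
#'
#' Draws one trajectory per condition from the two mixture specifications
#' and returns the closed-form overlap coefficient and entropy difference
#' of the true mixtures, for parameter-recovery testing.
#'
#' @param specSolution,specCrystal [ensembleSpec()]s for the same residue
#'   type.
#' @param library a [RotamerLibrary-class].
#' @param seed integer seed (the two conditions use derived sub-seeds).
#' @inheritParams confEntropy
#' @return list `solution`, `crystal` (each as returned by
#'   [generateTorsionTrajectory()]), `ocTrue`, `tdsTrue`.
#' @export
generateConditionPair <- function(specSolution, specCrystal, library,
                                  seed = 1L,
                                  temperature = entropyConstants$temperature,
                                  kB = entropyConstants$kB) {
  if (specSolution$residueType != specCrystal$residueType)
    stop("condition pair must share a residue type")
  ws <- specSolution$mixtureWeights; wc <- specCrystal$mixtureWeights
  seed <- as.integer(seed)
  list(solution = generateTorsionTrajectory(specSolution, library,
                                            seed = seed * 2L),
       crystal = generateTorsionTrajectory(specCrystal, library,
                                           seed = seed * 2L + 1L),
       ocTrue = sum(pmin(ws, wc)),
       tdsTrue = deltaEntropy(ws, wc, temperature, kB))
}

#' Select mutually well-separated rotamer states
#'
#' Greedily picks library states of a residue type whose pairwise
#' separation under the max-per-angle circular metric is at least `minSep`
#' degrees. With within-well noise truncated at 3 SD, mixtures over states
#' separated by more than 6 SD plus the truncation width can never be
#' misassigned, so empirical state frequencies estimate the mixture weights
#' with purely binomial error - the regime parameter-recovery experiments
#' assume.
#'
#' @param library a [RotamerLibrary-class].
#' @param residueType three-letter code.
#' @param minSep minimum pairwise separation in degrees (default 50).
#' @return integer state IDs, in library order.
#' @export
wellSeparatedStates <- function(library, residueType, minSep = 50) {
  modal <- modalChis(library, residueType)
  sep <- function(i, j)
    max(.chiDeviation(modal[i, , drop = FALSE],
                      modal[j, , drop = FALSE], residueType))
  keep <- integer(0)
  for (i in seq_len(nrow(modal))) {
    if (all(vapply(keep, function(j) sep(i, j) >= minSep, logical(1))))
      keep <- c(keep, i)
  }
  keep
}

#' Specification for a toy mini-crystal
#'
#' A single pseudo-residue chain placed in a unit cell so that the set of
#' crystal-contacting residues is known by construction, for exercising
#' symmetry expansion and contact detection end to end.
#'
#' @param nResidues pseudo-residues in the chain (each a CA plus a CB-like
#'   atom).
#' @param gap closest heavy-atom distance to the neighboring lattice copy
#'   along the packing direction, Angstrom.
#' @param spacing intra-chain residue spacing, Angstrom (default 3.8).
#' @param padding cell padding in the non-packing directions, Angstrom
#'   (default 30, large enough that only the packing direction can make
#'   contacts).
#' @param spaceGroup "P1" or "P21".
#' @return list of class "MiniCrystalSpec".
#' @export
miniCrystalSpec <- function(nResidues = 10L, gap = 3.5, spacing = 3.8,
                            padding = 30, spaceGroup = "P1") {
  stopifnot(gap >= 0, nResidues >= 2)
  structure(list(nResidues = as.integer(nResidues), gap = gap,
                 spacing = spacing, padding = padding,
                 spaceGroup = .normalizeSpaceGroup(spaceGroup)),
            class = "MiniCrystalSpec")
}

#' Build a toy mini-crystal with truth annotations
#'
#' The chain runs along x; the cell's a axis equals the chain extent plus
#' `gap`, so across the x faces the closest approach between copies is
#' exactly `gap` (P1). Truth contact flags are computed by direct
#' enumeration of all atom pairs between the chain and every neighbor copy
#' - an independent, brute-force path that does not use
#' [detectContacts()]'s box-filtered search.
#'
#' @param spec a [miniCrystalSpec()].
#' @param cutoff contact cutoff used for the truth flags (default 4.0).
#' @param shell neighbor shell used for the truth enumeration (default 1).
#' @return list with `lattice` (a [LatticeModel-class]) and `truth`
#'   (data.frame `chain`, `resno`, `resname`, `contacting`).
#' @export
generateMiniCrystal <- function(spec, cutoff = 4.0, shell = 1) {
  stopifnot(inherits(spec, "MiniCrystalSpec"))
  n <- spec$nResidues
  xs <- (seq_len(n) - 1L) * spec$spacing
  at <- data.frame(
    chain = "A", resno = rep(seq_len(n), each = 2L), resname = "GLY",
    atom = rep(c("CA", "CB"), n), element = "C",
    x = rep(xs, each = 2L), y = rep(c(0, 1.5), n),
    z = 0, stringsAsFactors = FALSE)
  ext <- max(xs) - min(xs)
  cellA <- ext + spec$gap
  # keep b, c wide so only a-axis translations can reach the cutoff;
  # the P21 screw along b needs extra clearance for the rotated mate
  pad <- spec$padding + if (spec$spaceGroup == "P21") 2 * spec$gap else 0
  cell <- c(cellA, ext + pad, ext + pad, 90, 90, 90)
  # center the chain in y/z so rotated mates stay remote
  at$y <- at$y + cell[2] / 2
  at$z <- at$z + cell[3] / 2
  lattice <- new("LatticeModel", atoms = at,
                 spaceGroup = spec$spaceGroup, cell = cell)
  truth <- .bruteForceContacts(lattice, cutoff = cutoff, shell = shell)
  list(lattice = lattice, truth = truth)
}

# independent all-pairs contact oracle: enumerates every neighbor-copy atom
# and takes plain pairwise distances, no prefiltering
.bruteForceContacts <- function(lattice, cutoff = 4.0, shell = 1) {
  asu <- .heavy(atoms(lattice))
  res <- unique(asu[, c("chain", "resno", "resname")])
  nb <- expandNeighbors(lattice, shell = shell)
  axyz <- as.matrix(asu[, c("x", "y", "z")])
  touched <- logical(nrow(asu))
  for (cp in nb) {
    h <- .heavy(cp$atoms)
    for (i in seq_len(nrow(asu))) {
      d2 <- (h$x - axyz[i, 1])^2 + (h$y - axyz[i, 2])^2 +
            (h$z - axyz[i, 3])^2
      if (any(d2 <= cutoff^2 + 1e-9)) touched[i] <- TRUE
    }
  }
  key <- paste(asu$chain, asu$resno)
  res$contacting <- paste(res$chain, res$resno) %in% unique(key[touched])
  res
}

#' Write a mini-crystal to a PDB file
#'
#' Emits ATOM records plus a CRYST1 record so the file round-trips through
#' [readLattice()].
#'
#' @param lattice a [LatticeModel-class].
#' @param path output file.
#' @export
writeLatticePDB <- function(lattice, path) {
  at <- atoms(lattice)
  cell <- cellParameters(lattice)
  sg <- spaceGroup(lattice)
  sgOut <- c(P1 = "P 1", P21 = "P 1 21 1", P212121 = "P 21 21 21",
             C2 = "C 1 2 1")[.normalizeSpaceGroup(sg)]
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11sZ", cell[1],
                   cell[2], cell[3], cell[4], cell[5], cell[6], sgOut)
  lines <- vapply(seq_len(nrow(at)), function(i) {
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, at$atom[i], at$resname[i], at$chain[i], at$resno[i],
            at$x[i], at$y[i], at$z[i], at$element[i])
  }, character(1))
  writeLines(c(cryst, lines, "END"), path)
}
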