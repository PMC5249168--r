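#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' common crystallographic practice: 4 Angstrom heavy-atom contacts, a
#' 1.4 Angstrom water probe at 15 points per square Angstrom, exposure at
#' relative accessibility > 0.2, a 30-degree per-angle agreement tolerance,
#' entropy reporting at 300 K, region boundaries at OC 0.5 and 0.5 kcal/mol,
#' and analysis over the last half of frames.
#'
#' @param contactCutoff heavy-atom crystal-contact cutoff, Angstrom.
#' @param probe SASA probe radius, Angstrom.
#' @param pointDensity SASA point density, points per square Angstrom.
#' @param exposureThreshold relative-accessibility exposure cutoff.
#' @param agreementTolerance per-angle rotamer identity tolerance, degrees.
#' @param temperature entropy reporting temperature, Kelvin.
#' @param ocBoundary,tdsBoundary region-classification boundaries.
#' @param window frame window ("lastHalf", NULL for all, or indices).
#' @param stride keep every stride-th frame of the window.
#' @param pooling named character vector mapping chain-copy labels to pooled
#'   chains (e.g. c(A1 = "A", A2 = "A")); NULL pools by the table's `chain`
#'   column.
#' @param altLoc alternate-location conformer used for X-ray chi angles.
#' @param klPseudocount KL smoothing mass per bin; NULL means 1/n_frames.
#' @param agreementMode "state" or "tolerance" (see [rotamerAgreement()]).
#' @param shell symmetry expansion shell for contact detection.
#' @param seed integer seed recorded in the manifest.
#' @return list of class "RunConfig".
#' @export
runConfig <- function(contactCutoff = 4.0, probe = 1.4, pointDensity = 15,
                      exposureThreshold = 0.2, agreementTolerance = 30,
                      temperature = 300, ocBoundary = 0.5,
                      tdsBoundary = 0.5, window = "lastHalf", stride = 1L,
                      pooling = NULL, altLoc = "A", klPseudocount = NULL,
                      agreementMode = "state", shell = 1L, seed = 1L) {
  stopifnot(contactCutoff > 0, probe > 0, pointDensity > 0,
            exposureThreshold >= 0, agreementTolerance >= 0,
            temperature > 0)
  structure(as.list(environment()), class = "RunConfig")
}

#' Read a chi-angle table
#'
#' The interchange dialect is tab-separated with a header row and columns
#' `condition`, `chain_copy`, `chain`, `resnum`, `resname`, `frame`,
#' `chi1`..`chi4` (empty cells for absent angles, degrees otherwise).
#' Rows are grouped into one [ChiTrajectory-class] per (condition,
#' chain_copy, chain, residue), frames ordered by the `frame` column.
#'
#' @param path file path.
#' @return list of [ChiTrajectory-class] objects.
#' @export
readChiTable <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("chi table '", path, "' has no data rows")
  need <- c("condition", "chain_copy", "chain", "resnum", "resname",
            "frame", paste0("chi", 1:4))
  if (!all(need %in% names(tab)))
    stop("chi table missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  key <- paste(tab$condition, tab$chain_copy, tab$chain, tab$resnum,
               tab$frame)
  if (anyDuplicated(key))
    stop("duplicate (condition, copy, residue, frame) row(s), first at ",
         which(duplicated(key))[1])
  grp <- paste(tab$condition, tab$chain_copy, tab$chain, tab$resnum)
  lapply(split(seq_len(nrow(tab)), grp), function(i) {
    sub <- tab[i[order(tab$frame[i])], , drop = FALSE]
    rt <- sub$resname[1]
    nc <- chiCount(rt)
    if (nc == 0L)
      stop("residue type ", rt, " has no chi angles; row for residue ",
           sub$chain[1], ":", sub$resnum[1])
    f <- as.matrix(sub[, paste0("chi", seq_len(nc)), drop = FALSE])
    if (anyNA(f))
      stop("missing chi value(s) for ", rt, " ", sub$chain[1], ":",
           sub$resnum[1])
    dimnames(f) <- NULL
    new("ChiTrajectory", chain = sub$chain[1],
        resno = as.integer(sub$resnum[1]), restype = rt,
        condition = sub$condition[1], chainCopy = sub$chain_copy[1],
        frames = wrapAngle(f))
  })
}

#' Write chi trajectories as a chi-angle table
#'
#' @param trajectories list of [ChiTrajectory-class].
#' @param path output file.
#' @export
writeChiTable <- function(trajectories, path) {
  if (is(trajectories, "ChiTrajectory")) trajectories <- list(trajectories)
  rows <- lapply(trajectories, function(tr) {
    f <- frames(tr)
    chis <- matrix(NA_real_, nrow(f), 4)
    if (ncol(f) > 0) chis[, seq_len(ncol(f))] <- f
    data.frame(condition = tr@condition, chain_copy = tr@chainCopy,
               chain = tr@chain, resnum = tr@resno, resname = tr@restype,
               frame = seq_len(nrow(f)), chi1 = chis[, 1], chi2 = chis[, 2],
               chi3 = chis[, 3], chi4 = chis[, 4],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a crystal structure and derive X-ray rotamer assignments
#'
#' Wraps [readLattice()] and adds per-residue X-ray chi vectors and their
#' nearest rotamer states. Residues modelled with alternate locations use
#' the conformer selected by `altLoc` for the primary assignment; the other
#' conformer's state is retained as an alternate. Alanine/glycine,
#' disulfide-bonded cysteines and residues with missing side-chain atoms
#' are recorded as excluded with machine-readable reasons.
#'
#' @param path PDB file.
#' @param library a [RotamerLibrary-class].
#' @param altLoc conformer used for the primary X-ray state (default "A").
#' @param ssCutoff disulfide SG-SG cutoff, Angstrom (default 2.3).
#' @return list with `lattice` ([LatticeModel-class]), `xray` (data.frame
#'   `chain`, `resno`, `resname`, `chi1`..`chi4`, `state_id`,
#'   `alt_state_id`) and `excluded` (data.frame `chain`, `resno`,
#'   `resname`, `reason`).
#' @export
readStructure <- function(path, library = loadRotamerLibrary(),
                          altLoc = "A", ssCutoff = 2.3) {
  lattice <- readLattice(path, altLoc = altLoc)
  at <- atoms(lattice)
  altChar <- setdiff(c("A", "B"), altLoc)[1]
  altLat <- tryCatch(readLattice(path, altLoc = altChar),
                     error = function(e) NULL)
  ss <- disulfideCysteines(at, ssCutoff = ssCutoff)
  res <- unique(at[, c("chain", "resno", "resname")])
  xray <- list(); excluded <- list()
  addExcl <- function(ch, rn, rt, why)
    excluded[[length(excluded) + 1L]] <<- data.frame(
      chain = ch, resno = rn, resname = rt, reason = why,
      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    ch <- res$chain[i]; rn <- res$resno[i]; rt <- res$resname[i]
    if (chiCount(rt) == 0L) { addExcl(ch, rn, rt, "no_chi_angles"); next }
    if (!rt %in% residueTypes(library)) {
      addExcl(ch, rn, rt, "not_in_library"); next
    }
    if (rt == "CYS" && any(ss$chain == ch & ss$resno == rn)) {
      addExcl(ch, rn, rt, "disulfide"); next
    }
    chis <- withCallingHandlers(
      computeChiAngles(at, ch, rn),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(chis)) { addExcl(ch, rn, rt, "missing_atoms"); next }
    altState <- NA_integer_
    if (!is.null(altLat)) {
      aat <- atoms(altLat)
      hasAlt <- nrow(aat[aat$chain == ch & aat$resno == rn, ]) > 0 &&
        !identical(aat[aat$chain == ch & aat$resno == rn, c("x", "y", "z")],
                   at[at$chain == ch & at$resno == rn, c("x", "y", "z")])
      if (hasAlt) {
        achis <- withCallingHandlers(
          computeChiAngles(aat, ch, rn),
          warning = function(w) invokeRestart("muffleWarning"))
        if (!is.null(achis))
          altState <- assignRotamer(achis, rt, library)
      }
    }
    pad <- c(chis, rep(NA_real_, 4 - length(chis)))
    xray[[length(xray) + 1L]] <- data.frame(
      chain = ch, resno = rn, resname = rt, chi1 = pad[1], chi2 = pad[2],
      chi3 = pad[3], chi4 = pad[4],
      state_id = assignRotamer(chis, rt, library),
      alt_state_id = altState, stringsAsFactors = FALSE)
  }
  list(lattice = lattice,
       xray = do.call(rbind, c(xray, list(make.row.names = FALSE))),
       excluded = do.call(rbind, c(excluded, list(make.row.names = FALSE))))
}

#' Run the full ensemble-comparison pipeline
#'
#' Orchestrates the analysis end to end: X-ray rotamer assignment and
#' environment annotation from the structure; windowing, rotamer
#' assignment and copy pooling of the chi trajectories; per-residue overlap
#' coefficient, KL divergence, entropy difference, region classification,
#' X-ray agreement and two-segment uncertainty bounds; and set-level
#' summaries over solvent-exposed residues. Deterministic for fixed inputs
#' and configuration.
#'
#' @param trajectories chi-table path or list of [ChiTrajectory-class]
#'   covering both conditions.
#' @param structure PDB path or the result of [readStructure()].
#' @param config a [runConfig()].
#' @param library a [RotamerLibrary-class].
#' @return list of class "rotamerComparisonReport": `comparisons`
#'   (per-residue data.frame), `summaries` (set-level data.frame),
#'   `histograms` (long data.frame of per-state probabilities),
#'   `annotation`, `composition`, `segmentR` (OC and T*dS cross-segment
#'   correlations), and `manifest`.
#' @export
runPipeline <- function(trajectories, structure, config = runConfig(),
                        library = loadRotamerLibrary()) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.character(trajectories)) trajectories <- readChiTable(trajectories)
  if (is.character(structure))
    structure <- readStructure(structure, library = library,
                               altLoc = config$altLoc)
  ann <- annotateEnvironment(structure$lattice,
                             contactCutoff = config$contactCutoff,
                             probe = config$probe,
                             pointDensity = config$pointDensity,
                             exposureThreshold = config$exposureThreshold,
                             shell = config$shell)
  xray <- structure$xray
  exclusions <- if (is.null(structure$excluded)) list()
                else split(structure$excluded,
                           seq_len(nrow(structure$excluded)))

  # pool copies: map each trajectory's copy label to its pooled chain
  poolChain <- function(tr) {
    if (is.null(config$pooling)) tr@chain
    else {
      m <- config$pooling[tr@chainCopy]
      if (is.na(m)) stop("chain copy '", tr@chainCopy,
                         "' missing from pooling map")
      unname(m)
    }
  }
  keys <- vapply(trajectories, function(tr)
    paste(poolChain(tr), tr@resno, tr@condition, sep = "|"), character(1))
  byKey <- split(trajectories, keys)

  resKeys <- unique(sub("\\|[^|]+$", "", names(byKey)))
  rows <- list(); hist <- list()
  solSeries <- list(); crySeries <- list()
  for (rk in resKeys) {
    parts <- strsplit(rk, "|", fixed = TRUE)[[1]]
    ch <- parts[1]; rn <- as.integer(parts[2])
    sol <- byKey[[paste(rk, "solution", sep = "|")]]
    cry <- byKey[[paste(rk, "crystal", sep = "|")]]
    rt <- c(sol, cry)[[1]]@restype
    if (is.null(sol) || is.null(cry)) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        chain = ch, resno = rn, resname = rt,
        reason = "missing_condition", stringsAsFactors = FALSE)
      next
    }
    mkSeries <- function(trs) lapply(trs, function(tr) {
      s <- assignSeries(tr, library)
      idx <- windowFrames(length(s@states), config$window, config$stride)
      new("RotamerStateSeries", chain = ch, resno = rn, restype = rt,
          condition = s@condition, chainCopy = s@chainCopy,
          states = s@states[idx])
    })
    sSer <- mkSeries(sol); cSer <- mkSeries(cry)
    dS <- buildDistribution(sSer, library)
    dC <- buildDistribution(cSer, library)
    xr <- xray[xray$chain == ch & xray$resno == rn, , drop = FALSE]
    xrState <- if (nrow(xr)) xr$state_id[1] else NA_integer_
    a <- ann[ann$chain == ch & ann$resno == rn, , drop = FALSE]
    eps <- if (is.null(config$klPseudocount)) 1 / nFrames(dS)
           else config$klPseudocount
    oc <- overlapCoefficient(dS, dC)
    tds <- deltaEntropy(dS, dC, config$temperature)
    solSeries[[rk]] <- sSer; crySeries[[rk]] <- cSer
    agree <- function(d) {
      if (config$agreementMode == "state")
        rotamerAgreement(d, xrayState = xrState)
      else if (nrow(xr))
        rotamerAgreement(d, xrayChis = unlist(xr[1, paste0("chi",
                           seq_len(chiCount(rt)))]),
                         library = library,
                         tol = config$agreementTolerance)
      else NA
    }
    rows[[rk]] <- data.frame(
      chain = ch, resno = rn, resname = rt,
      contacting = if (nrow(a)) a$contacting else NA,
      exposed = if (nrow(a)) a$exposed else NA,
      n_states = nStates(library, rt),
      n_frames_solution = nFrames(dS), n_frames_crystal = nFrames(dC),
      oc = oc, kl = klDivergence(dS, dC, pseudocount = eps),
      tds = tds,
      region = as.character(classifyRegion(oc, tds, config$ocBoundary,
                                           config$tdsBoundary)),
      xray_state = xrState,
      p_xray_solution = if (is.na(xrState)) NA_real_
                        else probabilities(dS)[xrState],
      p_xray_crystal = if (is.na(xrState)) NA_real_
                       else probabilities(dC)[xrState],
      agree_solution = agree(dS), agree_crystal = agree(dC),
      stringsAsFactors = FALSE)
    hist[[rk]] <- data.frame(
      chain = ch, resno = rn, resname = rt,
      state_id = seq_len(nStates(library, rt)),
      state_name = stateNames(library, rt),
      p_solution = probabilities(dS), p_crystal = probabilities(dC),
      xray_flag = seq_len(nStates(library, rt)) == ifelse(is.na(xrState),
                                                          0L, xrState),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no residue present under both conditions")
  comparisons <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  comparisons <- comparisons[order(comparisons$chain, comparisons$resno), ]
  rownames(comparisons) <- NULL

  ord <- paste(comparisons$chain, comparisons$resno)
  okeys <- resKeys[match(ord, sub("\\|", " ", resKeys))]
  addBounds <- function(stat, cols) {
    su <- segmentUncertainty(solSeries[okeys], crySeries[okeys], library,
                             statistic = stat,
                             temperature = config$temperature)
    comparisons[[cols[1]]] <<- su$bounds$low
    comparisons[[cols[2]]] <<- su$bounds$high
    su$r
  }
  rOC <- addBounds("oc", c("oc_low", "oc_high"))
  rTDS <- addBounds("tds", c("tds_low", "tds_high"))

  summaries <- if (all(is.na(comparisons$exposed))) NULL
    else summarizeSets(comparisons[!is.na(comparisons$exposed), ])
  composition <- if (nrow(ann)) residueComposition(ann, library) else NULL
  excludedTab <- if (length(exclusions))
    do.call(rbind, c(exclusions, list(make.row.names = FALSE))) else NULL

  manifest <- list(
    package_version = as.character(packageVersion("RotamerEnsembles")),
    r_version = R.version.string,
    config = unclass(config),
    n_residues_compared = nrow(comparisons),
    n_excluded = if (is.null(excludedTab)) 0L else nrow(excludedTab),
    excluded = excludedTab,
    seed = config$seed)
  structure(list(comparisons = comparisons, summaries = summaries,
                 histograms = do.call(rbind,
                                      c(hist, list(make.row.names = FALSE))),
                 annotation = ann, composition = composition,
                 segmentR = c(oc = rOC, tds = rTDS), manifest = manifest),
            class = "rotamerComparisonReport")
}

#' @export
print.rotamerComparisonReport <- function(x, ...) {
  cat("rotamerComparisonReport:", nrow(x$comparisons),
      "residues compared\n")
  cat("  cross-segment R: OC", sprintf("%.3f", x$segmentR["oc"]),
      "/ T*dS", sprintf("%.3f", x$segmentR["tds"]), "\n")
  if (!is.null(x$summaries)) {
    cat("  set summaries:\n")
    print(x$summaries, digits = 3)
  }
  invisible(x)
}

#' Write a report bundle to tab-separated files
#'
#' Emits `comparisons.tsv`, `summaries.tsv`, `histograms.tsv`,
#' `annotation.tsv` and `manifest.txt` under `dir`. Reruns on identical
#' inputs and configuration produce byte-identical tables.
#'
#' @param report a "rotamerComparisonReport" from [runPipeline()].
#' @param dir output directory (created if absent).
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tab, name) {
    if (!is.null(tab))
      write.table(tab, file.path(dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE, na = "")
  }
  emit(report$comparisons, "comparisons.tsv")
  emit(report$summaries, "summaries.tsv")
  emit(report$histograms, "histograms.tsv")
  emit(report$annotation, "annotation.tsv")
  emit(report$composition, "composition.tsv")
  m <- report$manifest
  lines <- c(paste("package_version", m$package_version),
             paste("r_version", m$r_version),
             paste("n_residues_compared", m$n_residues_compared),
             paste("n_excluded", m$n_excluded),
             paste("seed", m$seed))
  writeLines(lines, file.path(dir, "manifest.txt"))
  if (!is.null(m$excluded)) emit(m$excluded, "excluded.tsv")
  invisible(dir)
}
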