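#' Load a rotamer library table
#'
#' Reads the tab-separated rotamer state catalogue shipped with the package
#' (or any user-supplied table in the same dialect) into a
#' [RotamerLibrary-class]. The dialect has a header row and columns
#' `residue_type`, `state_id`, `state_name`, `n_chi`, `chi1`..`chi4`, with
#' empty cells for absent chi angles; `#` lines are comments. State order
#' within a residue type is the library's published order, so state IDs are
#' directly comparable to histogram axes built from the same table.
#'
#' @param path file path; defaults to the packaged library.
#' @return A [RotamerLibrary-class].
#' @examples
#' lib <- loadRotamerLibrary()
#' nStates(lib, "LEU")
#' @export
loadRotamerLibrary <- function(path = system.file("extdata",
                                 "rotamer_library.tsv",
                                 package = "RotamerEnsembles")) {
  if (!nzchar(path) || !file.exists(path))
    stop("rotamer library file not found: '", path, "'")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue_type", "state_id", "state_name", "n_chi",
            paste0("chi", 1:4))
  if (!all(need %in% names(tab)))
    stop("malformed rotamer library; missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  bad <- which(is.na(tab$n_chi) | tab$n_chi < 1 | tab$n_chi > 4 |
                 is.na(tab$chi1))
  if (length(bad))
    stop("malformed rotamer library row(s): ",
         paste(bad, collapse = ", "), " (counting data rows)")
  for (j in paste0("chi", 1:4)) tab[[j]] <- as.numeric(tab[[j]])
  tab$state_id <- as.integer(tab$state_id)
  tab$n_chi <- as.integer(tab$n_chi)
  new("RotamerLibrary", table = tab)
}

.libEntry <- function(x, residueType) {
  sub <- x@table[x@table$residue_type == residueType, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("residue type '", residueType, "' is not in the rotamer library")
  sub[order(sub$state_id), , drop = FALSE]
}

#' @describeIn loadRotamerLibrary residue types present in a library.
#' @param x a `RotamerLibrary`.
#' @export
setMethod("residueTypes", "RotamerLibrary",
          function(x) unique(x@table$residue_type))

#' @describeIn loadRotamerLibrary number of rotamer states N for a residue type.
#' @param residueType three-letter code.
#' @export
setMethod("nStates", "RotamerLibrary",
          function(x, residueType) nrow(.libEntry(x, residueType)))

#' @describeIn loadRotamerLibrary number of chi angles for a residue type.
#' @export
setMethod("nChi", "RotamerLibrary",
          function(x, residueType) .libEntry(x, residueType)$n_chi[1])

#' @describeIn loadRotamerLibrary modal chi matrix (states x n_chi) for a
#'   residue type, rows in state order.
#' @export
setMethod("modalChis", "RotamerLibrary", function(x, residueType) {
  sub <- .libEntry(x, residueType)
  m <- as.matrix(sub[, paste0("chi", seq_len(sub$n_chi[1])), drop = FALSE])
  dimnames(m) <- list(sub$state_name, paste0("chi", seq_len(ncol(m))))
  m
})

#' @describeIn loadRotamerLibrary short state labels in state order.
#' @export
setMethod("stateNames", "RotamerLibrary",
          function(x, residueType) .libEntry(x, residueType)$state_name)

setMethod("show", "RotamerLibrary", function(object) {
  tab <- object@table
  cat("RotamerLibrary with", nrow(tab), "states over",
      length(unique(tab$residue_type)), "residue types\n")
  cnt <- table(tab$residue_type)
  cat("  states per type:",
      paste(names(cnt), as.integer(cnt), sep = ":", collapse = " "), "\n")
})

setMethod("show", "ChiTrajectory", function(object) {
  cat(sprintf("ChiTrajectory %s:%s%d (%s, copy %s): %d frames x %d chi\n",
              object@chain, object@restype, object@resno, object@condition,
              object@chainCopy, nrow(object@frames), ncol(object@frames)))
})

setMethod("show", "RotamerStateSeries", function(object) {
  cat(sprintf("RotamerStateSeries %s:%s%d (%s, copy %s): %d frames\n",
              object@chain, object@restype, object@resno, object@condition,
              object@chainCopy, length(object@states)))
})

setMethod("show", "RotamerDistribution", function(object) {
  cat(sprintf("RotamerDistribution %s:%s%d (%s), %d frames\n  p = %s\n",
              object@chain, object@restype, object@resno, object@condition,
              object@nFrames,
              paste(sprintf("%.3f", object@probabilities), collapse = " ")))
})

setMethod("show", "LatticeModel", function(object) {
  cat(sprintf("LatticeModel: %d atoms, %d chains, space group '%s'\n",
              nrow(object@atoms), length(unique(object@atoms$chain)),
              object@spaceGroup))
  cat(sprintf("  cell: a=%.2f b=%.2f c=%.2f alpha=%.1f beta=%.1f gamma=%.1f\n",
              object@cell[1], object@cell[2], object@cell[3],
              object@cell[4], object@cell[5], object@cell[6]))
})

#' @describeIn loadRotamerLibrary accessors for the other core classes.
#' @export
setMethod("frames", "ChiTrajectory", function(x) x@frames)

#' @export
setMethod("states", "RotamerStateSeries", function(x) x@states)

#' @export
setMethod("probabilities", "RotamerDistribution", function(x) x@probabilities)

#' @export
setMethod("nFrames", "RotamerDistribution", function(x) x@nFrames)

#' @export
setMethod("condition", "ChiTrajectory", function(x) x@condition)

#' @export
setMethod("condition", "RotamerStateSeries", function(x) x@condition)

#' @export
setMethod("condition", "RotamerDistribution", function(x) x@condition)

.residueIdOf <- function(x)
  list(chain = x@chain, resno = x@resno, restype = x@restype)

#' @export
setMethod("residueId", "ChiTrajectory", .residueIdOf)

#' @export
setMethod("residueId", "RotamerStateSeries", .residueIdOf)

#' @export
setMethod("residueId", "RotamerDistribution", .residueIdOf)

#' @export
setMethod("atoms", "LatticeModel", function(x) x@atoms)

#' @export
setMethod("spaceGroup", "LatticeModel", function(x) x@spaceGroup)

#' @export
setMethod("cellParameters", "LatticeModel", function(x) x@cell)
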