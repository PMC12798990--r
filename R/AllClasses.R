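#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MsRun: one centroided MS1 run
#'
#' Container for a single LC-MS run as a time-ordered list of centroid
#' spectra. Each spectrum is a two-column matrix (`mz`, `intensity`) with
#' strictly increasing m/z and non-negative intensities.
#'
#' @slot runId Character, run identifier (e.g. `"sample_1"`).
#' @slot group Character, `"sample"` (active enzyme) or `"control"`
#'   (denatured enzyme), or `NA` when unknown.
#' @slot replicate Integer replicate index within the group.
#' @slot scanTime Numeric vector of scan retention times in minutes,
#'   non-decreasing.
#' @slot peaks List of numeric matrices, one per scan, columns `mz` and
#'   `intensity`.
#' @slot centroided Logical, whether scans are centroided (profile-mode
#'   data is rejected throughout the package).
#'
#' @aliases MsRun-class
#' @exportClass MsRun
setClass("MsRun",
  representation(runId = "character", group = "character",
                 replicate = "integer", scanTime = "numeric",
                 peaks = "list", centroided = "logical"))

setValidity("MsRun", function(object) {
  msgs <- character()
  if (length(object@scanTime) != length(object@peaks))
    msgs <- c(msgs, "scanTime and peaks must have the same length")
  if (is.unsorted(object@scanTime))
    msgs <- c(msgs, "scans must be ordered by retention time")
  for (i in seq_along(object@peaks)) {
    p <- object@peaks[[i]]
    if (!is.matrix(p) || ncol(p) != 2) {
      msgs <- c(msgs, sprintf("scan %d is not a two-column matrix", i))
      break
    }
    if (nrow(p) > 1 && any(diff(p[, 1]) <= 0)) {
      msgs <- c(msgs, sprintf("scan %d m/z values are not strictly increasing", i))
      break
    }
    if (any(p[, 2] < 0)) {
      msgs <- c(msgs, sprintf("scan %d has negative intensities", i))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an MsRun
#'
#' @param scanTime Numeric vector of retention times in minutes.
#' @param peaks List of two-column (`mz`, `intensity`) matrices, one per scan.
#' @param runId Run identifier.
#' @param group `"sample"`, `"control"` or `NA`.
#' @param replicate Replicate index.
#' @param centroided Logical.
#' @return An [MsRun-class] object.
#' @export
MsRun <- function(scanTime, peaks, runId = "run", group = NA_character_,
                  replicate = NA_integer_, centroided = TRUE) {
  peaks <- lapply(peaks, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("mz", "intensity")
    p
  })
  new("MsRun", runId = as.character(runId), group = as.character(group),
      replicate = as.integer(replicate), scanTime = as.numeric(scanTime),
      peaks = peaks, centroided = isTRUE(centroided))
}

#' @describeIn MsRun Number of scans.
#' @param x,object An `MsRun`.
#' @export
setMethod("length", "MsRun", function(x) length(x@scanTime))

#' Accessors for MsRun
#'
#' @param object An [MsRun-class].
#' @return `scanTimes`: numeric vector of scan retention times (minutes);
#'   `peaksData`: list of centroid matrices; `runId`: character;
#'   `runGroup`: character; `runReplicate`: integer.
#' @name MsRun-accessors
NULL

#' @rdname MsRun-accessors
#' @export
setGeneric("scanTimes", function(object) standardGeneric("scanTimes"))
#' @rdname MsRun-accessors
#' @export
setMethod("scanTimes", "MsRun", function(object) object@scanTime)

#' @rdname MsRun-accessors
#' @export
setGeneric("peaksData", function(object) standardGeneric("peaksData"))
#' @rdname MsRun-accessors
#' @export
setMethod("peaksData", "MsRun", function(object) object@peaks)

#' @rdname MsRun-accessors
#' @export
setGeneric("runId", function(object) standardGeneric("runId"))
#' @rdname MsRun-accessors
#' @export
setMethod("runId", "MsRun", function(object) object@runId)

#' @rdname MsRun-accessors
#' @export
setGeneric("runGroup", function(object) standardGeneric("runGroup"))
#' @rdname MsRun-accessors
#' @export
setMethod("runGroup", "MsRun", function(object) object@group)

#' @rdname MsRun-accessors
#' @export
setGeneric("runReplicate", function(object) standardGeneric("runReplicate"))
#' @rdname MsRun-accessors
#' @export
setMethod("runReplicate", "MsRun", function(object) object@replicate)

setMethod("show", "MsRun", function(object) {
  n <- length(object@scanTime)
  cat("MsRun '", object@runId, "' (", object@group, ", replicate ",
      object@replicate, ")\n", sep = "")
  cat("  ", n, " centroid MS1 scans", sep = "")
  if (n) cat(", RT ", sprintf("%.2f", min(object@scanTime)), "-",
             sprintf("%.2f", max(object@scanTime)), " min", sep = "")
  cat("\n  ", sum(vapply(object@peaks, nrow, integer(1))), " centroids\n",
      sep = "")
})

#' ConsensusSet: compounds aligned across runs
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one row
#' per consensus compound and one column per run. The `"area"` assay
#' carries integrated peak areas (NA = compound not detected in that run),
#' `rowData` carries the consensus neutral mass and retention time, and
#' `colData` carries the run grouping (`group`, `replicate`). Screening
#' statistics are appended to `rowData` by [screenCompounds()].
#'
#' @aliases ConsensusSet-class
#' @exportClass ConsensusSet
setClass("ConsensusSet", contains = "SummarizedExperiment")

setValidity("ConsensusSet", function(object) {
  msgs <- character()
  if (!"area" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "missing 'area' assay")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "replicate") %in% colnames(cd)))
    msgs <- c(msgs, "colData needs 'group' and 'replicate'")
  else if (!all(cd$group %in% c("sample", "control")))
    msgs <- c(msgs, "group must be 'sample' or 'control'")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("neutral_mass", "rt") %in% colnames(rd)))
    msgs <- c(msgs, "rowData needs 'neutral_mass' and 'rt'")
  if (length(msgs)) msgs else TRUE
})

#' Accessors for ConsensusSet
#'
#' @param object A [ConsensusSet-class].
#' @return `consensusMass`: neutral monoisotopic masses (Da); `consensusRT`:
#'   retention times (minutes); `areaMatrix`: the compounds x runs peak-area
#'   matrix.
#' @name ConsensusSet-accessors
NULL

#' @rdname ConsensusSet-accessors
#' @export
setGeneric("consensusMass", function(object) standardGeneric("consensusMass"))
#' @rdname ConsensusSet-accessors
#' @export
setMethod("consensusMass", "ConsensusSet", function(object)
  SummarizedExperiment::rowData(object)$neutral_mass)

#' @rdname ConsensusSet-accessors
#' @export
setGeneric("consensusRT", function(object) standardGeneric("consensusRT"))
#' @rdname ConsensusSet-accessors
#' @export
setMethod("consensusRT", "ConsensusSet", function(object)
  SummarizedExperiment::rowData(object)$rt)

#' @rdname ConsensusSet-accessors
#' @export
setGeneric("areaMatrix", function(object) standardGeneric("areaMatrix"))
#' @rdname ConsensusSet-accessors
#' @export
setMethod("areaMatrix", "ConsensusSet", function(object)
  SummarizedExperiment::assay(object, "area"))

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet with", nrow(object), "consensus compounds across",
      ncol(object), "runs\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(cd$group)),
                                 table(cd$group)), collapse = ", "), "\n")
  rd <- SummarizedExperiment::rowData(object)
  if ("selected" %in% colnames(rd))
    cat("  selected ligands:", sum(rd$selected, na.rm = TRUE), "\n")
  full <- sum(apply(!is.na(SummarizedExperiment::assay(object, "area")), 1, all))
  cat("  compounds with a complete area matrix:", full, "\n")
})
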