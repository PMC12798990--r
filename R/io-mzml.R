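#' Write centroided MS1 runs to mzML
#'
#' Serialises an [MsRun-class] to a centroid MS1 mzML file (positive-ion
#' metadata) via the proteowizard writer behind `mzR`.
#'
#' @param run An [MsRun-class].
#' @param file Output path (`.mzML`).
#' @return `file`, invisibly.
#' @export
writeMsRun <- function(run, file) {
  stopifnot(is(run, "MsRun"))
  pk <- peaksData(run)
  n <- length(pk)
  if (n == 0) stop("run has no scans")
  npk <- vapply(pk, nrow, integer(1))
  tic <- vapply(pk, function(p) sum(p[, 2]), numeric(1))
  bp <- t(vapply(pk, function(p) {
    if (nrow(p) == 0) return(c(0, 0))
    i <- which.max(p[, 2]); c(p[i, 1], p[i, 2])
  }, numeric(2)))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk, totIonCurrent = tic,
    retentionTime = scanTimes(run) * 60,
    basePeakMZ = bp[, 1], basePeakIntensity = bp[, 2],
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = run@centroided, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(object = pk, file = file, header = hdr,
                   outformat = "mzml")
  invisible(file)
}

#' @describeIn writeMsRun Write a list of runs to `<run_id>.mzML` files in
#'   a directory.
#' @param runs List of [MsRun-class] objects.
#' @param dir Output directory (created if needed).
#' @return `writeMsRuns`: character vector of file paths, invisibly.
#' @export
writeMsRuns <- function(runs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(runs, function(r)
    file.path(dir, paste0(runId(r), ".mzML")), character(1))
  for (i in seq_along(runs)) writeMsRun(runs[[i]], paths[i])
  invisible(paths)
}

#' Read centroided MS1 runs from mzML
#'
#' Reads the MS1 scans of an mzML file into an [MsRun-class], ordered by
#' retention time. Profile-mode spectra are rejected: this package
#' operates on centroided data only.
#'
#' @param file Path to an mzML file.
#' @param runId Run identifier; defaults to the file name without
#'   extension.
#' @return An [MsRun-class]; `group`/`replicate` are filled in when the
#'   run id looks like `"sample_1"` / `"control_2"`.
#' @export
readMsRun <- function(file, runId = NULL) {
  if (!file.exists(file)) stop("input file not found: ", file)
  if (is.null(runId))
    runId <- sub("\\.[^.]+$", "", basename(file))
  fh <- mzR::openMSfile(file)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1))
    stop("no MS1 scans in ", file)
  if (any(hdr$centroided[ms1] %in% FALSE))
    stop("profile-mode spectra in ", file,
         " (scan ", which(hdr$centroided %in% FALSE)[1],
         "); centroided MS1 data is required")
  pk <- mzR::peaks(fh, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  rt <- hdr$retentionTime[ms1] / 60
  ord <- order(rt)
  grp <- NA_character_; rep_i <- NA_integer_
  m <- regexec("^(sample|control)_([0-9]+)$", runId)[[1]]
  if (m[1] != -1) {
    parts <- regmatches(runId, regexec("^(sample|control)_([0-9]+)$", runId))[[1]]
    grp <- parts[2]; rep_i <- as.integer(parts[3])
  }
  MsRun(scanTime = rt[ord], peaks = pk[ord], runId = runId, group = grp,
        replicate = rep_i)
}

#' @describeIn readMsRun Read every `.mzML` file in a directory (or an
#'   explicit vector of paths).
#' @param paths Directory containing `.mzML` files, or a character vector
#'   of file paths.
#' @return `readMsRuns`: named list of [MsRun-class] objects.
#' @export
readMsRuns <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.mzML$", full.names = TRUE)
    if (!length(paths))
      stop("no .mzML files found; expected a directory with files named ",
           "like sample_1.mzML ... control_<n>.mzML")
  }
  runs <- lapply(paths, readMsRun)
  names(runs) <- vapply(runs, runId, character(1))
  runs
}
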