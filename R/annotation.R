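## md5 checksums of the packaged knowledge-base transcriptions; guards
## against silent fixture corruption.
.KB_CHECKSUMS <- c(
  ligand_screen_table.csv = "13d42107f956b56b3e73b93b04bd3763",
  definite_structures_table.csv = "c0f356bac3bee89c6f16f6d194e1dcbc")

#' Load the packaged ligand knowledge base
#'
#' Returns the transcribed screening results shipped with the package: the
#' 84-ligand table (formula, retention time, detected MW, mean PAR +- SD,
#' name, reference-standard vs literature source) and the 26-compound
#' definite-structure table (docking sites, Kd, IC50, inhibition
#' percentages). Rows with known data-quality problems in the printed
#' source carry a non-empty `flag` (`mw_placeholder` for the three
#' 578.0000 molecular-weight placeholders, `mw_outlier` for one detected
#' MW inconsistent with its formula beyond 5 ppm, `par_typo` for one PAR
#' misprint corrected by an obvious factor of 100).
#'
#' @param check Verify the md5 checksums of the packaged files (default
#'   `TRUE`); a mismatch is an error.
#' @return List with `data.frame`s `ligands` (84 rows) and `definite`
#'   (26 rows); `ligands` gains `theoretical_mass` and `mass_ppm_error`
#'   columns computed from the formulas.
#' @export
loadKnowledgeBase <- function(check = TRUE) {
  files <- names(.KB_CHECKSUMS)
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "afuScreen", mustWork = TRUE),
    character(1))
  if (check) {
    sums <- tools::md5sum(paths)
    bad <- sums != .KB_CHECKSUMS
    if (any(bad))
      stop("knowledge-base checksum mismatch for: ",
           paste(files[bad], collapse = ", "))
  }
  lig <- utils::read.csv(paths[1], stringsAsFactors = FALSE,
                         colClasses = c(flag = "character"))
  def <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  lig$flag[is.na(lig$flag)] <- ""
  lig$theoretical_mass <- monoisotopicMass(lig$formula)
  lig$mass_ppm_error <- ppmError(lig$detected_mw, lig$theoretical_mass)
  list(ligands = lig, definite = def)
}

#' Reference library for annotation
#'
#' The definite-structure compounds of the knowledge base (names without
#' an "isomer" qualifier) as an annotation library: name, formula,
#' theoretical neutral mass and retention time.
#'
#' @param kb Knowledge base from [loadKnowledgeBase()].
#' @return `data.frame` with columns `id`, `name`, `formula`, `mass`,
#'   `rt`, `source`.
#' @export
referenceLibrary <- function(kb = loadKnowledgeBase()) {
  lig <- kb$ligands
  def <- lig[!grepl("isomer", lig$name), , drop = FALSE]
  data.frame(id = def$id, name = def$name, formula = def$formula,
             mass = def$theoretical_mass, rt = def$rt_min,
             source = def$source, stringsAsFactors = FALSE)
}

## Annotates one (mass, rt) query against the library. Same-formula
## entries are reported jointly ("A/B"); a mass match without an RT match
## gets the "isomer" qualifier.
.annotate_one <- function(mass, rt, library, tol_ppm, rt_tol) {
  ppm <- ppmError(mass, library$mass)
  hit <- abs(ppm) <= tol_ppm
  if (!any(hit))
    return(list(annotation = NA_character_, match_id = NA_character_,
                ppm_error = NA_real_, rt_match = NA))
  # the formula group closest in ppm wins ties between distinct masses
  masses <- unique(library$mass[hit])
  best_mass <- masses[which.min(vapply(masses, function(m)
    min(abs(ppm[hit & library$mass == m])), numeric(1)))]
  grp <- which(hit & library$mass == best_mass)
  exact <- grp[!is.na(library$rt[grp]) & abs(rt - library$rt[grp]) <= rt_tol]
  if (length(exact)) {
    lab <- paste(unique(library$name[exact]), collapse = "/")
    ids <- paste(library$id[exact], collapse = "/")
    best <- exact[which.min(abs(ppm[exact]))]
    return(list(annotation = lab, match_id = ids,
                ppm_error = ppm[best], rt_match = TRUE))
  }
  lab <- paste(paste(unique(library$name[grp]), "isomer"), collapse = "/")
  ids <- paste(library$id[grp], collapse = "/")
  best <- grp[which.min(abs(ppm[grp]))]
  list(annotation = lab, match_id = ids, ppm_error = ppm[best],
       rt_match = FALSE)
}

#' Annotate consensus compounds against a reference library
#'
#' A compound matching a library entry in mass (within `tol_ppm`) and
#' retention time (within `rt_tol`) inherits its name; a mass match with a
#' different retention time is reported as "&lt;name&gt; isomer"; several
#' same-formula library names are joined with "/"; no mass match leaves
#' the compound unannotated (`NA`).
#'
#' @param x A [ConsensusSet-class], or a `data.frame` with `neutral_mass`
#'   and `rt` columns.
#' @param library Annotation library from [referenceLibrary()] (default),
#'   or any `data.frame` with `id`, `name`, `mass`, `rt`.
#' @param tol_ppm Mass tolerance in ppm, default 5.
#' @param rt_tol RT tolerance in minutes for same-compound identity,
#'   default 0.1.
#' @return For a `ConsensusSet`: the object with `annotation`,
#'   `annotation_id`, `annotation_ppm`, `annotation_rt_match` appended to
#'   `rowData`. For a `data.frame`: the annotated `data.frame`.
#' @export
annotateCompounds <- function(x, library = referenceLibrary(), tol_ppm = 5,
                              rt_tol = 0.1) {
  if (nrow(library) == 0) stop("annotation library is empty")
  is_cs <- is(x, "ConsensusSet")
  mass <- if (is_cs) consensusMass(x) else x$neutral_mass
  rt <- if (is_cs) consensusRT(x) else x$rt
  res <- lapply(seq_along(mass), function(i)
    .annotate_one(mass[i], rt[i], library, tol_ppm, rt_tol))
  ann <- vapply(res, `[[`, character(1), "annotation")
  ids <- vapply(res, `[[`, character(1), "match_id")
  ppm <- vapply(res, `[[`, numeric(1), "ppm_error")
  rtm <- vapply(res, function(r) as.logical(r$rt_match), logical(1))
  if (is_cs) {
    rd <- SummarizedExperiment::rowData(x)
    rd$annotation <- ann
    rd$annotation_id <- ids
    rd$annotation_ppm <- ppm
    rd$annotation_rt_match <- rtm
    SummarizedExperiment::rowData(x) <- rd
    x
  } else {
    x$annotation <- ann
    x$annotation_id <- ids
    x$annotation_ppm <- ppm
    x$annotation_rt_match <- rtm
    x
  }
}

#' Build a targeted-MS/MS precursor inclusion list
#'
#' One entry per selected compound: the [M+H]+ precursor m/z, an RT window
#' of +- `rt_window` minutes around the consensus apex, and the stepped
#' collision energies of the targeted method. Entries whose precursor
#' falls outside the instrument scan range are dropped with a warning;
#' duplicates (same m/z within 5 ppm with overlapping RT windows) are
#' merged.
#'
#' @param selected A screened [ConsensusSet-class] (its selected rows are
#'   used) or a `data.frame` with `neutral_mass` and `rt` columns (all
#'   rows used).
#' @param rt_window Half-width of the RT window in minutes, default 0.5.
#' @param collision_energies Normalised collision energies (%), default
#'   `c(30, 45, 60)`.
#' @param scan_range Instrument scan range in Th, default `c(150, 1000)`.
#' @param adduct Precursor adduct, default `"[M+H]+"`.
#' @return `data.frame` sorted by `rt_center`: `precursor_mz`,
#'   `rt_center`, `rt_start`, `rt_end`, `collision_energies`
#'   (";"-separated).
#' @export
buildInclusionList <- function(selected, rt_window = 0.5,
                               collision_energies = c(30, 45, 60),
                               scan_range = c(150, 1000),
                               adduct = "[M+H]+") {
  stopifnot(rt_window > 0)
  if (is(selected, "ConsensusSet")) {
    rd <- SummarizedExperiment::rowData(selected)
    keep <- if ("selected" %in% colnames(rd))
      !is.na(rd$selected) & rd$selected else rep(TRUE, nrow(rd))
    mass <- rd$neutral_mass[keep]; rt <- rd$rt[keep]
  } else {
    mass <- selected$neutral_mass; rt <- selected$rt
  }
  if (!length(mass)) {
    return(data.frame(precursor_mz = numeric(), rt_center = numeric(),
                      rt_start = numeric(), rt_end = numeric(),
                      collision_energies = character()))
  }
  mz <- mzFromNeutral(mass, adduct)
  inside <- mz >= scan_range[1] & mz <= scan_range[2]
  if (any(!inside))
    warning(sum(!inside), " precursor(s) outside the scan range dropped")
  mz <- mz[inside]; rt <- rt[inside]
  ord <- order(rt, mz)
  mz <- mz[ord]; rt <- rt[ord]
  out <- data.frame(precursor_mz = mz, rt_center = rt,
                    rt_start = rt - rt_window, rt_end = rt + rt_window)
  # merge duplicates: same m/z within 5 ppm and overlapping windows
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      if (abs(ppmError(out$precursor_mz[j], out$precursor_mz[i])) <= 5 &&
          out$rt_start[j] <= out$rt_end[i] &&
          out$rt_end[j] >= out$rt_start[i]) {
        out$rt_start[i] <- min(out$rt_start[i], out$rt_start[j])
        out$rt_end[i] <- max(out$rt_end[i], out$rt_end[j])
        out$rt_center[i] <- mean(c(out$rt_start[i], out$rt_end[i]))
        keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out$collision_energies <- paste(collision_energies, collapse = ";")
  out <- out[order(out$rt_center, out$precursor_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
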