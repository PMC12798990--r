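.infer_run_info <- function(ids) {
  m <- regmatches(ids, regexec("^(sample|control)_([0-9]+)$", ids))
  ok <- lengths(m) == 3
  if (!all(ok))
    stop("cannot infer group/replicate from run id(s): ",
         paste(ids[!ok], collapse = ", "),
         "; supply runInfo with columns run_id, group, replicate")
  data.frame(run_id = ids,
             group = vapply(m, `[`, character(1), 2),
             replicate = as.integer(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

## Single per-run RT offset from mutual-nearest mass matches against the
## reference run. Pairs further than 0.5 min apart are ignored so that
## same-mass positional isomers cannot corrupt the median.
.rt_offset <- function(tab, ref, tol_ppm) {
  if (nrow(tab) == 0 || nrow(ref) == 0) return(0)
  near_ref <- vapply(seq_len(nrow(tab)), function(i) {
    ppm <- abs(ppmError(tab$neutral_mass[i], ref$neutral_mass))
    j <- which.min(ppm)
    if (ppm[j] <= tol_ppm) j else NA_integer_
  }, integer(1))
  near_tab <- vapply(seq_len(nrow(ref)), function(j) {
    ppm <- abs(ppmError(ref$neutral_mass[j], tab$neutral_mass))
    i <- which.min(ppm)
    if (ppm[i] <= tol_ppm) i else NA_integer_
  }, integer(1))
  mutual <- which(!is.na(near_ref) & near_tab[near_ref] == seq_len(nrow(tab)))
  if (!length(mutual)) return(0)
  drt <- tab$rt_apex[mutual] - ref$rt_apex[near_ref[mutual]]
  drt <- drt[abs(drt) <= 0.5]
  if (!length(drt)) return(0)
  stats::median(drt)
}

#' Align feature tables across runs into consensus compounds
#'
#' Implements the align / group steps of the screening workflow: the run
#' with the most features serves as retention-time reference; every other
#' run is shifted by a single offset (the median RT difference of
#' mutual-nearest mass matches); features are then grouped greedily in
#' order of descending height (ties by ascending m/z) into consensus
#' compounds, joining a consensus when within `tol_ppm` of its median
#' neutral mass and `rt_tol` minutes of its median RT. Each feature joins
#' at most one consensus and each consensus holds at most one feature per
#' run.
#'
#' @param featureTables Named list (>= 2) of per-run feature tables from
#'   [detectFeatures()]; names are run ids.
#' @param tol_ppm Mass tolerance in ppm, default 5.
#' @param rt_tol Retention-time tolerance in minutes, default 0.1.
#' @param runInfo Optional `data.frame` (`run_id`, `group`, `replicate`);
#'   inferred from names like `"sample_1"` / `"control_2"` when `NULL`.
#' @return A [ConsensusSet-class] with the `"area"` assay (NA = missing),
#'   consensus `neutral_mass`/`rt` in `rowData`, and the applied RT offsets
#'   and median peak width (seconds) in `metadata()`.
#' @export
alignRuns <- function(featureTables, tol_ppm = 5, rt_tol = 0.1,
                      runInfo = NULL) {
  if (!is.list(featureTables) || length(featureTables) < 2)
    stop("alignment needs at least two runs")
  ids <- names(featureTables)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(featureTables, function(t)
      if (nrow(t)) as.character(t$run_id[1]) else NA_character_, character(1))
  if (anyNA(ids)) stop("feature tables must be named or carry run_id")
  if (is.null(runInfo)) runInfo <- .infer_run_info(ids)
  runInfo <- runInfo[match(ids, runInfo$run_id), , drop = FALSE]

  nfeat <- vapply(featureTables, nrow, integer(1))
  ref_idx <- which.max(nfeat)
  offsets <- vapply(seq_along(featureTables), function(r) {
    if (r == ref_idx) 0
    else .rt_offset(featureTables[[r]], featureTables[[ref_idx]], tol_ppm)
  }, numeric(1))
  names(offsets) <- ids

  pool <- do.call(rbind, lapply(seq_along(featureTables), function(r) {
    t <- featureTables[[r]]
    if (nrow(t) == 0) return(NULL)
    data.frame(run = r, feature = seq_len(nrow(t)),
               neutral_mass = t$neutral_mass, mz = t$mz,
               rt = t$rt_apex - offsets[r], height = t$height,
               area = t$area, width_s = (t$rt_end - t$rt_start) * 60)
  }))
  if (is.null(pool) || nrow(pool) == 0)
    stop("no features to align")
  pool <- pool[order(-pool$height, pool$mz), , drop = FALSE]

  n_cons <- 0L
  cap <- nrow(pool)
  c_mass <- numeric(cap); c_rt <- numeric(cap)
  members <- vector("list", cap)
  assign_to <- integer(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    hit <- 0L
    if (n_cons > 0L) {
      ppm <- abs(ppmError(pool$neutral_mass[i], c_mass[seq_len(n_cons)]))
      cand <- which(ppm <= tol_ppm &
                      abs(pool$rt[i] - c_rt[seq_len(n_cons)]) <= rt_tol)
      if (length(cand)) {
        # one feature per run per consensus
        cand <- cand[vapply(cand, function(k)
          !pool$run[i] %in% pool$run[members[[k]]], logical(1))]
        if (length(cand)) hit <- cand[which.min(ppm[cand])]
      }
    }
    if (hit == 0L) {
      n_cons <- n_cons + 1L
      hit <- n_cons
    }
    members[[hit]] <- c(members[[hit]], i)
    assign_to[i] <- hit
    c_mass[hit] <- stats::median(pool$neutral_mass[members[[hit]]])
    c_rt[hit] <- stats::median(pool$rt[members[[hit]]])
  }

  n_runs <- length(featureTables)
  area <- matrix(NA_real_, n_cons, n_runs, dimnames = list(NULL, ids))
  n_members <- integer(n_cons)
  feat_ids <- character(n_cons)
  mz_med <- numeric(n_cons)
  for (k in seq_len(n_cons)) {
    mem <- members[[k]]
    area[k, pool$run[mem]] <- pool$area[mem]
    n_members[k] <- length(mem)
    mz_med[k] <- stats::median(pool$mz[mem])
    feat_ids[k] <- paste(sprintf("%s:%d", ids[pool$run[mem]],
                                 pool$feature[mem]), collapse = ";")
  }

  ord <- order(c_rt[seq_len(n_cons)], c_mass[seq_len(n_cons)])
  rowdat <- S4Vectors::DataFrame(
    compound_id = sprintf("M%.4fT%.2f", c_mass[ord], c_rt[ord]),
    neutral_mass = c_mass[ord], mz = mz_med[ord], rt = c_rt[ord],
    n_members = n_members[ord], member_features = feat_ids[ord])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(area = area[ord, , drop = FALSE]),
    rowData = rowdat,
    colData = S4Vectors::DataFrame(runInfo, row.names = runInfo$run_id))
  rownames(se) <- rowdat$compound_id
  out <- methods::new("ConsensusSet", se)
  S4Vectors::metadata(out) <- list(
    rt_offsets = offsets,
    median_peak_width_s = stats::median(pool$width_s),
    tol_ppm = tol_ppm, rt_tol = rt_tol)
  out
}

#' Collapse isotopologue satellites into their monoisotopic compound
#'
#' A consensus compound whose mass equals another's plus k x 1.00336 Da
#' (k = 1 or 2, within `tol_ppm`), whose retention time matches within
#' `rt_tol`, and whose total area is smaller, is treated as an A+k
#' isotopologue satellite and removed; the monoisotopic record and its
#' areas are kept unchanged. A satellite with the larger area is left
#' alone with a warning (a mass coincidence, not an isotopologue). The
#' operation is idempotent.
#'
#' @param cs A [ConsensusSet-class].
#' @param tol_ppm Mass tolerance in ppm, default 5.
#' @param rt_tol RT tolerance in minutes, default 0.1.
#' @return The pruned [ConsensusSet-class]; the ids of removed satellites
#'   are recorded in `metadata()$collapsed`.
#' @export
collapseIsotopologues <- function(cs, tol_ppm = 5, rt_tol = 0.1) {
  mass <- consensusMass(cs)
  rt <- consensusRT(cs)
  tot <- rowSums(areaMatrix(cs), na.rm = TRUE)
  ord <- order(mass)
  drop <- rep(FALSE, length(mass))
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (drop[i]) next
    for (k in 1:2) {
      target <- mass[i] + k * 1.00336
      cand <- which(!drop &
                      abs(ppmError(mass, target)) <= tol_ppm &
                      abs(rt - rt[i]) <= rt_tol)
      cand <- setdiff(cand, i)
      for (j in cand) {
        if (tot[j] < tot[i]) {
          drop[j] <- TRUE
        } else {
          warning(sprintf(
            "consensus %s is %d Da above %s but has the larger area; not merged",
            rownames(cs)[j], k, rownames(cs)[i]))
        }
      }
    }
  }
  out <- cs[!drop, ]
  md <- S4Vectors::metadata(cs)
  md$collapsed <- c(md$collapsed, rownames(cs)[drop])
  S4Vectors::metadata(out) <- md
  out
}
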