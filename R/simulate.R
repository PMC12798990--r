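#' Configuration for a simulated affinity-ultrafiltration experiment
#'
#' Collects the acquisition and noise parameters of the paired-design
#' generator. Defaults reproduce the screening study design this package
#' models: four replicate pairs, a 30-minute gradient, full-scan m/z
#' 150-1000, and positive-mode [M+H]+ ions.
#'
#' @param n_replicate_pairs Number of sample/control replicate pairs (>= 2),
#'   default 4.
#' @param run_duration Run length in minutes, default 30.
#' @param scan_interval MS1 scan interval in seconds, default 0.5 (>= 20
#'   points across a 0.1-min-sigma peak).
#' @param mz_range Instrument scan range in Th, default `c(150, 1000)`.
#' @param peak_sigma Chromatographic Gaussian sigma in minutes, default
#'   0.05 (a UPLC-scale peak width that resolves the closest same-formula
#'   isomer pairs of the packaged ligand table, 0.14 min apart).
#' @param rt_jitter_sd SD of the per-run retention-time shift in minutes,
#'   default 0.02.
#' @param intensity_cv Default coefficient of variation of the multiplicative
#'   log-normal peak-area noise, default 0.1; overridden per compound when
#'   the compound table carries its own `intensity_cv`.
#' @param mz_jitter_ppm SD of the per-centroid Gaussian mass error in ppm,
#'   default 1.
#' @param noise_peak_rate Expected number of spurious centroids per scan
#'   (Poisson), default 1.
#' @param nonspecific_floor Fractional inflation of control-group areas by
#'   nonspecific membrane binding, default 0 (the expected control area is
#'   `base_area * (1 + nonspecific_floor)`).
#' @param seed Integer RNG seed; identical seed implies identical output.
#' @return A validated list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(n_replicate_pairs = 4L, run_duration = 30,
                             scan_interval = 0.5, mz_range = c(150, 1000),
                             peak_sigma = 0.05, rt_jitter_sd = 0.02,
                             intensity_cv = 0.1, mz_jitter_ppm = 1,
                             noise_peak_rate = 1, nonspecific_floor = 0,
                             seed = 1L) {
  cfg <- list(n_replicate_pairs = as.integer(n_replicate_pairs),
              run_duration = run_duration, scan_interval = scan_interval,
              mz_range = mz_range, peak_sigma = peak_sigma,
              rt_jitter_sd = rt_jitter_sd, intensity_cv = intensity_cv,
              mz_jitter_ppm = mz_jitter_ppm, noise_peak_rate = noise_peak_rate,
              nonspecific_floor = nonspecific_floor, seed = as.integer(seed))
  if (cfg$n_replicate_pairs < 2)
    stop("at least 2 replicate pairs are required")
  if (cfg$run_duration <= 0 || cfg$scan_interval <= 0 || cfg$peak_sigma <= 0)
    stop("run_duration, scan_interval and peak_sigma must be positive")
  if (length(cfg$mz_range) != 2 || cfg$mz_range[1] >= cfg$mz_range[2])
    stop("mz_range must be an increasing [low, high] pair")
  if (cfg$rt_jitter_sd < 0 || cfg$intensity_cv < 0 || cfg$mz_jitter_ppm < 0 ||
      cfg$noise_peak_rate < 0 || cfg$nonspecific_floor < 0)
    stop("noise parameters must be non-negative")
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' Define ground-truth compounds for the simulator
#'
#' @param formula Character vector of CHO formulas.
#' @param retention_time Numeric, true elution apex in minutes.
#' @param base_area Numeric, expected control-group peak area (ion counts x
#'   s), > 0.
#' @param enrichment Numeric, expected sample/control area ratio (> 0);
#'   values > 1 mark binders.
#' @param intensity_cv Optional per-compound area CV; `NA` falls back to the
#'   config-level `intensity_cv`.
#' @param name Optional compound names; defaults to the formula.
#' @return `data.frame` with one row per compound, including `is_binder`.
#' @export
trueCompounds <- function(formula, retention_time, base_area, enrichment = 1,
                          intensity_cv = NA_real_, name = NULL) {
  n <- length(formula)
  df <- data.frame(
    name = if (is.null(name)) formula else rep_len(name, n),
    formula = formula,
    retention_time = rep_len(retention_time, n),
    base_area = rep_len(base_area, n),
    enrichment = rep_len(enrichment, n),
    intensity_cv = rep_len(intensity_cv, n),
    stringsAsFactors = FALSE)
  if (any(df$base_area <= 0)) stop("base_area must be positive")
  if (any(df$enrichment <= 0)) stop("enrichment must be positive")
  parseFormula(df$formula)  # validates
  df$is_binder <- df$enrichment > 1
  df
}

.check_compounds <- function(compounds, config) {
  if (!is.data.frame(compounds) || nrow(compounds) == 0)
    stop("the compound list must be a non-empty data frame; see trueCompounds()")
  needed <- c("name", "formula", "retention_time", "base_area", "enrichment")
  if (!all(needed %in% names(compounds)))
    stop("compound table is missing columns: ",
         paste(setdiff(needed, names(compounds)), collapse = ", "))
  bad <- compounds$retention_time <= 0 |
    compounds$retention_time >= config$run_duration
  if (any(bad))
    stop("retention time outside the run for compound(s): ",
         paste(compounds$name[bad], collapse = ", "))
  if (is.null(compounds$intensity_cv)) compounds$intensity_cv <- NA_real_
  compounds
}

## Draws realized per-run areas and apex RTs. Runs are ordered
## sample_1..sample_n, control_1..control_n; the per-run RT shift is the
## "inter-run jitter" that alignment later corrects.
.draw_truth <- function(compounds, config) {
  n <- config$n_replicate_pairs
  n_cmp <- nrow(compounds)
  run_id <- c(paste0("sample_", seq_len(n)), paste0("control_", seq_len(n)))
  group <- rep(c("sample", "control"), each = n)
  replicate <- rep(seq_len(n), 2)
  cv <- ifelse(is.na(compounds$intensity_cv), config$intensity_cv,
               compounds$intensity_cv)
  sigma <- sqrt(log(1 + cv^2))
  run_shift <- stats::rnorm(2 * n, 0, config$rt_jitter_sd)
  expected <- outer(compounds$base_area, rep(1, 2 * n)) *
    cbind(matrix(compounds$enrichment, n_cmp, n),
          matrix(1 + config$nonspecific_floor, n_cmp, n))
  noise <- matrix(stats::rnorm(n_cmp * 2 * n, 0, sigma), n_cmp, 2 * n)
  area <- expected * exp(noise)
  apex <- outer(compounds$retention_time, rep(1, 2 * n)) +
    matrix(run_shift, n_cmp, 2 * n, byrow = TRUE)
  dimnames(area) <- dimnames(apex) <- list(compounds$name, run_id)
  list(area = area, apex = apex, run_id = run_id, group = group,
       replicate = replicate, run_shift = run_shift)
}

#' Draw realized peak areas for a paired experiment
#'
#' Runs only the area model of the generator (multiplicative log-normal
#' noise around `base_area` and `base_area * enrichment`), without building
#' spectra. This is the statistical backbone used for calibration studies
#' of the selection rule; [simulateExperiment()] draws identical areas for
#' the same seed.
#'
#' @param compounds Compound table from [trueCompounds()].
#' @param config An [experimentConfig()].
#' @return List with matrices `sample` and `control` (compounds x
#'   replicates) of realized areas.
#' @export
simulateAreas <- function(compounds, config = experimentConfig()) {
  compounds <- .check_compounds(compounds, config)
  set.seed(config$seed)
  tr <- .draw_truth(compounds, config)
  n <- config$n_replicate_pairs
  list(sample = tr$area[, seq_len(n), drop = FALSE],
       control = tr$area[, n + seq_len(n), drop = FALSE])
}

#' Simulate a paired affinity-ultrafiltration LC-MS experiment
#'
#' Generates `2 * n_replicate_pairs` centroided MS1 runs (active-enzyme
#' sample group and denatured-enzyme control group) plus a ground-truth
#' manifest. Each compound elutes as a Gaussian peak at its theoretical
#' [M+H]+ m/z with its first three isotopologue traces; realized areas
#' carry multiplicative log-normal noise (so the median sample/control
#' ratio equals the compound's `enrichment`), apexes are shifted by a
#' per-run retention-time offset, each centroid receives Gaussian ppm mass
#' error, and spurious low-intensity centroids are added at
#' `noise_peak_rate` per scan.
#'
#' @inheritParams simulateAreas
#' @return List with `runs` (list of [MsRun-class], samples first), and
#'   `manifest` (long `data.frame`: name, formula, is_binder, enrichment,
#'   run_id, group, replicate, area, apex_rt, mz).
#' @export
simulateExperiment <- function(compounds, config = experimentConfig()) {
  compounds <- .check_compounds(compounds, config)
  set.seed(config$seed)
  tr <- .draw_truth(compounds, config)

  scan_rt <- seq(0, config$run_duration, by = config$scan_interval / 60)
  sigma_min <- config$peak_sigma
  sigma_s <- sigma_min * 60
  patterns <- lapply(compounds$formula, isotopePattern, n_isotopologues = 3)
  mz_theo <- lapply(patterns, function(p) mzFromNeutral(p$mass))
  abund <- lapply(patterns, function(p) p$abundance)

  runs <- vector("list", length(tr$run_id))
  for (r in seq_along(tr$run_id)) {
    scan_idx <- integer(0); mzs <- numeric(0); ints <- numeric(0)
    for (i in seq_len(nrow(compounds))) {
      apex <- tr$apex[i, r]
      lo <- apex - 4 * sigma_min; hi <- apex + 4 * sigma_min
      sel <- which(scan_rt >= lo & scan_rt <= hi)
      if (!length(sel)) next
      amp0 <- tr$area[i, r] / (sigma_s * sqrt(2 * pi))
      shape <- exp(-(scan_rt[sel] - apex)^2 / (2 * sigma_min^2))
      for (k in seq_along(mz_theo[[i]])) {
        mzk <- mz_theo[[i]][k]
        if (mzk < config$mz_range[1] || mzk > config$mz_range[2]) next
        y <- amp0 * abund[[i]][k] * shape
        keep <- y >= 1
        if (!any(keep)) next
        nkeep <- sum(keep)
        scan_idx <- c(scan_idx, sel[keep])
        mzs <- c(mzs, mzk * (1 + stats::rnorm(nkeep, 0, config$mz_jitter_ppm * 1e-6)))
        ints <- c(ints, y[keep])
      }
    }
    n_noise <- stats::rpois(length(scan_rt), config$noise_peak_rate)
    tot_noise <- sum(n_noise)
    if (tot_noise > 0) {
      scan_idx <- c(scan_idx, rep(seq_along(scan_rt), n_noise))
      mzs <- c(mzs, stats::runif(tot_noise, config$mz_range[1], config$mz_range[2]))
      ints <- c(ints, 10^stats::runif(tot_noise, 2, 4))
    }
    peaks <- rep(list(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("mz", "intensity")))),
                 length(scan_rt))
    if (length(scan_idx)) {
      ord <- order(scan_idx, mzs)
      scan_idx <- scan_idx[ord]; mzs <- mzs[ord]; ints <- ints[ord]
      split_mz <- split(mzs, scan_idx)
      split_int <- split(ints, scan_idx)
      for (j in seq_along(split_mz)) {
        s <- as.integer(names(split_mz)[j])
        mzv <- split_mz[[j]]; iv <- split_int[[j]]
        dup <- duplicated(mzv)
        if (any(dup)) {  # merge coincident centroids (mzv already sorted)
          grp <- cumsum(!dup)
          iv <- as.vector(rowsum(iv, grp))
          mzv <- mzv[!dup]
        }
        peaks[[s]] <- cbind(mz = mzv, intensity = iv)
      }
    }
    runs[[r]] <- MsRun(scanTime = scan_rt, peaks = peaks,
                       runId = tr$run_id[r], group = tr$group[r],
                       replicate = tr$replicate[r])
  }
  names(runs) <- tr$run_id

  n_runs <- length(tr$run_id)
  manifest <- data.frame(
    name = rep(compounds$name, n_runs),
    formula = rep(compounds$formula, n_runs),
    is_binder = rep(compounds$is_binder, n_runs),
    enrichment = rep(compounds$enrichment, n_runs),
    run_id = rep(tr$run_id, each = nrow(compounds)),
    group = rep(tr$group, each = nrow(compounds)),
    replicate = rep(tr$replicate, each = nrow(compounds)),
    area = as.vector(tr$area),
    apex_rt = as.vector(tr$apex),
    mz = rep(vapply(mz_theo, `[`, numeric(1), 1), n_runs),
    stringsAsFactors = FALSE)
  list(runs = runs, manifest = manifest)
}

#' Realistic phantom compound library
#'
#' Returns a ground-truth compound table emulating a citrus-peel extract
#' screen: the 84 packaged knowledge-base ligands with their published
#' retention times and mean peak-area ratios as enrichment factors (their
#' published PAR dispersion sets each compound's intensity CV), plus
#' `n_matrix` non-binding matrix compounds (enrichment 1, random plausible
#' CHO formulas, uniform random retention times).
#'
#' @param n_matrix Number of non-binder matrix compounds, default 50.
#' @param seed Seed for the library's own draws (base areas, matrix
#'   compounds); the global RNG state is left untouched.
#' @return Compound table as from [trueCompounds()].
#' @export
defaultPhantomLibrary <- function(n_matrix = 50, seed = 20260113) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  kb <- loadKnowledgeBase()
  lig <- kb$ligands
  binders <- trueCompounds(
    formula = lig$formula,
    retention_time = lig$rt_min,
    base_area = 10^stats::runif(nrow(lig), log10(2.5e6), log10(4e7)),
    enrichment = lig$par_mean,
    intensity_cv = lig$par_sd / (lig$par_mean * sqrt(2)),
    name = lig$id)

  mat <- list(); accepted <- 0
  while (accepted < n_matrix) {
    nc <- sample(10:30, 1)
    r <- sample(0:15, 1)
    nh <- 2 * nc + 2 - 2 * r
    if (nh < 0) next
    no <- sample(1:12, 1)
    f <- formulaString(c(C = nc, H = nh, O = no))
    m <- monoisotopicMass(f)
    if (m < 160 || m > 880) next
    rt <- stats::runif(1, 1, 29)
    # keep matrix compounds resolvable from the binders (and one another)
    clash <- abs(ppmError(m, monoisotopicMass(binders$formula))) < 10 &
      abs(rt - binders$retention_time) < 0.25
    if (length(mat)) {
      prev <- do.call(rbind, mat)
      clash <- c(clash, abs(ppmError(m, prev$mass)) < 10 &
                   abs(rt - prev$rt) < 0.25)
    }
    if (any(clash)) next
    accepted <- accepted + 1
    mat[[accepted]] <- data.frame(formula = f, mass = m, rt = rt)
  }
  mat <- do.call(rbind, mat)
  matrix_cmp <- trueCompounds(
    formula = mat$formula,
    retention_time = mat$rt,
    base_area = 10^stats::runif(n_matrix, log10(2.5e6), log10(4e7)),
    enrichment = 1,
    name = sprintf("matrix_%02d", seq_len(n_matrix)))
  rbind(binders, matrix_cmp)
}
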