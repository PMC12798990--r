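#' Per-pair peak-area ratios
#'
#' PAR_i = sample area / control area for replicate pair i. Control areas
#' missing from a pair are imputed at `floor_area` (a binder fully
#' depleted from the denatured-enzyme control is the strongest possible
#' signal, so such compounds must not be dropped); pairs with a missing
#' sample area are unusable and excluded. At least two usable pairs are
#' required.
#'
#' @param sample_areas,control_areas Numeric vectors of paired peak areas
#'   (same length, NA = missing).
#' @param floor_area Imputation value for missing control areas (the
#'   detection floor, see [screenCompounds()]).
#' @return List: `par_values` (one per usable pair), `par_mean`, `par_sd`
#'   (n-1 denominator), `imputed_control` (any control imputed),
#'   `n_pairs`, `used` (logical per input pair). When fewer than two pairs
#'   are usable, `par_mean`/`par_sd` are `NA` and `n_pairs` reports the
#'   usable count.
#' @export
computePAR <- function(sample_areas, control_areas, floor_area) {
  stopifnot(length(sample_areas) == length(control_areas))
  imput <- is.na(control_areas) & !is.na(sample_areas)
  control <- ifelse(imput, floor_area, control_areas)
  used <- !is.na(sample_areas) & !is.na(control)
  pv <- sample_areas[used] / control[used]
  if (sum(used) < 2) {
    return(list(par_values = pv, par_mean = NA_real_, par_sd = NA_real_,
                imputed_control = any(imput), n_pairs = sum(used),
                used = used))
  }
  list(par_values = pv, par_mean = mean(pv), par_sd = stats::sd(pv),
       imputed_control = any(imput), n_pairs = sum(used), used = used)
}

#' Two-sample t-test on peak areas
#'
#' Two-tailed t-test between sample and control peak areas on the raw
#' scale, Student (pooled variance) by default, Welch as an option.
#' Degenerate inputs are resolved explicitly: zero variance in both groups
#' with equal means gives p = 1; zero variance overall with unequal means
#' gives p = 0 with a warning.
#'
#' @param sample_areas,control_areas Numeric vectors (>= 2 finite values
#'   each).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return Two-tailed p-value in [0, 1].
#' @export
tTestAreas <- function(sample_areas, control_areas,
                       variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- sample_areas[is.finite(sample_areas)]
  y <- control_areas[is.finite(control_areas)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(1)
    warning("zero variance with unequal means; p set to 0")
    return(0)
  }
  stats::t.test(x, y, var.equal = (variant == "student"))$p.value
}

#' Screen consensus compounds by the PAR rule
#'
#' The defining computation of the affinity-ultrafiltration screen: for
#' every consensus compound, per-pair peak-area ratios, their mean and SD,
#' and a two-tailed t-test of sample vs control areas; a compound is
#' selected as a ligand when mean PAR > `par_threshold` (strictly) and
#' p < `alpha` (strictly, optionally after Benjamini-Hochberg adjustment).
#'
#' Missing control areas are imputed at the detection floor
#' `min_height x` (median peak width in seconds), using the median width
#' recorded by [alignRuns()]; the t-test runs on the same imputed values.
#' Compounds with fewer than two usable pairs are excluded from testing
#' (`selected = NA`, reason recorded).
#'
#' @param cs A [ConsensusSet-class] from [alignRuns()] /
#'   [collapseIsotopologues()].
#' @param par_threshold Mean-PAR selection threshold, default 1.
#' @param alpha Significance level, default 0.05.
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @param correction Multiple-testing correction, `"none"` (default) or
#'   `"BH"`.
#' @param min_height Detection floor used for control imputation, default
#'   1e5.
#' @return The [ConsensusSet-class] with screening columns appended to
#'   `rowData`: a `par` matrix column (one column per pair), `par_mean`,
#'   `par_sd`, `p_value`, `selected`, `imputed_control`, `n_pairs`,
#'   `excluded_reason`.
#' @export
screenCompounds <- function(cs, par_threshold = 1, alpha = 0.05,
                            variant = c("student", "welch"),
                            correction = c("none", "BH"),
                            min_height = 1e5) {
  variant <- match.arg(variant)
  correction <- match.arg(correction)
  cd <- SummarizedExperiment::colData(cs)
  n <- max(cd$replicate)
  s_cols <- match(paste0("sample_", seq_len(n)), rownames(cd))
  c_cols <- match(paste0("control_", seq_len(n)), rownames(cd))
  if (anyNA(s_cols) || anyNA(c_cols)) {
    s_cols <- which(cd$group == "sample")[order(cd$replicate[cd$group == "sample"])]
    c_cols <- which(cd$group == "control")[order(cd$replicate[cd$group == "control"])]
  }
  if (length(s_cols) != length(c_cols))
    stop("sample and control group sizes are unequal")
  a <- areaMatrix(cs)
  width_s <- S4Vectors::metadata(cs)$median_peak_width_s
  if (is.null(width_s) || !is.finite(width_s)) width_s <- 10
  floor_area <- min_height * width_s

  m <- nrow(cs)
  par_mat <- matrix(NA_real_, m, length(s_cols),
                    dimnames = list(NULL, paste0("par_", seq_along(s_cols))))
  par_mean <- par_sd <- p_value <- rep(NA_real_, m)
  imputed <- rep(FALSE, m)
  n_pairs <- integer(m)
  reason <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    sa <- a[i, s_cols]; ca <- a[i, c_cols]
    pr <- computePAR(sa, ca, floor_area)
    imputed[i] <- pr$imputed_control
    n_pairs[i] <- pr$n_pairs
    if (pr$n_pairs < 2) {
      reason[i] <- sprintf("only %d usable replicate pair(s)", pr$n_pairs)
      next
    }
    par_mat[i, which(pr$used)] <- pr$par_values
    par_mean[i] <- pr$par_mean
    par_sd[i] <- pr$par_sd
    ca_imp <- ifelse(is.na(ca) & !is.na(sa), floor_area, ca)
    p_value[i] <- tTestAreas(sa[pr$used], ca_imp[pr$used], variant = variant)
  }
  p_adj <- p_value
  if (correction == "BH") p_adj <- stats::p.adjust(p_value, method = "BH")
  selected <- par_mean > par_threshold & p_adj < alpha
  rd <- SummarizedExperiment::rowData(cs)
  rd$par <- par_mat
  rd$par_mean <- par_mean
  rd$par_sd <- par_sd
  rd$p_value <- p_value
  rd$p_adjusted <- p_adj
  rd$selected <- selected
  rd$imputed_control <- imputed
  rd$n_pairs <- n_pairs
  rd$excluded_reason <- reason
  SummarizedExperiment::rowData(cs) <- rd
  md <- S4Vectors::metadata(cs)
  md$screening <- list(par_threshold = par_threshold, alpha = alpha,
                       variant = variant, correction = correction,
                       floor_area = floor_area)
  S4Vectors::metadata(cs) <- md
  cs
}

#' Flatten screening results to a report table
#'
#' @param cs A screened [ConsensusSet-class].
#' @return `data.frame` with one row per compound: `compound_id`,
#'   `neutral_mass`, `rt`, `par_1..n`, `par_mean`, `par_sd`, `p_value`,
#'   `selected`, `imputed_control`, plus `annotation` when present.
#' @export
screeningReport <- function(cs) {
  rd <- SummarizedExperiment::rowData(cs)
  if (!"par_mean" %in% colnames(rd))
    stop("run screenCompounds() first")
  out <- data.frame(compound_id = rd$compound_id,
                    neutral_mass = rd$neutral_mass, rt = rd$rt,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(rd$par))
  out$par_mean <- rd$par_mean
  out$par_sd <- rd$par_sd
  out$p_value <- rd$p_value
  out$selected <- rd$selected
  out$imputed_control <- rd$imputed_control
  if ("annotation" %in% colnames(rd)) out$annotation <- rd$annotation
  out
}

#' Select ligands from a screening report
#'
#' Applies the selection rule (mean PAR strictly above `par_threshold` and
#' p strictly below `alpha`, optionally BH-adjusted) to a screening report
#' and returns the selected subset sorted by decreasing mean PAR.
#'
#' @param report `data.frame` with `par_mean` and `p_value` columns (from
#'   [screeningReport()]), or a screened [ConsensusSet-class].
#' @inheritParams screenCompounds
#' @return The selected rows, sorted by `par_mean` descending.
#' @export
selectLigands <- function(report, par_threshold = 1, alpha = 0.05,
                          correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (is(report, "ConsensusSet")) report <- screeningReport(report)
  if (nrow(report) == 0) stop("empty screening report")
  p <- report$p_value
  if (correction == "BH") p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(report$par_mean) & !is.na(p) &
    report$par_mean > par_threshold & p < alpha
  out <- report[keep, , drop = FALSE]
  out[order(-out$par_mean), , drop = FALSE]
}

#' Enzyme-inhibition percentage from assay absorbances
#'
#' Inhibition (%) = (A_control - A_test) / A_control x 100, where
#' `a_control` is the absorbance of the no-inhibitor control and `a_test`
#' that of the tested compound.
#'
#' @param a_control Control absorbance (AU), > 0.
#' @param a_test Test absorbance (AU), >= 0.
#' @return Inhibition percentage (vectorised).
#' @export
inhibitionPercent <- function(a_control, a_test) {
  if (any(!is.finite(a_control)) || any(a_control <= 0))
    stop("control absorbance must be positive")
  if (any(a_test < 0)) stop("test absorbance must be non-negative")
  (a_control - a_test) / a_control * 100
}
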