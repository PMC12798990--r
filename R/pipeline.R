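#' Pipeline configuration
#'
#' Bundles every tolerance and threshold of the screening pipeline with
#' the simulator settings, validated on construction. `intensity_tolerance`
#' is recorded for provenance only (a vendor-software detection parameter
#' with no public algorithmic definition) and is not used in computation.
#'
#' @param ppm Mass tolerance in ppm (detection, grouping, annotation),
#'   default 5.
#' @param rt_tol Retention-time grouping tolerance in minutes, default 0.1.
#' @param snr_min S/N threshold for peak detection, default 3.
#' @param min_height Minimum peak intensity, default 1e5.
#' @param max_gap Trace gap tolerance in scans, default 2.
#' @param par_threshold Mean-PAR selection threshold, default 1.
#' @param alpha Significance level, default 0.05.
#' @param ttest_variant `"student"` or `"welch"`.
#' @param correction `"none"` or `"BH"`.
#' @param rt_window Inclusion-list half window in minutes, default 0.5.
#' @param intensity_tolerance Recorded-only vendor parameter, default 30.
#' @param seed Integer seed controlling all randomness, default 1.
#' @param simulate Logical: generate input runs with the simulator
#'   (default) instead of reading mzML files.
#' @param input_dir Directory of mzML runs when `simulate = FALSE`.
#' @param config Simulator [experimentConfig()] (its `seed` is overridden
#'   by `seed`).
#' @param compounds Ground-truth table for the simulator; default
#'   [defaultPhantomLibrary()].
#' @return Validated list of class `afuPipelineConfig`.
#' @export
pipelineConfig <- function(ppm = 5, rt_tol = 0.1, snr_min = 3,
                           min_height = 1e5, max_gap = 2,
                           par_threshold = 1, alpha = 0.05,
                           ttest_variant = c("student", "welch"),
                           correction = c("none", "BH"), rt_window = 0.5,
                           intensity_tolerance = 30, seed = 1L,
                           simulate = TRUE, input_dir = NULL,
                           config = experimentConfig(),
                           compounds = NULL) {
  cfg <- list(ppm = ppm, rt_tol = rt_tol, snr_min = snr_min,
              min_height = min_height, max_gap = max_gap,
              par_threshold = par_threshold, alpha = alpha,
              ttest_variant = match.arg(ttest_variant),
              correction = match.arg(correction), rt_window = rt_window,
              intensity_tolerance = intensity_tolerance,
              seed = as.integer(seed), simulate = isTRUE(simulate),
              input_dir = input_dir, config = config, compounds = compounds)
  if (cfg$ppm <= 0 || cfg$rt_tol <= 0 || cfg$snr_min < 0 ||
      cfg$min_height < 0 || cfg$rt_window <= 0)
    stop("tolerances and thresholds must be positive")
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must lie in [0, 1]")
  if (!cfg$simulate && is.null(cfg$input_dir))
    stop("input_dir is required when simulate = FALSE")
  class(cfg) <- "afuPipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipelineConfig()] arguments; a nested
#' `config:` block maps onto [experimentConfig()].
#'
#' @param file Path to a YAML file.
#' @return An `afuPipelineConfig`.
#' @export
readPipelineConfig <- function(file) {
  y <- yaml::read_yaml(file)
  sim <- if (!is.null(y$config)) do.call(experimentConfig, y$config)
  else experimentConfig()
  y$config <- sim
  do.call(pipelineConfig, y)
}

.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  dput(cfg[setdiff(names(cfg), "compounds")], file = f)
  unname(tools::md5sum(f))
}

#' Run the full screening pipeline
#'
#' Executes simulate (or read) -> detect -> align -> collapse -> screen ->
#' annotate -> targets, and optionally writes the report bundle: a
#' combined per-run feature table, the consensus table, the screening
#' report (with annotations), the annotation report, the targeted-MS/MS
#' inclusion list, the resolved configuration and a run log. Identical
#' configuration and seed give identical outputs.
#'
#' @param cfg An [pipelineConfig()] (or path handled by
#'   [readPipelineConfig()]).
#' @param out_dir Output directory for the report bundle; `NULL` skips
#'   writing.
#' @return Invisibly, a list: `runs`, `features` (data.frame),
#'   `consensus` ([ConsensusSet-class], screened + annotated), `report`,
#'   `selected`, `inclusion`, `manifest` (when simulated), `files`.
#' @export
runPipeline <- function(cfg = pipelineConfig(), out_dir = NULL) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  stopifnot(inherits(cfg, "afuPipelineConfig"))
  t0 <- Sys.time()

  manifest <- NULL
  if (cfg$simulate) {
    sim_cfg <- cfg$config
    sim_cfg$seed <- cfg$seed
    compounds <- if (is.null(cfg$compounds)) defaultPhantomLibrary()
    else cfg$compounds
    sim <- simulateExperiment(compounds, sim_cfg)
    runs <- sim$runs
    manifest <- sim$manifest
  } else {
    runs <- readMsRuns(cfg$input_dir)
  }
  groups <- vapply(runs, runGroup, character(1))
  if (sum(groups == "sample") != sum(groups == "control"))
    stop("unequal group sizes: ", sum(groups == "sample"), " sample vs ",
         sum(groups == "control"), " control runs")

  tabs <- lapply(runs, detectFeatures, tol_ppm = cfg$ppm,
                 max_gap = cfg$max_gap, snr_min = cfg$snr_min,
                 min_height = cfg$min_height)
  names(tabs) <- names(runs)
  features <- do.call(rbind, tabs)
  rownames(features) <- NULL

  cs <- alignRuns(tabs, tol_ppm = cfg$ppm, rt_tol = cfg$rt_tol)
  cs <- collapseIsotopologues(cs, tol_ppm = cfg$ppm, rt_tol = cfg$rt_tol)
  cs <- screenCompounds(cs, par_threshold = cfg$par_threshold,
                        alpha = cfg$alpha, variant = cfg$ttest_variant,
                        correction = cfg$correction,
                        min_height = cfg$min_height)
  cs <- annotateCompounds(cs, tol_ppm = cfg$ppm, rt_tol = cfg$rt_tol)
  report <- screeningReport(cs)
  selected <- selectLigands(report, par_threshold = cfg$par_threshold,
                            alpha = cfg$alpha, correction = cfg$correction)
  inclusion <- buildInclusionList(cs, rt_window = cfg$rt_window)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    ann_report <- report[, c("compound_id", "neutral_mass", "rt",
                             "selected", "annotation")]
    files <- c(
      features = wr(features, "features.csv"),
      consensus = wr(as.data.frame(SummarizedExperiment::rowData(cs)[
        , c("compound_id", "neutral_mass", "rt", "n_members")]),
        "consensus.csv"),
      screening = wr(report, "screening_report.csv"),
      annotation = wr(ann_report, "annotation_report.csv"),
      inclusion = wr(inclusion, "inclusion_list.csv"))
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(cfg[setdiff(names(cfg), c("compounds", "config"))],
                     cfg_path)
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      sprintf("afuScreen %s", as.character(utils::packageVersion("afuScreen"))),
      sprintf("R %s", as.character(getRversion())),
      sprintf("seed %d", cfg$seed),
      sprintf("config_hash %s", .config_hash(cfg)),
      sprintf("runs %d (samples %d, controls %d)", length(runs),
              sum(groups == "sample"), sum(groups == "control")),
      sprintf("features %d", nrow(features)),
      sprintf("consensus_compounds %d", nrow(cs)),
      sprintf("selected_ligands %d", nrow(selected)),
      sprintf("elapsed_s %.1f", as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")))),
      log_path)
    files <- c(files, config = cfg_path, log = log_path)
  }
  invisible(list(runs = runs, features = features, consensus = cs,
                 report = report, selected = selected,
                 inclusion = inclusion, manifest = manifest,
                 files = files))
}
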