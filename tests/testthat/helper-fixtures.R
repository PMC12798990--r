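# In-code fixtures shared across test files.

# A dense Gaussian mass trace (amplitude in counts, sigma/rt in minutes).
makeGaussianTrace <- function(apex_rt = 5, sigma = 0.05, amplitude = 1e6,
                              mz = 359.1125, from = apex_rt - 4 * sigma,
                              to = apex_rt + 4 * sigma, dt_s = 0.5,
                              noise_sd = 0, baseline = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rt <- seq(from, to, by = dt_s / 60)
  y <- amplitude * exp(-(rt - apex_rt)^2 / (2 * sigma^2)) + baseline
  if (noise_sd > 0) y <- pmax(0, y + rnorm(length(rt), 0, noise_sd))
  list(mz = mz, rt = rt, intensity = y, scan = seq_along(rt))
}

# A minimal ConsensusSet with given paired area matrices (compounds x n).
makeConsensusSet <- function(sample_areas, control_areas,
                             mass = NULL, rt = NULL,
                             median_peak_width_s = 12) {
  m <- nrow(sample_areas); n <- ncol(sample_areas)
  if (is.null(mass)) mass <- 300 + seq_len(m)
  if (is.null(rt)) rt <- 5 + seq_len(m)
  area <- cbind(sample_areas, control_areas)
  colnames(area) <- c(paste0("sample_", seq_len(n)),
                      paste0("control_", seq_len(n)))
  rowdat <- S4Vectors::DataFrame(
    compound_id = sprintf("cmp_%d", seq_len(m)),
    neutral_mass = mass, mz = mass + 1.007276, rt = rt,
    n_members = rowSums(!is.na(area)),
    member_features = "synthetic")
  coldat <- S4Vectors::DataFrame(
    run_id = colnames(area),
    group = rep(c("sample", "control"), each = n),
    replicate = rep(seq_len(n), 2),
    row.names = colnames(area))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(area = area), rowData = rowdat, colData = coldat)
  rownames(se) <- rowdat$compound_id
  out <- methods::new("ConsensusSet", se)
  S4Vectors::metadata(out) <- list(median_peak_width_s = median_peak_width_s)
  out
}

# A small paired experiment: a strong binder, a weak binder and a matrix
# compound, over a short gradient.
smallScenario <- function(seed = 11, run_duration = 15, ...) {
  list(
    compounds = trueCompounds(
      formula = c("C19H18O7", "C15H12O5", "C10H12O4"),
      retention_time = c(5, 8, 12),
      base_area = c(1e7, 8e6, 6e6),
      enrichment = c(2, 1.5, 1),
      name = c("binder_strong", "binder_weak", "matrix_1")),
    config = experimentConfig(run_duration = run_duration, seed = seed, ...))
}
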