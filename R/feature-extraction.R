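#' Build ppm-bounded mass traces from a centroided run
#'
#' Pools all centroids of a run, sorts them by m/z, and cuts the sorted
#' list wherever the gap between neighbouring centroids exceeds the ppm
#' tolerance, so each centroid belongs to at most one trace. Within an m/z
#' cluster, traces are additionally split where more than `max_gap`
#' consecutive scans are missing; only one centroid per scan (the most
#' intense) is kept per trace. Traces shorter than `min_points` are
#' discarded.
#'
#' @param run An [MsRun-class] with time-ordered centroid scans.
#' @param tol_ppm Mass tolerance in ppm, default 5.
#' @param max_gap Maximum number of consecutive missing scans before a
#'   trace is closed, default 2.
#' @param min_points Minimum number of points per emitted trace, default 3.
#' @return List of traces; each is a list with `mz` (intensity-weighted
#'   centre), `rt`, `intensity`, and `scan` (scan indices).
#' @export
buildMassTraces <- function(run, tol_ppm = 5, max_gap = 2, min_points = 3) {
  stopifnot(is(run, "MsRun"))
  if (is.unsorted(scanTimes(run)))
    stop("spectra must be ordered by retention time")
  pk <- peaksData(run)
  npts <- vapply(pk, nrow, integer(1))
  if (sum(npts) == 0) return(list())
  scan <- rep(seq_along(pk), npts)
  mz <- unlist(lapply(pk, function(p) p[, 1]), use.names = FALSE)
  int <- unlist(lapply(pk, function(p) p[, 2]), use.names = FALSE)
  rt <- scanTimes(run)

  ord <- order(mz)
  mz <- mz[ord]; int <- int[ord]; scan <- scan[ord]
  gap <- c(FALSE, diff(mz) > tol_ppm * 1e-6 * mz[-length(mz)])
  cluster <- cumsum(gap)

  traces <- list()
  for (idx in split(seq_along(mz), cluster)) {
    if (length(idx) < min_points) next
    s <- scan[idx]; m <- mz[idx]; y <- int[idx]
    o <- order(s, -y)
    s <- s[o]; m <- m[o]; y <- y[o]
    keep <- !duplicated(s)        # one centroid per scan: the most intense
    s <- s[keep]; m <- m[keep]; y <- y[keep]
    # close the trace after max_gap consecutive missing scans
    piece <- cumsum(c(FALSE, diff(s) > max_gap + 1))
    for (sub in split(seq_along(s), piece)) {
      if (length(sub) < min_points) next
      traces[[length(traces) + 1L]] <- list(
        mz = sum(m[sub] * y[sub]) / sum(y[sub]),
        rt = rt[s[sub]], intensity = y[sub], scan = s[sub])
    }
  }
  traces
}

#' Trapezoidal peak-area integration
#'
#' Integrates a mass trace between two retention times by the trapezoidal
#' rule, with time converted to seconds, so areas are in ion counts x s.
#'
#' @param trace A trace from [buildMassTraces()], or any list with numeric
#'   `rt` (minutes) and `intensity`.
#' @param rt_start,rt_end Integration window in minutes
#'   (`rt_start < rt_end`).
#' @return Peak area (ion counts x s).
#' @export
integrateArea <- function(trace, rt_start, rt_end) {
  stopifnot(rt_start < rt_end)
  sel <- trace$rt >= rt_start & trace$rt <= rt_end
  if (sum(sel) < 2)
    stop("integration window contains fewer than two trace points")
  t_s <- trace$rt[sel] * 60
  y <- trace$intensity[sel]
  sum(diff(t_s) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

## Locates candidate peaks (threshold-independent): local maxima with
## boundaries at flanking minima or baseline return.
.candidate_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  apex <- which(y > 0 &
                  y >= c(-Inf, y[-n]) &
                  y > c(y[-1], -Inf))
  apex <- apex[apex > 1 & apex < n]
  apex
}

.peak_bounds <- function(y, a) {
  n <- length(y)
  lo <- a
  while (lo > 1 && y[lo - 1] <= y[lo] && y[lo - 1] > 0) lo <- lo - 1
  if (lo > 1 && y[lo - 1] == 0) lo <- lo - 1  # include baseline touch
  hi <- a
  while (hi < n && y[hi + 1] <= y[hi] && y[hi + 1] > 0) hi <- hi + 1
  if (hi < n && y[hi + 1] == 0) hi <- hi + 1
  c(lo, hi)
}

#' Detect chromatographic peaks in a mass trace
#'
#' Peaks are local maxima with boundaries at the flanking minima (or
#' baseline return). The noise level is estimated robustly as 1.4826 x the
#' median absolute deviation of the off-peak trace intensities (points
#' outside every prominent candidate peak, prominence judged against the
#' trace's high-frequency MAD), floored at 1 count; S/N is peak height
#' over this estimate. Peaks below `min_height` or below `snr_min` are
#' suppressed, so lowering either threshold can only add features, never
#' remove one.
#'
#' @param trace A trace from [buildMassTraces()].
#' @param snr_min Minimum signal-to-noise ratio, default 3.
#' @param min_height Minimum apex intensity in ion counts, default 1e5.
#' @return `data.frame` of features: `mz`, `neutral_mass` (assuming
#'   [M+H]+), `rt_apex`, `rt_start`, `rt_end` (minutes), `height`, `area`
#'   (ion counts x s), `snr`.
#' @export
detectPeaks <- function(trace, snr_min = 3, min_height = 1e5) {
  empty <- data.frame(mz = numeric(), neutral_mass = numeric(),
                      rt_apex = numeric(), rt_start = numeric(),
                      rt_end = numeric(), height = numeric(),
                      area = numeric(), snr = numeric())
  y <- trace$intensity
  apexes <- .candidate_peaks(y)
  if (!length(apexes)) return(empty)
  bounds <- lapply(apexes, .peak_bounds, y = y)
  ## Two-pass noise estimate. The provisional level comes from the
  ## high-frequency component (scaled MAD of successive differences),
  ## which stays small on smooth peak-dominated traces; candidates
  ## prominent against it are masked, and the final estimate is the MAD
  ## of the remaining off-peak points (falling back to the provisional
  ## level when too few remain). Independent of the snr_min/min_height
  ## arguments, so detection stays monotone in both.
  provisional <- max(1, stats::mad(diff(y)) / sqrt(2))
  in_peak <- rep(FALSE, length(y))
  for (i in seq_along(apexes)) {
    if (y[apexes[i]] > 3 * provisional) {
      b <- bounds[[i]]
      in_peak[b[1]:b[2]] <- TRUE
    }
  }
  off <- y[!in_peak]
  noise <- if (length(off) >= 3) max(1, stats::mad(off)) else provisional

  rows <- lapply(seq_along(apexes), function(i) {
    a <- apexes[i]; b <- bounds[[i]]
    if (b[1] >= a || b[2] <= a || b[2] - b[1] < 2) return(NULL)
    area <- integrateArea(trace, trace$rt[b[1]], trace$rt[b[2]])
    data.frame(mz = trace$mz, neutral_mass = neutralFromMz(trace$mz),
               rt_apex = trace$rt[a], rt_start = trace$rt[b[1]],
               rt_end = trace$rt[b[2]], height = y[a], area = area,
               snr = y[a] / noise)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[out$height >= min_height & out$snr >= snr_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect and quantify all features in a run
#'
#' Convenience wrapper: builds mass traces with [buildMassTraces()] and
#' runs [detectPeaks()] on each, returning the per-run feature table.
#'
#' @inheritParams buildMassTraces
#' @inheritParams detectPeaks
#' @return `data.frame` with columns `run_id`, `mz`, `neutral_mass`,
#'   `rt_apex`, `rt_start`, `rt_end`, `height`, `area`, `snr`, sorted by
#'   `rt_apex` then `mz`.
#' @export
detectFeatures <- function(run, tol_ppm = 5, max_gap = 2, min_points = 3,
                           snr_min = 3, min_height = 1e5) {
  traces <- buildMassTraces(run, tol_ppm = tol_ppm, max_gap = max_gap,
                            min_points = min_points)
  tabs <- lapply(traces, detectPeaks, snr_min = snr_min,
                 min_height = min_height)
  out <- do.call(rbind, tabs)
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(run_id = character(), mz = numeric(),
                      neutral_mass = numeric(), rt_apex = numeric(),
                      rt_start = numeric(), rt_end = numeric(),
                      height = numeric(), area = numeric(), snr = numeric())
    return(out)
  }
  out <- cbind(run_id = runId(run), out)
  out <- out[order(out$rt_apex, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
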