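#' @include AllClasses.R
NULL

## Monoisotopic atomic masses, IUPAC 2021 (12C defines the scale exactly).
## Pinned here as the single source of truth for bit-reproducibility.
.ATOMIC_MASS <- c(C = 12, H = 1.0078250319, O = 15.9949146221)

## Mass of the proton; [M+H]+ <-> neutral conversions.
.PROTON_MASS <- 1.007276466621

## Nominal A+1 isotopologue spacing (13C - 12C).
.C13_OFFSET <- 1.00336

## Natural isotope abundances used by the pattern model.
.P_13C <- 0.0107
.P_18O <- 0.00205

.ADDUCTS <- list("[M+H]+" = .PROTON_MASS)

#' Parse molecular formulas in Hill notation
#'
#' Parses CHO formulas such as `"C19H18O7"` or `"CH4"` into element counts.
#' Only carbon, hydrogen and oxygen are supported; any other element symbol
#' is an error.
#'
#' @param x Character vector of formulas.
#' @return Integer matrix with one row per formula and columns `C`, `H`, `O`.
#' @examples
#' parseFormula(c("C19H18O7", "H2O"))
#' @export
parseFormula <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  out <- matrix(0L, nrow = length(x), ncol = 3,
                dimnames = list(x, c("C", "H", "O")))
  for (i in seq_along(x)) {
    f <- x[i]
    if (is.na(f) || !nzchar(f))
      stop("empty formula string at position ", i)
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    parts <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    if (sum(nchar(parts)) != nchar(f))
      stop("cannot parse formula '", f, "'")
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      n <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% colnames(out))
        stop("unsupported element '", el, "' in formula '", f,
             "' (only C, H, O are supported)")
      out[i, el] <- out[i, el] + n
    }
  }
  out
}

.as_counts <- function(formula) {
  if (is.character(formula)) return(parseFormula(formula))
  if (is.null(dim(formula))) formula <- matrix(formula, nrow = 1,
                                               dimnames = list(NULL, names(formula)))
  if (!all(c("C", "H", "O") %in% colnames(formula)))
    stop("formula counts need columns C, H and O")
  m <- formula[, c("C", "H", "O"), drop = FALSE]
  if (any(m < 0)) stop("invalid formula: negative element count")
  if (any(m != round(m))) stop("invalid formula: non-integer element count")
  storage.mode(m) <- "integer"
  m
}

#' Format element counts as Hill-notation formulas
#'
#' @param counts Integer matrix or vector with elements/columns `C`, `H`, `O`.
#' @return Character vector of formulas (e.g. `"C19H18O7"`; unit counts omit
#'   the digit, zero counts omit the element).
#' @export
formulaString <- function(counts) {
  m <- .as_counts(counts)
  unname(apply(m, 1, function(r) {
    s <- ""
    for (el in c("C", "H", "O")) {
      if (r[el] == 0) next
      s <- paste0(s, el, if (r[el] > 1) r[el] else "")
    }
    s
  }))
}

#' Monoisotopic mass of a CHO formula
#'
#' Sum of monoisotopic atomic masses over the element counts. Additive in
#' composition; the empty formula has mass 0.
#'
#' @param formula Character vector of Hill formulas, or a counts matrix /
#'   named vector with elements `C`, `H`, `O`.
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopicMass("C19H18O7")  # ~358.1053
#' @export
monoisotopicMass <- function(formula) {
  m <- .as_counts(formula)
  as.numeric(m %*% .ATOMIC_MASS[colnames(m)])
}

#' Signed ppm error between an observed and a theoretical mass
#'
#' @param observed,theoretical Numeric vectors (Da or Th).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppmError <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Convert between neutral mass and adduct m/z
#'
#' `mzFromNeutral` maps a neutral monoisotopic mass to the ion m/z for a
#' supported adduct (only `[M+H]+` in this release); `neutralFromMz` is its
#' exact inverse.
#'
#' @param mass,mz Numeric vector of neutral masses (Da) / ion m/z (Th); must
#'   be positive.
#' @param adduct Adduct tag, default `"[M+H]+"`.
#' @return Numeric vector.
#' @export
mzFromNeutral <- function(mass, adduct = "[M+H]+") {
  if (!adduct %in% names(.ADDUCTS))
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("neutral mass must be positive")
  mass + .ADDUCTS[[adduct]]
}

#' @rdname mzFromNeutral
#' @export
neutralFromMz <- function(mz, adduct = "[M+H]+") {
  if (!adduct %in% names(.ADDUCTS))
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  if (any(!is.finite(mz)) || any(mz <= .ADDUCTS[[adduct]]))
    stop("m/z must exceed the adduct mass")
  mz - .ADDUCTS[[adduct]]
}

#' Ring-and-double-bond equivalents of a CHO formula
#'
#' RDBE = C - H/2 + 1. May be half-integer (odd-electron species) or
#' negative (chemically implausible); used as a plausibility filter during
#' formula enumeration.
#'
#' @inheritParams monoisotopicMass
#' @return Numeric vector.
#' @export
rdbe <- function(formula) {
  m <- .as_counts(formula)
  m[, "C"] - m[, "H"] / 2 + 1
}

#' Enumerate CHO molecular formulas matching an accurate mass
#'
#' Returns every formula within the element-count bounds whose monoisotopic
#' mass lies within `tol_ppm` of `query_mass` and whose RDBE lies within
#' `rdbe_bounds`. The default bounds are the full-scan deconvolution
#' constraints used throughout the package: minimum composition CHO (at
#' least one carbon) and maximum composition C90H190O90.
#'
#' @param query_mass Neutral monoisotopic mass to match, Da (> 0).
#' @param tol_ppm Mass tolerance in ppm (> 0), default 5.
#' @param min_counts,max_counts Named vectors (`C`, `H`, `O`) of inclusive
#'   element-count bounds.
#' @param rdbe_bounds Length-2 inclusive RDBE interval, default `c(0, 40)`.
#' @return `data.frame` with columns `formula`, `n_C`, `n_H`, `n_O`,
#'   `theoretical_mass`, `ppm_error`, `rdbe`, sorted by absolute ppm error
#'   (ties broken by `(n_C, n_H, n_O)`).
#' @examples
#' enumerateFormulas(358.1052)
#' @export
enumerateFormulas <- function(query_mass, tol_ppm = 5,
                              min_counts = c(C = 1, H = 0, O = 0),
                              max_counts = c(C = 90, H = 190, O = 90),
                              rdbe_bounds = c(0, 40)) {
  stopifnot(length(query_mass) == 1, is.finite(query_mass), query_mass > 0)
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1 || tol_ppm <= 0)
    stop("mass tolerance must be a single positive ppm value")
  min_counts <- min_counts[c("C", "H", "O")]
  max_counts <- max_counts[c("C", "H", "O")]
  if (any(is.na(min_counts)) || any(is.na(max_counts)))
    stop("min_counts and max_counts need named elements C, H, O")
  if (any(min_counts > max_counts))
    stop("min_counts must not exceed max_counts")
  lo <- query_mass * (1 - tol_ppm * 1e-6)
  hi <- query_mass * (1 + tol_ppm * 1e-6)
  mC <- .ATOMIC_MASS[["C"]]; mH <- .ATOMIC_MASS[["H"]]; mO <- .ATOMIC_MASS[["O"]]
  res <- vector("list", 64L); nres <- 0L
  c_max <- min(max_counts[["C"]], floor(hi / mC))
  c_rng <- seq.int(max(min_counts[["C"]], 0L), c_max)
  for (nc in c_rng) {
    rem_c <- hi - nc * mC
    if (rem_c < 0) break
    o_max <- min(max_counts[["O"]], floor(rem_c / mO))
    for (no in seq.int(min_counts[["O"]], o_max)) {
      base <- nc * mC + no * mO
      h_lo <- max(min_counts[["H"]], ceiling((lo - base) / mH))
      h_hi <- min(max_counts[["H"]], floor((hi - base) / mH))
      if (h_hi < h_lo) next
      for (nh in seq.int(h_lo, h_hi)) {
        mass <- base + nh * mH
        if (mass < lo || mass > hi) next
        r <- nc - nh / 2 + 1
        if (r < rdbe_bounds[1] || r > rdbe_bounds[2]) next
        nres <- nres + 1L
        res[[nres]] <- c(nc, nh, no, mass, r)
      }
    }
  }
  if (nres == 0L) {
    return(data.frame(formula = character(), n_C = integer(), n_H = integer(),
                      n_O = integer(), theoretical_mass = numeric(),
                      ppm_error = numeric(), rdbe = numeric()))
  }
  m <- do.call(rbind, res[seq_len(nres)])
  out <- data.frame(
    formula = formulaString(cbind(C = m[, 1], H = m[, 2], O = m[, 3])),
    n_C = as.integer(m[, 1]), n_H = as.integer(m[, 2]), n_O = as.integer(m[, 3]),
    theoretical_mass = m[, 4],
    ppm_error = ppmError(query_mass, m[, 4]),
    rdbe = m[, 5])
  out <- out[order(abs(out$ppm_error), out$n_C, out$n_H, out$n_O), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coarse isotopologue pattern of a CHO formula
#'
#' Abundances follow independent binomial substitution of 13C
#' (p = 0.0107) and 18O (p = 0.00205); an 18O substitution contributes two
#' nominal mass units, so isotopologue A+k collects j 13C plus m 18O
#' substitutions with j + 2m = k. Masses use the nominal A+1 spacing of
#' 1.00336 Da and abundances are expressed relative to the monoisotopic
#' peak. Fine structure is deliberately out of scope.
#'
#' @inheritParams monoisotopicMass
#' @param n_isotopologues Number of isotopologue peaks to return (>= 1),
#'   including the monoisotopic peak.
#' @return `data.frame` with columns `k` (0-based isotopologue index),
#'   `mass` (Da) and `abundance` (fraction of monoisotopic).
#' @examples
#' isotopePattern("C19H18O7", 2)
#' @export
isotopePattern <- function(formula, n_isotopologues = 3) {
  m <- .as_counts(formula)
  if (nrow(m) != 1) stop("one formula at a time")
  if (sum(m) == 0) stop("isotope pattern of the empty formula is undefined")
  stopifnot(n_isotopologues >= 1)
  mono <- monoisotopicMass(m)
  ks <- seq.int(0L, n_isotopologues - 1L)
  p0 <- stats::dbinom(0, m[, "C"], .P_13C) * stats::dbinom(0, m[, "O"], .P_18O)
  ab <- vapply(ks, function(k) {
    tot <- 0
    for (m18 in 0:(k %/% 2)) {
      j <- k - 2L * m18
      tot <- tot + stats::dbinom(j, m[, "C"], .P_13C) *
        stats::dbinom(m18, m[, "O"], .P_18O)
    }
    tot / p0
  }, numeric(1))
  data.frame(k = ks, mass = mono + ks * .C13_OFFSET, abundance = ab)
}
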