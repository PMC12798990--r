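---
title: "Screening enzyme ligands by affinity ultrafiltration LC-MS: methods and design"
author: "afuScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening enzyme ligands by affinity ultrafiltration LC-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The screen and its statistical model

Affinity ultrafiltration ("ligand fishing") incubates a complex extract
with a target enzyme, retains enzyme–ligand complexes on a
molecular-weight-cutoff membrane, washes away unbound compounds, and
releases the bound ligands for LC-MS analysis. Because many matrix
compounds bind membranes and denatured protein nonspecifically, every
sample run (active enzyme) is paired with a control run in which the
enzyme was heat-denatured: a compound retained equally in both tells us
nothing, while genuine ligands are enriched in the sample group.

The decisive statistic is the **peak area ratio (PAR)**. For replicate
pair $i$ of $n$ (four by default),

$$\mathrm{PAR}_i = \frac{A^{\mathrm{sample}}_i}{A^{\mathrm{control}}_i},$$

where $A$ is the integrated chromatographic peak area of the compound's
[M+H]$^+$ trace. A compound is selected as a ligand when

$$\overline{\mathrm{PAR}} > 1 \quad\text{and}\quad p < 0.05,$$

with $p$ from a two-tailed two-sample t-test of the raw sample areas
against the raw control areas. Both inequalities are strict. The PAR > 1
conjunct makes the rule effectively one-sided, so under the null the
empirical selection rate is well below the nominal $\alpha$ — the
calibration suite measures about 2.5% at $\alpha = 0.05$.

Assumptions worth stating explicitly:

* Areas are paired by replicate (pair $i$ of the sample group against
  pair $i$ of the control group), matching how the specimens are
  prepared; a ratio-of-group-means variant is deliberately not the
  default.
* The t-test runs on raw areas with pooled variance (Student). The
  source workflow states only "two-tailed t-test"; Welch and
  Benjamini–Hochberg correction are available as options
  (`screenCompounds(variant = "welch", correction = "BH")`) but off by
  default, since the original screen applied neither.
* PAR dispersion is reported as the sample SD with the $n-1$
  denominator. The source tables do not state the denominator; $n-1$ is
  the conventional choice for $n = 4$ replicates.
* A compound absent from every control run is imputed at the detection
  floor (minimum peak intensity × median peak width) rather than
  dropped: full depletion from the control is the strongest evidence of
  binding, and dropping such compounds would systematically discard true
  positives. Imputed compounds are flagged `imputed_control`.

## From raw scans to the area matrix

The pipeline mirrors the standard untargeted workflow — align
retention time, detect compounds, group compounds — with every
tolerance surfaced in `pipelineConfig()`:

| parameter | default | unit | role |
|---|---|---|---|
| `ppm` | 5 | ppm | mass tolerance for traces, grouping, formula assignment, annotation |
| `rt_tol` | 0.1 | min | retention-time grouping tolerance |
| `snr_min` | 3 | – | chromatographic S/N threshold |
| `min_height` | 1e5 | counts | minimum peak apex intensity |
| `max_gap` | 2 | scans | missing scans before a trace closes |
| `par_threshold` | 1 | – | mean-PAR selection threshold (strict) |
| `alpha` | 0.05 | – | significance level (strict) |
| `rt_window` | 0.5 | min | half-width of targeted-MS/MS windows |

Mass traces are built by pooling all centroids of a run, sorting by m/z
and cutting at gaps larger than the ppm tolerance; within a trace only
the most intense centroid per scan is kept, and a run of more than
`max_gap` missing scans closes the trace. Peaks are local maxima with
boundaries at flanking minima or baseline return; areas come from the
trapezoidal rule with time in seconds.

The S/N denominator is estimated in two passes: a provisional level from
the scaled median absolute deviation of successive intensity
differences (which stays small on smooth, peak-dominated traces), then
the MAD of the off-peak points after masking candidates prominent
against that level, floored at one count. A single-pass MAD of raw
intensities fails on traces that are mostly peak — several co-eluting
same-formula isomers chained into one trace would otherwise suppress
each other. Because the estimator never looks at `snr_min` or
`min_height`, detection is monotone: relaxing either threshold can only
add features. Note that absolute S/N values are not comparable with
vendor software, which does not document its estimator; the vendor's
"intensity tolerance" detection parameter is likewise recorded in the
configuration for provenance but has no public definition and is not
used.

Alignment corrects each run by a single RT offset — the median RT
difference of mutual-nearest mass matches against the reference run (the
run with the most features). A 30-minute gradient with 0.1-min grouping
tolerance needs no warping curve at this scale; pairs more than 0.5 min
apart are excluded from the offset median so that same-mass positional
isomers cannot corrupt it. Grouping is greedy in order of descending
feature height (ties by ascending m/z, fixed for determinism); consensus
mass and RT are medians over members, each feature joins at most one
consensus, and each consensus takes at most one feature per run.
Isotopologue satellites (+1.00336 or +2.00672 Da within tolerance, same
RT, smaller total area) are collapsed onto their monoisotopic record
after alignment; keeping them through detection keeps the peak picker
generic.

## Formula assignment

CHO formulas are enumerated within the element bounds C$_{1-90}$
H$_{0-190}$ O$_{0-90}$ — the "minimum composition CHO" constraint is
read as *at least one carbon*, the weakest interpretation that excludes
non-organic compositions — and filtered to the ppm window and an RDBE
interval of $[0, 40]$ by default (wide, because the original workflow
applies no explicit RDBE filter; `rdbe_bounds` is configurable).
Candidates are ordered by absolute ppm error with lexicographic
$(n_C, n_H, n_O)$ tie-breaks, fixed for determinism. Atomic masses are
pinned to IUPAC monoisotopic values in a single constant table so
results are bit-reproducible across platforms.

Annotation reuses the grouping tolerances: a knowledge-base compound
matching in mass and RT contributes its name; a mass match at another RT
contributes "*name* isomer"; several same-formula names are joined with
"/". The packaged knowledge base transcribes the published 84-ligand
screen (20 reference standards, 64 literature assignments) and the
26-compound definite-structure subset, with md5 checksums verified on
load. Three rows print a placeholder molecular weight (578.0000) and one
prints a detected MW about 8 ppm from its formula; these carry
`mw_placeholder`/`mw_outlier` flags and are excluded from
mass-consistency audits. One PAR value misprinted by a factor of 100 is
corrected and flagged `par_typo`.

## What the synthetic generator emulates — and what it does not

`simulateExperiment()` produces the paired design end to end: 2 × 4
centroided MS1 runs over a 30-min gradient at 0.5-s scan intervals, m/z
150–1000, each compound eluting as a Gaussian of σ = 0.05 min at its
[M+H]$^+$ m/z with its first three isotopologues (binomial $^{13}$C,
p = 0.0107, plus $^{18}$O, p = 0.00205). Realized areas carry
multiplicative log-normal noise; each run receives a Gaussian RT shift
(σ = 0.02 min) that the aligner must undo; each centroid receives 1-ppm
Gaussian mass error; spurious low-intensity centroids arrive at one per
scan. Choices and their reasons:

* **Peak width.** σ = 0.05 min (≈ 7 s FWHM) is typical sub-2-µm UPLC
  performance and, more importantly, is required for internal
  consistency: the packaged ligand table lists same-formula isomer pairs
  as close as 0.14 min, which a σ = 0.1 min peak cannot resolve into two
  maxima. The 0.5-s scan interval leaves ~12 points per σ.
* **Noise scale.** The default area CV is 0.10, but the phantom library
  derives a per-compound CV from the published PAR dispersion,
  $\mathrm{cv}_i = \mathrm{sd}_i / (\overline{\mathrm{PAR}}_i\sqrt{2})$,
  attributing the observed ratio noise equally to numerator and
  denominator. The generator thus reproduces each compound's published
  mean ± SD rather than a single global noise level.
* **Ratio expectation.** Noise is symmetric on the log scale, so the
  *median* realized sample/control ratio equals the planted enrichment
  exactly, while the mean exceeds it by $e^{\sigma^2}$ (≈ 1% at CV 0.1).
* **Nonspecific binding.** Whether membrane binding inflates control
  areas uniformly is not documented; `nonspecific_floor` exposes the
  mechanism (control expectation $= (1+\text{floor})\times$ base area)
  with a default of 0 rather than asserting one.
* **Matrix compounds.** `defaultPhantomLibrary()` adds 50 non-binders
  with random plausible CHO formulas (C 10–30, RDBE 0–15, 160–880 Da)
  at uniform RTs, base areas log-uniform in [2.5e6, 4e7] (peak heights
  comfortably above the 1e5 detection floor, as expected after an
  enrichment protocol); compounds are kept ≥ 10 ppm or ≥ 0.25 min from
  one another so ground truth stays unambiguous.

Not emulated: chromatographic tailing, ion suppression, wash carry-over,
profile-mode peaks, MS/MS spectra, and RT warping beyond a constant
shift. Passing the closure suites therefore demonstrates that the
statistics, grouping and annotation logic are correct under the stated
noise model — not that the detector would cope with strongly tailing or
suppressed real-world peaks.

## Calibration results the test-suite recomputes

With the defaults above, the suites measure (sizes chosen to make the
binomial error bars meaningful at desk scale):

* **Null calibration** — 200 planted null compounds × 50 seeds: the
  selection rate stays below $0.05 + 3\,\mathrm{SE}$ (observed ≈ 0.025,
  reflecting the one-sided conjunct).
* **Power** — the same design at enrichment 2: sensitivity ≥ 0.90
  (observed ≈ 1.0).
* **Pipeline closure** — the 84-ligand phantom library plus 50 matrix
  compounds through the full spectra-level pipeline: ≥ 95% of planted
  binders are selected and annotated with their planted name or isomer
  label at the default seed; the three or so misses are always the
  weakest binders (published PAR ≤ 1.3), for which a two-sample t-test
  at $n = 4$ genuinely has power well below 1 — per-seed recovery
  fluctuates between roughly 0.94 and 0.99, which is an honest property
  of the published design, not of the implementation.
* **Oracle equivalence** — formula enumeration agrees exactly with an
  exhaustive search over all bounded compositions on random masses; the
  t-test p equals the hand-written pooled closed form to 1e-10 and
  tracks a $10^6$-draw permutation oracle. At $n = 4$ per group the
  permutation distribution has only 70 atoms, so Student p and
  permutation p can differ by far more than Monte-Carlo error; the
  quantitative comparison is therefore made at $n = 12$ per group,
  where the randomization approximation is good, with a 0.03 absolute
  band.

## Degenerate inputs and tie-breaks

Zero variance in both groups yields $p = 1$ for equal means and $p = 0$
with a warning otherwise (arising in practice only from fully-imputed
controls). Compounds with fewer than two usable replicate pairs are
excluded with a recorded reason rather than scored. Integration windows
with fewer than two points, empty compound lists, RTs outside the run,
unordered scans, and profile-mode mzML all fail fast with named errors.
All orderings that affect output (feature processing, candidate
formulas, inclusion entries) have fixed deterministic tie-breaks, and
every random draw flows from the single configured seed, so a rerun with
the same configuration is byte-identical.

## Limitations

Absolute S/N values differ from vendor software by construction. The
single-offset RT correction would be inadequate for multi-batch studies.
Only [M+H]$^+$ and elements C/H/O are supported in this release, which
matches the flavonoid-focused screen the package models but not general
metabolomics. MS/MS fragment matching is out of scope; the inclusion
list hands off to the instrument instead.
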