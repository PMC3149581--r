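---
title: "Single-step m/z detection for LC-orbitrap profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step m/z detection for LC-orbitrap profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdorap)
```

## The problem and the modelling stance

Non-targeted metabolic profiling by LC-MS asks for a list of m/z features,
comparable across biological samples, from runs that each contain on the
order of a million centroid data points. The conventional workflow detects
chromatographic peaks per sample in both the m/z and retention-time
dimensions and then aligns the per-sample peak lists. That design couples
the quality of the final m/z values to a retention-time alignment, even
though on an orbitrap the *time* axis is the unstable one (gradient drift,
column ageing) while the *mass* axis is stable to a few ppm without
recalibration.

This package inverts the priority. Its working assumptions are:

* almost all centroid data points in a run are background noise, and the
  informative ions sit in a small top fraction of the intensity
  distribution;
* ions of the same composition appear at nearly the same m/z in every
  sample and every scan, regardless of when they elute;
* therefore, pooling the high-intensity points of *all* samples and
  clustering them on the m/z axis alone performs peak picking and
  cross-sample alignment simultaneously, and no retention-time warping is
  ever needed.

The output unit is the **m/z group**: a set of pooled data points whose
neighbor gaps are all within a ppm tolerance, represented by its median
m/z, with one extracted ion chromatogram (EIC) per sample.

## The procedure

**Collection.** Each sample's points are ranked by intensity and the top
`top_fraction` (default 0.01) are kept: with `N` points the threshold is
the intensity of the `⌈f·N⌉`-th largest, and all points at or above it are
retained. Ties are therefore all kept — the retained set is a deterministic
function of the multiset of intensities, independent of input order.
Thresholding is strictly per sample: scaling one sample's intensities by
any positive constant does not change which of *its* points are collected,
so a globally dimmer sample still contributes its own top fraction.

**Grouping.** The pooled m/z values are sorted and cut wherever the
relative neighbor gap exceeds `closeness_ppm` (default 5):
`(m_i − m_{i−1})/m_{i−1} × 10⁶ > tol`. The denominator is fixed as the
*lower* member of the pair; at 5 ppm the difference from using the mean is
negligible, but an explicit convention makes results bit-reproducible.
This is single-linkage chaining with no cap on group size or span, which
matches the intent that all observations of one ion — however many samples
and scans it appears in — land in one group. The degenerate consequence
(a long chain of points each within tolerance of the next can span far
more than the tolerance) is accepted deliberately; with well-separated
compounds it does not arise.

**Representative m/z.** The median of the pooled member m/z values; for an
even count, the mean of the two central values (the standard convention).
The median is label-free — permuting sample assignments cannot change it —
and robust to the occasional outlying observation at the cloud's edge.

**Extraction.** For each group and sample, the EIC sums, per scan, all
centroid peaks inside the inclusive window `m·(1 ± tol·10⁻⁶)` (default
±5 ppm). Window ends are closed on both sides: a half-open window would
drop a boundary peak or keep it depending on the last bit of floating-point
rounding. Each sample keeps its own scan grid; traces are never resampled
or aligned.

**Quantification.** Two values per trace. `eic_sum` is the plain sum of the
raw trace. `sn_area` is the sum of *raw* intensities over the scans
selected by a signal-to-noise gate applied to the Gaussian-smoothed trace;
smoothing only ever selects scans, it never rescales the quantity, so the
two numbers remain directly comparable and `0 ≤ sn_area ≤ eic_sum` always
holds.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `top_fraction` | 0.01 | – | per-sample collected fraction |
| `closeness_ppm` | 5 | ppm | neighbor-gap grouping tolerance |
| `eic_tol_ppm` | 5 | ppm | EIC window half-width |
| `sn_cutoff` | 3 | – | S/N gate multiple |
| `gaussian_sigma_scans` | 3 | scans | smoothing kernel sigma |
| `min_region_scans` | 3 | scans | shortest admissible peak region |
| `stretch_fraction` | 0.8 | – | stretched-trace reliability bound |
| `annotation_tol_ppm` | 5 | ppm | database matching tolerance |

The first three are the method's standard settings. The quantification
parameters are not prescribed by the method itself; the values here are
conventional chromatography choices (a 3-scan sigma smooths electronic
spikes without merging separate elution events at typical scan rates; an
S/N of 3 and a 3-scan minimum are the usual detection floor) and all of
them are exposed through `amdorap_config()`.

**Noise estimation.** The gate needs a noise level, for which no standard
definition exists on EIC traces that are mostly exact zeros. The estimator
is the scaled MAD, `1.4826 · median(|x − median(x)|)`, which on a trace
with a flat noisy baseline estimates the baseline standard deviation and is
immune to the peak itself. When the MAD is zero — the majority of scans are
exactly zero, the common case for a narrow window — the estimator falls
back to the smallest positive intensity at or below the trace median (so a
constant positive baseline estimates its own level), and finally to 1.0
intensity count, the smallest meaningful difference on count-like data.
With the fallback at 1.0 the gate `3 × noise` then passes essentially any
real signal, which is the intended behaviour on a clean, sparse trace.

**Reliability.** The published workflow judged chromatograms visually,
flagging traces "stretched" over the whole run or with a noisy baseline.
The automated stand-ins are: *stretched* — more than `stretch_fraction`
(0.8) of scans above the S/N gate; *noisy baseline* — no qualifying region
found, yet more than 20% of scans above one noise level. These are declared
heuristic substitutes for a manual call; the published reliable/unreliable
counts on real data are therefore not targets the test suite asserts.

## The synthetic-data generator

`simulate_run()` emulates the *statistical structure* of a centroid
LC-orbitrap run, which is what the pipeline is sensitive to:

* each compound contributes, per scan, one centroid point with a Gaussian
  elution envelope `apex · exp(−(rt − c)²/2σ²)` (summed over one or two
  elution centers, to reproduce the twice-eluting-compound phenomenon),
  cut off below an intensity floor;
* the m/z of every observation is jittered multiplicatively,
  `m = m₀(1 + ε·10⁻⁶)`, `ε ~ N(0, 1 ppm)` by default — mass error on an
  orbitrap is relative, hence ppm-scale and Gaussian is the natural model;
* the noise floor is uniform in m/z over the instrument range with
  exponential intensities — a maximum-entropy choice for positive,
  low-mean background counts that concentrates most points at negligible
  intensity, matching the observation that ~99% of real points behave as
  background.

The default validation scenario uses 20 compounds spread over m/z
100–1000 (pairwise separations far beyond 20 ppm), apex 5·10⁵ counts,
elution sigma 3.2 min within a 45-min, 1000-scan run, floor 2000 counts,
and 900 noise points per scan with mean 50 counts. Two deliberate,
coupled choices: the floor (2000) sits far above the maximum of ~9·10⁵
exponential noise draws (~950), so compound and noise points are
perfectly separable by intensity; and the broad elution sigma makes the
twenty compounds supply slightly *more* than 1% of all points
(9454 of 909454). Under the default `top_fraction = 0.01` the collected
set then consists of compound points only, which is what makes parameter
recovery exactly checkable: the pipeline must return *exactly* 20 groups,
every median within 1 ppm of its true m/z, and every gated area within 5%
of the injected ion count. The suite asserts exactly that, at seeds fixed
in the tests.

What the generator does **not** emulate: profile peak shapes, isotope
envelopes and adducts of the same compound, co-eluting isobars, detector
saturation, intensity-dependent mass error, and chromatographic peak
widths typical of a modern gradient (the 3.2-min sigma is far broader than
a real LC peak — it is a device for making signal abundance match the
collected fraction with only 20 compounds, where a real run has hundreds
of true ions). Passing the recovery tests therefore demonstrates the
correctness of the collection/grouping/extraction logic under the stated
noise model, not performance on real biological runs.

## Numerical and degenerate-input conventions

* `⌈f·N⌉` (ceiling) defines the collected count; ties at the threshold are
  all kept.
* Grouping gap denominator: the lower m/z of the pair. Even-count median:
  mean of the two central values. Window ends: inclusive.
* `variance_explained()` measures deviations from the **global** mean of
  all intensities (sorting does not change the mean); a constant vector has
  zero total variance and returns 100 by convention, with a warning.
* Smoothing kernels are truncated at ±4σ and renormalized to unit mass,
  also at trace edges (division by the in-bounds kernel mass), so constants
  are fixed points and interior-supported signal is conserved.
* Empty inputs are errors where the operation is meaningless (grouping
  nothing, collecting from a run with no points, serializing an empty run
  to mzML); an empty *database* for annotation is an empty result, not an
  error.
* All simulation randomness derives from the scenario seed
  (Mersenne-Twister, inversion normals); the caller's RNG state is saved
  and restored, so `simulate_run()` has no side effects on the session.
* Profile-mode spectra in an input file are a hard error naming the scan:
  silently centroiding would change quantities in ways this package cannot
  audit.

## Scale of the validation suite

The bundled tests run the full pipeline on two simulated default-scenario
samples (~9·10⁵ points each), check the grouping implementation against a
brute-force single-linkage oracle on 1000 random instances of up to 200
points, and exercise mzML round trips on ~200-scan runs; the whole suite
completes in well under a minute on one CPU. These sizes were chosen to
keep the oracle comparisons exhaustive at small n while the end-to-end
recovery runs at the default scenario's full point count.

## Known limitations

* Isobaric compounds land in the same m/z group by construction; only
  chromatographic or MS² evidence can separate them, and neither is used
  here (annotation reports *all* in-tolerance matches for this reason).
* A contaminant within the ppm window of a real compound inflates both
  quantities; the EIC window has no shape model to reject it.
* Single-linkage grouping can, in principle, chain two nearby ion clouds
  into one group if a bridge of intermediate points exists; the closeness
  sweep (`sweep_closeness()`) is the diagnostic for choosing a tolerance
  where the group count is stable.
* The reliability flags are heuristics tuned for obviously pathological
  traces; borderline chromatograms should be inspected with
  `plot(result, group = i)`.
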