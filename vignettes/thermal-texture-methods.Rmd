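---
title: "Methods: ROI texture analysis of pseudo-color thermograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI texture analysis of pseudo-color thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotex)
```

## The design under analysis

The package analyses a crossed pre/post imaging design: every rider rides
every horse once, and the horse's thoracolumbar region is imaged with an
infrared camera immediately before and after a standardized ridden exercise
bout. Riders are banded by the rider:horse bodyweight ratio,

$$ R/H = 100 \cdot \frac{\text{rider BW} + \text{saddle BW}}{\text{horse BW}} \;[\%], $$

into light (L, 10–12%), moderate (M, >12 ≤15%) and heavy (H, >15 <18%)
groups. With 6 riders (2 per group) and 12 horses this gives 72
combinations and 144 images. Each rider×horse combination is one
statistical realization; per group there are 24 paired pre/post
observations.

Two conventions matter downstream and are applied everywhere:

* **Half-up rounding to 1 decimal** for BMI and bodyweight ratios, before
  banding and before summarising. The published cohort tables print
  1-decimal values and the group ranges quote exactly those; base R's
  round-half-even would disagree on ties such as 23.15.
* **Band edges read literally**: a ratio of exactly 12.0 is L and 15.0 is
  M. Ratios outside [10, 18) are labelled `out-of-design` rather than
  rejected, so simulations may stress the bands.

## From image to feature vector

A pseudo-color thermogram is decomposed into its R, G and B channels; each
channel is an 8-bit grayscale plane and all texture mathematics operates on
such planes, restricted to a region of interest (ROI). Four ROIs mirror the
anatomy: 1 withers, 2 thoracic spine (a narrow midline strip), 3/4
left/right back musculature. Masks are binary rasters; the bundled layout
uses axis-aligned rectangles. Only pixels inside the mask ever contribute:
runs and co-occurring pairs must lie wholly inside the mask, and mask gaps
terminate runs, so bounding-box fill values cannot leak into any statistic.

Conventional thermal features (Taver/Tmax/Tmin) are computed **only** from a
radiometric temperature matrix, never inferred from the rendered colors;
Taver is the plain arithmetic mean over member pixels (the vendor software's
weighting is undocumented; the plain mean is the defensible default).

### Histogram statistics (13)

From the normalized histogram $H(k)$, $k = 0..2^n-1$ over member pixels:
mean, variance, skewness $\mu_3/\sigma^3$ and excess kurtosis
$\mu_4/\sigma^4 - 3$ (both defined as 0 when the variance is 0);
percentiles $\mathrm{Perc}q = \min\{k : \sum_{t \le k} H(t) \ge q\}$ for
$q \in \{0.01, 0.1, 0.5, 0.9, 0.99\}$; Domn01, the smallest mode; Maxm01,
the modal mass $\max_k H(k)$; and the windowed pair Domn10/Maxm10, the
smallest start and the mass of the best $r$-bin moving window
$\sum_{t=k}^{k+r-1} H(t)$ with $r = 10$ bins. The printed formulas for the
dominant/maximum features are typographically corrupted in the source
material; the windowed moving-sum reading matches the "01"/"10" naming
convention and is recorded here as an interpretation. Ties take the
smallest index; the implementation sums windows directly rather than by
cumulative differences, because floating-point cancellation in the latter
breaks exact ties.

### Run-length features (7)

The gray-level run-length matrix $p(i, j)$ counts maximal runs of equal
level $i$ and length $j$ along scan lines of one direction (default 0°,
the only direction the source worked through; configurable, with averaging
over directions when several are given). With $n_p = \sum\sum p$:
GLN $= \sum_i (\sum_j p)^2 / n_p$, RLN $= \sum_j (\sum_i p)^2 / n_p$,
LRE $= \sum\sum j^2 p / n_p$, SRE $= \sum\sum p/j^2 / n_p$,
Fraction $= n_p / \sum\sum j\,p$ (runs per member pixel), and the moment
variants MRLN and MGLN — the same squared marginals normalized by $n_p^2$.
The $1/n_p^2$ prefactor is the natural "moment" reading of the printed
formulas, recorded as an interpretation.

### Co-occurrence features (11)

The co-occurrence matrix at distance $d = 1$ and a direction accumulates
ordered pixel pairs symmetrically — a pair with levels $(a, b)$ increments
both $p(a,b)$ and $p(b,a)$ — and is then normalized to sum 1.
Symmetrizing before or after normalization gives the same matrix. Features
use 0-based gray values, $0\log 0 \equiv 0$, and base-2 logarithms for all
three entropies (the log base is unstated in the source; bits are the
convention and the base is configurable). Correlat is the Pearson
correlation of the pair distribution,
$(\sum\sum ij\,p - \mu_i\mu_j)/(\sigma_i\sigma_j)$ with standard-deviation
denominators — the printed marginal moments are variances, but dividing by
variances leaves the checkerboard plane with a "correlation" of −4, outside
$[-1, 1]$, so the standard-deviation reading is used and Correlat $= 0$
when a marginal is degenerate. InvDefMom uses the standard
$1/(1 + (i-j)^2)$ kernel. Sum/difference marginals are over $k = i + j$ and
$k = |i - j|$. Features are computed per direction and averaged over
{0°, 45°, 90°, 135°} by default, since the direction choice of the original
analysis software is unreported; per-direction output is available.

Degenerate ROIs (constant gray level) are well-defined throughout:
variance, contrast and entropies are 0, AngScMom and InvDefMom are 1,
rather than errors.

### Depth and requantization

The default depth is $n = 8$ bits ($K = 256$ levels), the depth of the
rendered channels. `texture_config(bits = b)` requantizes 8-bit planes to
$2^b$ levels at the extraction layer by integer division — order-preserving
— which shrinks the co-occurrence support quadratically. Coarser depths are
used in the test suite to keep the brute-force oracles cheap; the
requantization is an explicit, documented transformation of the input, not
a change to any formula.

## The two-stage screen

Stage one compares pre vs post within each group, feature by feature. A
Shapiro–Wilk gate (α = 0.05) is applied to **both** paired series; the
paired t-test is used only when both pass, otherwise the Wilcoxon
matched-pairs signed-rank test (zero differences discarded; exact p for
small samples without ties, normal approximation with continuity correction
otherwise). The gate level is a package choice — the source states only the
comparison α — and gating on both series is the conservative reading.
Constant series fail the gate; a comparison whose differences are all zero
is reported non-significant (p = 1), and a constant *non-zero* difference
(possible for integer-valued features such as percentiles) is routed to the
sign-rank test, whose statistic remains defined.

A feature is **carried forward only when p < 0.05 in L, M and H
simultaneously**. No multiplicity correction is applied across the 372
features — the per-feature α = 0.05 procedure is the design being
implemented — but a Benjamini–Hochberg column is emitted for users; it
never drives selection. Under a global null the triple-significance rule
itself is a strong filter: the expected carried fraction per feature is
α³ ≈ 1.25×10⁻⁴.

Stage two compares the post-exercise series of L, M and H for carried
features: ANOVA + Tukey when all three series pass the gate, otherwise
Kruskal–Wallis + Dunn. Dunn's pairwise z-tests on mean ranks (with tie
correction) are implemented in the package because no installed package
provides them; p-values are unadjusted by default, matching the named
procedure, with any `p.adjust` method available. Pairwise outcomes map to
patterns: I (only L–H differs), II (L–H and M–H differ), III (all three
pairs differ), `none`, and any other configuration is reported verbatim as
`other`.

## What the synthetic generator emulates

The generator exists because the raw images are not publicly deposited. It
reproduces the *statistical* structure the analysis assumes, in temperature
space first:

* **Cohort**: horse bodyweights from the real cohort's moments
  (normal(566.7, 13.7) kg, truncated to 545–590 kg), heights
  normal(160.3, 3.9) cm, saddles uniform(4.1, 4.5) kg; rider bodyweights
  uniform over each group's observed range (L 58–60, M 75–77, H 91–92 kg).
  The truncation bounds are the algebraic condition under which every
  rider×horse ratio stays inside its design band, so group-by-construction
  always agrees with banding-by-ratio.
* **Fields**: a smooth anatomical component (Gaussian-filtered white noise,
  sd 1.5 °C, correlation length 12 px, seeded per horse so a session's pre
  and post images share anatomy) around a 30 °C baseline, plus per-pixel
  measurement noise (sd 0.25 °C, seeded per rider×horse×timepoint).
* **Exercise effect**: post-exercise fields gain a uniform +1.5 °C warming
  everywhere plus extra high-frequency noise of group-dependent sd —
  (L, M, H) = (0.5, 1.0, 1.5) °C — inside the muscle-rich ROIs 1, 3 and 4
  only. ROI 2 warms without gaining heterogeneity. The magnitudes are
  order-of-magnitude physiological choices (the real per-feature means live
  in unavailable supplements); they were fixed once when the generator was
  designed.
* **Rendering**: a 6-control-point iron-like palette over the camera range
  10–50 °C, piecewise-linear per channel, with a red channel that is
  non-decreasing in temperature and still unsaturated across the
  post-exercise range — the property that couples red-component texture to
  thermal heterogeneity. (A red ramp that saturates just above the warmed
  baseline would compress exactly the group differences the design
  injects.)
* **Seeding**: every random draw flows from the master seed through a
  stable 31-bit string hash of its role (`anatomy/<horse>`,
  `session/<rider>/<horse>/<timepoint>`), so any subset of the study
  regenerates identically.

What it does **not** emulate: horse-back geometry, biomechanical load
distribution, vendor palette nonlinearities, emissivity or ambient-air
radiometrics, or hand-drawn ROI variability. Passing tests therefore show
that the pipeline recovers known structure injected under its own
assumptions — not that the specific biological findings replicate on real
images.

## Problem sizes and numerical checks

The test suite verifies all 31 features against independent brute-force
oracles (dictionary counting, explicit scan-line walks, double-loop matrix
sums) on 110 seeded planes of 8×8–16×16 pixels — 100 at 6-bit depth to keep
the dense-loop oracles cheap, 10 at the full 8-bit default — to 10⁻⁹
relative tolerance. Null calibration uses 1000 replicates of 24-pair
groups; parameter recovery uses 50 replicate full-size studies (144 images
each) in which the post-exercise red-component Entropy and SumEntrp group
means in ROI 1 must be ordered L < M < H and the post-hoc pattern is
classified. The end-to-end disk pipeline runs on a reduced design (3
horses, 1 rider per group, 40×50 px, 5-bit depth) — the smallest study on
which the normality gate is defined.

## Known limitations

* Rectangular ROI masks only in the bundled layout; arbitrary rasters are
  accepted but no polygon rasterizer is included.
* BMP input is not supported (no installed decoder); PNG natively, JPEG and
  TIFF through EBImage when present. The synthetic study writes PNG.
* The GLRLM default direction (0°), GLCM direction averaging, entropy base,
  windowed-HS interpretation and Correlat denominators are documented
  interpretations of under-specified source formulas; all are configurable
  where that is meaningful.
* With n = 24 per group the Shapiro–Wilk gate has modest power, so the
  parametric branch is chosen liberally under near-Gaussian data; this
  mirrors the original procedure rather than optimal test selection.
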