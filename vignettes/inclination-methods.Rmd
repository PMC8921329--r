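---
title: "Computing nerve fibre inclinations from 3D-PLI measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing nerve fibre inclinations from 3D-PLI measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pliincline)
```

## The measurement and its signal model

3D polarised light imaging (3D-PLI) transmits linearly polarised light
through unstained histological brain sections and records, per pixel, the
intensity as the polariser rotates in equal steps over half a turn
(18 angles of 10° in the standard acquisition). Myelin is birefringent, so
the intensity follows a second-harmonic sinusoid

$$I(\rho) = \tfrac{T}{2}\,\bigl(1 + \sin\delta\,\sin 2(\rho - \varphi)\bigr),$$

whose mean carries the transmittance $T$ (tissue attenuation), whose phase
carries the in-plane fibre direction $\varphi$, and whose normalised
amplitude is the retardation $R = |\sin\delta|$. The phase of the optic
axis, $\delta \approx \tfrac{2\pi}{\lambda}\,\Delta n\, d_m \cos^2\alpha$,
couples the out-of-plane inclination $\alpha$ to the myelin thickness
$d_m$ and birefringence $\Delta n$: a steep fibre looks like a weakly
birefringent one. Recovering $\alpha$ therefore always requires a
reference assumption about the local amount of myelin; that assumption is
what distinguishes the three models below.

`extract_maps()` recovers $(T, \varphi, R)$ by discrete Fourier
coefficients of order 0 and 2 over the uniformly sampled angles. This is
exact for the signal model (the test suite checks a round trip at
$10^{-9}$ relative error) and is the standard estimator for
rotating-polariser polarimetry. Angles are handled in degrees at every
interface and radians internally. Pixels with zero mean intensity, or an
amplitude at numerical-noise level, return $T$ as given, $R = 0$ and
$\varphi = 0$ by convention (the phase is undefined there).

## Three inclination models

**Unweighted.** If $\Delta n\,d_m$ is taken as constant across the
section,
$$\alpha = \arccos\sqrt{\arcsin R / \arcsin R_\mathrm{ref}},$$
with $R_\mathrm{ref}$ the retardation of densely packed, parallel,
in-plane fibres. Where myelin is sparser than the reference this
*over-estimates* the inclination: part of the missing retardation is
attributed to steepness instead of thinner myelin.

**Transmittance-weighted.** Myelin scatters strongly, so myelin-rich
tissue is dark. Under two-compartment Lambert–Beer attenuation (myelin
$\mu_m$ over thickness $d_m$, other tissue $\mu_c$ over $d_M - d_m$, with
$d_M$ the maximal myelin thickness),
$$\frac{\ln(T_c/T)}{\ln(T_c/T_M)} = \frac{d_m}{d_M},$$
where $T_M$ and $T_c$ are the transmittances of fully myelinated and
myelin-free tissue. Scaling the retardation ratio by the inverse of this
fraction refers each pixel to its *locally available* myelin:
$$\alpha = \arccos\sqrt{\frac{\arcsin R}{\arcsin R_\mathrm{ref,HM}}\cdot
\frac{\ln(T_c/T_M)}{\ln(T_c/T)}}.$$
This is only meaningful where myelin dominates the attenuation; in grey
matter the transmittance mostly reflects cell bodies and the weighting
premise fails.

**Combined.** The section is segmented into highly myelinated (HM) and
lowly myelinated (LM) tissue, a probability $P_\mathrm{HM} \in [0,1]$ is
computed per pixel, and the two models are blended linearly:
$\alpha = P_\mathrm{HM}\,\alpha_\mathrm{HM} +
(1-P_\mathrm{HM})\,\alpha_\mathrm{LM}$, where the LM branch uses the
interpolated reference
$R_\mathrm{ref}^{*} = P_\mathrm{HM} R_\mathrm{ref,HM} +
(1-P_\mathrm{HM}) R_\mathrm{ref,LM}$, so the reference follows the tissue
composition smoothly through transition zones (fibres fanning from white
matter into cortex).

`run_scenario()` exposes the four evaluation modes: (i) unweighted with
the section-wide reference, (ii) weighted section-wide, (iii) both models
hard-split by the binary labels, (iv) the blended model.

## Classifying the degree of myelination

The classification works purely on histograms of the normalised
transmittance (affine to $[0,1]$, then a circular median filter of radius
5 px — large enough to suppress cellular structure, small enough to avoid
clouding) and the retardation:

* HM: $(R > R_\mathrm{thres}) \vee (T < T_\mathrm{thres})$ — the
  transmittance rule catches steep or crossing fibres whose retardation
  is low;
* LM: $(R \le R_\mathrm{thres}) \wedge
  (T_\mathrm{thres} \le T \le T_\mathrm{back})$;
* background: $(R \le R_\mathrm{thres}) \wedge (T > T_\mathrm{back})$.

Thresholds are points of maximum curvature of the histogram polyline
(counts rescaled to $[0,1]$ on a unit bin grid, plane-curve curvature
$y''/(1+y'^2)^{3/2}$ with central differences, ties towards the lower
bin). A coarse-to-fine chain makes this robust against the ragged peaks a
256-bin histogram shows: the threshold is first located on a 64-bin
histogram — within 20 × FWHM behind the biggest retardation peak, or
10 × FWHM before the biggest transmittance peak — then re-located on 128
and 256 bins inside the window $[2(r-1),\,2(r+1)]$ around the previous
result $r$. Background pixels are collapsed to the extreme bins before
the final pass so they cannot distort the tissue structure; because that
collapse needs provisional thresholds, the estimation runs in two passes.

$T_\mathrm{ref}$ is the mean transmittance of the connected region with
the highest retardation values, found by a binary search on a retardation
cut-off: threshold, label the components above the cut-off by union–find
(8-connectivity, so diagonal bundles stay one component), keep the
component with the highest mean retardation, and move the cut-off until
the component holds 0.009–0.011 % of the eligible pixels. On images so
small that no integer pixel count falls into that window, the smallest
component above it is used and a warning is raised.
$T_\mathrm{thres}$ is then the maximum-curvature point strictly between
$T_\mathrm{ref}$ and $T_\mathrm{back}$; the bin containing
$T_\mathrm{back}$ and one guard bin below it are excluded so that no
curvature stencil touches the base of the background peak.

## Transition zones by bootstrap

In a genuine transition zone a slight change of the thresholds flips the
classification. The sensitivity is measured by bootstrapping: each
iteration draws 25 % of the pixels with replacement (one joint index
stream for retardation and transmittance), rebuilds both histograms and
recomputes $R_\mathrm{thres}$ and $T_\mathrm{thres}$ through the full
64→128→256 refinement; $T_\mathrm{ref}$ and $T_\mathrm{back}$ stay at
their full-sample values. After 200 iterations the *positive/negative
means* — the mean of the recomputed thresholds above/below the original —
define the transition-zone widths
$w_\pm = |\text{side mean} - \text{original}|$. A side with no recomputed
values keeps the original value, i.e. a zero width. The defaults
(25 %, 200 iterations) sit where the running means have settled to within
one 256-bin width; `convergence_trace()` reproduces that convergence
study (running side means per iteration, averaged over 10 repeats, for
sample fractions 100 %, 25 %, 4 %, 1 %). One seeded generator drives all
iterations, with repeat $k$ on the documented sub-stream `seed + k - 1`,
so the full trace is reproducible, not just the totals.

## The HM-probability map

Deviations from the thresholds are scaled by the widths on the matching
side, retaining the sign of the numerator:
$\Delta R = (R - R_\mathrm{thres})/w_{R\pm}$ and likewise $\Delta T$. The
probability is a sigmoid in the deviation plane,

$$P_\mathrm{HM} = \tfrac12 - \tfrac12\,
\mathrm{erf}\!\Bigl(\cos\bigl(\tfrac{3\pi}{4} -
\mathrm{atan2}(\Delta T, \Delta R)\bigr)\sqrt{\Delta R^2 + \Delta T^2}\Bigr).$$

The direction term projects the deviation onto the HM/LM axis: deep high
retardation or low transmittance drives $P_\mathrm{HM}$ to 1, the
opposite corner to 0, equal conflicting evidence stays at 0.5. Two
conventions deserve emphasis, as the printed form of this expression is
ambiguous on both. First, the $+\tfrac12$ offset is required for
$P_\mathrm{HM}$ to span $(0,1)$ and honour the 0.05/0.95 region
cut-offs; without it the expression spans $(-\tfrac12,\tfrac12)$. Second,
magnitudes alone cannot tell the HM corner (high $R$, low $T$) from the
LM corner, so the signs are kept and the two-argument `atan2` is used.
The scale of the deviations is the bootstrap *width*, not the side-mean
value itself: only then does an empty bootstrap side give a zero-width
("the threshold is certain") limit, in which pixels take the hard 0/1
probability of the binary classification — which is also the pointwise
limit of the sigmoid map as all widths shrink. Background pixels always
carry $P_\mathrm{HM} = 0$, and the 0.05/0.95 band is stored as metadata
rather than baked into the map.

## Model parameters and the transmittance corrections

Before parameter estimation the transmittance is median-filtered per
region (HM and LM footprints kept separate, background excluded
everywhere) so borders stay sharp while cellular texture disappears.
Then, with LM meaning $P_\mathrm{HM} < 0.05$ and HM meaning
$P_\mathrm{HM} \ge 0.95$:

* $R_\mathrm{ref,LM}$: maximum-curvature point of the retardation
  histogram over LM pixels (the same estimator as $R_\mathrm{thres}$);
* $R_\mathrm{ref,HM}$: mean of the top 10 % retardation values inside the
  connected highest-retardation region of the HM pixels (0.009–0.011 % of
  the HM count);
* $T_M$: mean filtered transmittance over that same region;
* $T_c$: mode (most frequent 256-bin value) of the transmittance over LM
  pixels.

Steep fibres scatter more and appear darker than in-plane fibres of equal
myelin content, which the attenuation model would misread as impossibly
thick myelin; all transmittance below $T_M$ is therefore clipped up to
$T_M$. In the weighted formula the argument of the square root is clamped
to $[0,1]$ and clamped pixels are flagged in a quality mask, so
saturation at $\alpha = 0°$ remains auditable; pixels with $T \ge T_c$
(no detectable myelin attenuation — the weight diverges) saturate the
same way and are flagged. Applying the formula uniformly, including in
scenario (ii), reproduces the characteristic saturation of the
section-wide weighted model in myelin-poor regions.

## The phantom: what it emulates and what it does not

`generate_phantom()` evaluates the forward models — the polarimetric
sinusoid, the retardation phase and the two-compartment Lambert–Beer
attenuation — on a brain-like layout with full per-pixel ground truth:

* a dense in-plane fibre band (corpus-callosum-like) with a radial
  inclination field reaching 0° at a unique reference patch and myelin
  fractions 0.6–1, so the maximum-retardation region is connected and the
  dense tissue is not a transmittance delta;
* a steep-fibre band (70–85°) whose transmittance is additionally
  multiplied by 0.1, emulating the stronger scattering of out-of-plane
  fibres — this is what exercises the clipping step, and some pixels
  darker than $T_M$ must exist for the normalised $T_M$ to stay away
  from zero;
* a cortex with right-skewed myelin fractions (1.4–6 % of $d_M$, with a
  thin superficial layer of nearly constant low myelin) and inclinations
  that steepen with myelin content, keeping the birefringence product
  $d_m\cos^2\alpha$ in a narrow band, as a radially organised cortex
  would. This coupling is what gives the phantom the histogram shape the
  method assumes: one compact low retardation peak separated from the
  background bin, and a transmittance mode near the bright end with a
  sharp dark foot;
* fans in which bundles ramp linearly from cortex myelin to the band
  value at a moderate diving angle (45° at the tip, flattening into the
  band); fan pixels with myelin fraction in $[0.03, 0.97]$ are the
  ground-truth transition zones;
* putamen-like dense blobs in the cortex, a background margin, and a
  myelin-free rim of tapering section thickness (a cut edge) that
  populates the bright tissue range.

Default optics put the maximal phase at exactly $\pi/2$
($\Delta n\,d_M = \lambda/4$), so retardation is invertible; a `wrapped`
flag doubles the birefringence for stress tests of the folded regime.
Attenuation uses $(\mu_m - \mu_c)\,d_M = 4$, giving well-separated
transmittance modes. Smooth tissue fields come from rank-uniformised
random sinusoid sums, re-ranked within the cortex so the designed
mixture fractions hold for every seed.

The phantom deliberately does **not** model measurement noise on the
parameter maps (noise enters only through the optional rotation series),
inclination-dependent scattering beyond the single dark-steep factor,
crossing fibres, or optical effects such as diattenuation. Tests passing
on the phantom therefore certify the pipeline's numerics and its
behaviour under the stated attenuation model — not robustness to camera
noise or to fibre geometries the forward model cannot express. Two known
estimator biases are visible even here and are inherent to the method:
$T_c$ is estimated as the LM transmittance mode, which belongs to tissue
with a few percent myelin rather than none, so the weighted model loses
accuracy for pixels with very thin myelin (the residual transition-zone
error is concentrated at myelin fractions below about 10 %); and the LM
reference retardation ties to the upper edge of the LM distribution, so
absolute cortical inclinations are recovered only coarsely — the combined
model's merit there is *reducing* the over-estimation of the section-wide
unweighted model, which the acceptance checks verify as a strict
ordering.

## Numerical choices and degenerate inputs

* Histograms bin $[0,1]$ uniformly; a value of exactly 1 falls into the
  top bin. Thresholds are reported as 256-bin centres.
* FWHM is measured by linear interpolation of the half-maximum crossings
  on the count polyline, using the histogram edge when a side never drops
  below half; the search ranges floor the FWHM at one bin.
* The reference-region binary search runs at most 64 bisections of the
  retardation cut-off.
* The median filter truncates its disk footprint at image borders; no
  padding values are invented. Ties in the median average the two middle
  values, matching `stats::median()`.
* Degenerate inputs fail loudly: constant transmittance cannot be
  normalised, single-occupied-bin histograms carry no curvature
  structure, a section without LM (or HM) pixels has no reference tissue
  to estimate parameters from.
* Chunked execution (`chunked_apply()`) tiles only local-window
  operators, with a halo at least the footprint radius, and is exact;
  histogram stages always see the full pixel multiset — chunking is a
  memory tactic, never an algorithmic change.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
512 × 512 phantoms (the signal round trip on a 512 × 512 × 18 series),
the bootstrap convergence study on 256 × 256 with 500 iterations and 10
repeats, and property checks on batches of 64 × 64 images. On one CPU
core the complete pipeline takes a few seconds at 512 × 512; the
histogram machinery scales linearly in the pixel count.

## Interfaces

File exchange uses TIFF throughout: multi-page 32-bit float for rotation
series, single-page 32-bit float for parameter maps (direction stored as
degrees/180), 8-bit for label maps, JSON for parameter reports. The
`pli-incline` script under `inst/exec` drives the pipeline
(`run`), the phantom generator (`phantom`) and the bootstrap convergence
study (`trace`) from the shell.
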