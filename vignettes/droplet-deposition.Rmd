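---
title: "Droplet deposition detection: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet deposition detection: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropseg)
```

`dropseg` measures spray droplet deposition on a reusable achromatic-ink
carrier: droplets clear the opaque ink locally, a camera inside a
detection box sees bright stains on a dark background, and the package
turns such an image into a droplet count `N`, a coverage percentage `C`
and a coverage density `K` (droplets per cm²). This vignette explains the
models behind each stage, the parameters that matter, and the design
choices that were genuinely open.

## Carrier optics

Dry achromatic ink attenuates the ambient light `Io` entering the box
according to the Beer–Lambert law

$$ A = \log_{10}\frac{I_o}{I_t} = \tau L, \qquad
   I_t = I_o\,10^{-\tau L}, $$

where `L` (cm) is the ink thickness and `τ` collects the absorption
coefficient and the (constant, once dry) pigment concentration. Droplet
separation becomes insensitive to ambient light once the transmitted
intensity falls below a target `It` of 50 Lx, so the minimum usable ink
thickness at illumination `Io` is

$$ L \ge \frac{1}{\tau_m}\log_{10}\frac{I_o}{50}, $$

with the calibrated mean coefficient `τ_m = 257.11` cm⁻¹ shipped as the
default of `ink_model()` (overridable; `fit_tau_mean()` re-estimates it
from calibration readings as the mean of per-reading coefficients
`log10(Io/It)/L`). At the reference ambient illumination of
3.54 × 10³ Lx this gives 0.0072 cm:

```{r}
required_thickness(3540, ink_model())
```

Intensities at or below the 50 Lx target are rejected rather than clamped
— the inverse relation is undefined there, and silent clamping would mask
a faulty illuminance sensor. All logarithms are decadic. The 50 Lx target
is treated as a hard constant; no tolerance band is defined for it.

## Contrast adaptation with Sarsa

Ambient illumination drifts during a field campaign, and with it the
stain/background contrast. A tabular Sarsa agent learns, per illumination
bin, the contrast-adjustment parameter `c ∈ [0, 1]` that yields the best
segmentation. Design of the decision problem (the state/action encoding is
not dictated by the underlying method and was an open choice):

* **State** — (illumination bin, current contrast index). Illumination is
  discretized into 100 uniform bins over the configured operating range,
  by default [3500, 3600] Lx; `c` is quantized on a 0.01 grid.
* **Actions** — decrease `c` one step, hold, increase one step. An
  incremental scheme reproduces the characteristic learning trace: wild
  early fluctuation of the episode-final `c`, settling as exploration
  decays.
* **Reward** — `r = min(standard / realtime, 1)`, where `realtime` is the
  mean distance of mismatched pixels (candidate XOR reference) to the
  reference boundary (`mismatch_spacing()`) and `standard` is the best
  spacing found on a coarse calibration sweep. The ratio's orientation was
  ambiguous in its source; it is oriented so the optimum scores 1, which
  makes the learned values rise toward 1. The reference mask comes from a
  synthetic calibration scene's ground truth — a documented stand-in for a
  manually tuned reference segmentation.
* **Episodes** terminate when `r ≥ 0.99` (optimum found) or at a step cap
  (200). Because an episode ends the moment the optimum is entered,
  transitions *out of* the optimum are never observed; with the
  conventional zero-value terminal update the optimum would actually
  become repulsive (holding next to it accrues more discounted reward
  than entering it). The trainer therefore scores a terminal transition
  at its capitalized sustained reward `r/(1−γ)`, i.e. the value of an
  absorbing optimum. This is the one place the implementation deviates
  from the textbook episodic update, and it is what makes the learned
  greedy policy point *into* the optimum.
* **Learning parameters** — `α = 0.1`, `γ = 0.9` (convergence speed vs
  stability), ε-greedy exploration decaying exponentially from 0.9 to
  0.05 across the episodes (no schedule was prescribed; early exploration
  with late exploitation matches the intended learning trace).
* **Policy extraction** — greedy rollout from the bin's highest-valued
  state, stopping at the terminal contrast; ties in `argmax` break toward
  the lowest index, so training is bit-reproducible under a fixed seed.

The contrast transform itself (`apply_contrast()`) is an affine stretch
about the image mean, `out = clip(μ + (1 + 2c)(x − μ))`: `c = 0` is the
identity and the gain mapping is fixed and documented rather than
inherited from any particular display-adjustment convention.

## Adhesion-aware watershed segmentation

The pipeline (`mmcws()`):

1. **Preprocess** — BT.601 luma, 3×3 median smoothing, polarity
   normalization so droplets are dark. The source recipe asks for a
   "high-pass filter to denoise"; read literally a high-pass would
   *amplify* pixel noise, so the default is a median smoother
   (configurable, `median_radius = 0` disables).
2. **Binarize** — Otsu's 256-bin between-class-variance threshold.
3. **Adhesion test** — per 8-connected region, shape degree
   `E = 4πA/L²` and the per-image area threshold `d = mean(Aᵢ)`. A region
   is a single droplet only when `E > e` **and** `A < d` (`e = 0.67`, the
   midpoint of the calibrated group means 0.86/0.48; the generic 0.5 is
   available). The area clause catches fully engulfed overlaps that keep
   high circularity.
4. **Split** — each adhesive region is split by a marker-controlled
   watershed: markers are imposed as the only regional minima of the
   Sobel gradient magnitude (`impose_minima()`, any positive contrast
   step `δ` preserves the exact-minima property; default 10⁻³) and the
   relief is flooded by a deterministic priority-flood transform
   (`watershed_transform()`: queue keyed by surface value, FIFO on ties,
   ridge pixels assigned to the lowest adjacent label so the labels
   partition the region exactly).
5. **Clean up** — regions below `min_area` (4 px) are removed; labels are
   renumbered in raster order, so identical inputs give bit-identical
   label images.

**Marker choice.** The classical recipe derives foreground markers from
regional extrema of the intensity relief after an opening-by- plus
closing-by-reconstruction (`foreground_markers()`, implemented and
exposed). For an achromatic carrier this degenerates: a uniformly cleared
fused stain is one flat plateau, which yields a single marker and no
split. The default splitting markers are therefore the regional maxima of
the in-region Euclidean distance transform — the standard marker source
for near-circular touching objects; one maximum per circular lobe. No
h-maxima suppression is applied by default: the saddle between strongly
overlapped lobes can be under one pixel deep, and any positive depth
would swallow it (an optional `h_maxima` parameter remains). The
intensity-based markers stay available via `split_markers = "intensity"`.

**Reconstruction operators.** Grayscale reconstruction by dilation is
implemented as Vincent's two-sweep + FIFO hybrid algorithm (C++);
reconstruction by erosion is its exact negation dual. The hybrid
open-close reconstruction references its second stage on the opened
result: a reconstruction by erosion is bounded below by its reference, so
re-using the original image there would re-inject the bright structures
the first stage removed.

**Perimeter estimation.** The shape degree threshold semantics (`e =
0.67`) presume an estimator for which a circle scores near 1. Counting
pixel-edge steps biases digital circumferences ~8 % high (disks would
score E ≈ 0.91), so region boundaries are traced and measured with
Vossepoel–Smeulders-weighted chain codes (0.980 per axial step, 1.406 per
diagonal, −0.091 per corner), accurate to ~2 % for disks down to radius
5 px. Residual fluctuation can push `E` marginally above 1; values are
capped at 1 to respect the analytic range `0 < E ≤ 1`. The estimator is
tuned for smooth convex stains; grid-aligned rectangles are
underestimated, which is irrelevant to droplet imagery.

**Connectivity.** Foreground is 8-connected, background 4-connected (the
standard topological pairing); no connectivity was prescribed.

**Background markers.** `background_markers()` returns the watershed
ridge lines of the background distance transform — thin curves running
midway between stains — plus the image border frame, so a background
marker exists even for a single-droplet image.

**Structuring element.** A flat disk of radius 3 px by default (no size
was prescribed); it is scaled down automatically when the configured
cm/px implies stains narrower than ~6 px.

## Deposition metrics

`N` counts post-split, post-minimum-area regions. Coverage
`C = 100 · S(PIX=1)/S(PIX=0,1)` is computed on the Otsu foreground (the
stained fraction of the carrier is a property of the binary image, not of
the split). `K = N/S` with `S` the imaged area in cm², computed as pixel
count × scale². `evaluate_against_truth()` matches detected regions to
ground-truth droplets greedily, one-to-one, by centroid-in-disk; the
false-positive definition (unmatched detections over detections) is this
package's own, documented rather than inherited.

## Synthetic scenes: what they emulate and what they do not

`generate_scene()` renders anti-aliased disks (4× supersampling, so
shape-degree statistics are stable at small radii) whose contrast follows
the carrier optics: background = light transmitted through the full ink
layer at the scene illumination, spot = ambient light through a cleared
spot (transmission 0.85), both mapped to pixel values against a
4000 Lx full-scale camera. Spots carry a mild radial rim attenuation
(profile `1 − 0.35ρ²`): stains clear less completely at their rim.
Defaults describe one fixed study condition: a 576×576 px window at
0.002 cm/px (1.33 cm², so 200 droplets ≈ 150 n·cm⁻², the working range
of the deposition tests this tool targets), lognormal radii
(meanlog log 4.5, sdlog 0.22 → stains ~120–250 µm across), 15 % of
droplets in adhesive pairs placed at centre distance
`(r₁+r₂)·U(0.6, 0.95)`, additive Gaussian noise (sd 0.02), illumination
3550 Lx over 0.01 cm of ink. Ground truth records centres, radii,
adhesive pairs and the analytic union coverage (inclusion–exclusion over
the pair lenses; only paired disks overlap by construction).

What passing the recovery tests shows: the segmentation splits round,
pairwise-adhesive stains and counts them within 5 % under realistic
contrast and noise. What it does not show: robustness to slender-tailed
stains (shallow impact angles), chains of 3+ fused droplets, ink cracks
from over-thick coating, or non-uniform illumination across the carrier —
real-data failure modes the generator deliberately does not emulate, and
for which no quantitative bound is claimed. Elliptical/tailed spots are a
possible extension of the generator; they are not implemented.

## Numerical and testing choices

* Deterministic tie-breaks everywhere (argmax → lowest index; watershed
  queue FIFO; labels in raster order): every pipeline stage is
  bit-reproducible given a seed.
* The morphological kernels are verified against deliberately naive
  oracles: iterate-to-fixed-point geodesic reconstruction, an O(n²)
  ordered-flooding watershed, exhaustive regional-minima scans and
  brute-force mismatch distances, on randomized small rasters (200 cases
  ≤ 8×8 for reconstructions, 100 cases of 10×10 surfaces with 2–4 markers
  for the watershed, 100 cases of 16×16 reliefs for minima imposition).
* Full-pipeline recovery runs 10 seeded scenes at the default study
  condition; problem sizes were chosen so the whole suite completes in a
  few minutes on one core.
* Degenerate inputs: constant images binarize to an empty foreground with
  a warning; an all-foreground mask has no background markers (warning);
  an empty marker set is an error for minima imposition and watershed;
  packing failures in the generator raise an error after bounded retries
  rather than silently dropping droplets.

## Known limitations

* Heavily engulfed adhesive pairs (centre distance < ~0.65·(r₁+r₂), or a
  small droplet mostly inside a large one) present a single
  distance-transform maximum and are counted as one stain — the dominant
  source of the residual 2–5 % undercount.
* The shape-degree cap at 1 discards information about slightly
  super-circular estimates; only classification near `e = 0.67` matters.
* The Sarsa agent assumes the reward landscape over `c` is unimodal per
  illumination bin; multimodal landscapes would need a different
  exploration schedule.
* Label images use 16-bit TIFF (no 16-bit PNG writer is available to the
  package), capping a single image at 65 535 regions.
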