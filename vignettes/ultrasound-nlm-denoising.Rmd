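---
title: "Speckle reduction in B-mode ultrasound with non-local means: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle reduction in B-mode ultrasound with non-local means: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the noise and
denoising models it implements, the parameters that matter and their
defaults, what the synthetic data generator does and does not emulate, the
numerical conventions that make results bit-reproducible, and the design
choices that were genuinely open.

## The problem

B-mode ultrasound forms images from coherent echoes, so it carries speckle:
a granular, signal-dependent interference pattern. In fully developed
speckle the envelope amplitude follows a Rayleigh distribution, which makes
the local standard deviation *proportional to the local mean* — the
coefficient of variation of a homogeneous region is a constant,
$\sqrt{(4-\pi)/\pi} \approx 0.5227$, regardless of echogenicity. Speckle
obscures low-contrast structure (graded phantom targets, thyroid nodules)
and drives the two standard quality-control statistics:

$$\mathrm{CNR} = \frac{|S_T - S_B|}{\sqrt{\sigma_T^2 + \sigma_B^2}},
\qquad \mathrm{COV} = \frac{\sigma_T}{S_T},$$

with $S$ and $\sigma$ the mean and standard deviation over a region of
interest, and $T$/$B$ the target and background regions.

## The non-local means model

The denoiser replaces each pixel by a weighted average over its search
window $N_i$:

$$\hat I(i) = \sum_{j \in N_i} w_{ij} I(j), \qquad
w_{ij} = \frac{1}{Z_i}\exp\!\left(-\frac{d_{ij}}{h^2}\right),$$

where $d_{ij}$ is the dissimilarity of the patches around $i$ and $j$ and
$Z_i$ makes the weights sum to one. The key assumption is *self-similarity*:
a speckled image of piecewise-homogeneous tissue contains many patches that
are realizations of the same underlying structure, so averaging over
patch-similar pixels suppresses noise without averaging across edges —
patches from the far side of a boundary are dissimilar and receive
exponentially small weight.

Three conventions fix the model precisely:

- **Patch distance.** $d_{ij}$ is the plain (unweighted) mean squared
  difference over the $(2r+1)^2$ patch. Normalizing by patch pixel count
  makes $h$ mean the same thing at every patch radius; no Gaussian kernel
  is applied inside the patch.
- **Self weight.** The center pixel's raw weight is the maximum raw weight
  among its neighbors (`max_of_neighbors`, the default): with raw weight
  $\exp(0)=1$ the noisy center value would dominate exactly where no good
  matches exist. The literal `include` rule is selectable, and is also the
  right rule for studying the $h \to 0$ identity limit.
- **Bandwidth.** $h = c \cdot \delta / 255$, where $\delta$ is the noise
  standard deviation expressed on the 8-bit display scale and $c$ selects
  the smoothing level: 0.4 (low), 0.8 (middle), 1.2 (high). The presets use
  patch radius 3 (7×7) and search radius 10 (21×21), the classical choices:
  7×7 patches are large enough to characterize speckle texture and small
  enough to adapt to curved boundaries, and a 21×21 window offers ~440
  candidate matches per pixel.

### Choosing δ

δ is *the noise level of the image at hand*, not a universal constant. A
default of 20 (on 0–255) suits moderately noisy exported scans, but for
simulated speckle the honest choice is the measured one:
`255 * estimate_noise_sd(img)`. The estimator takes the diagonal Haar
detail of overlapping 2×2 blocks, $d = (x_{11}+x_{22}-x_{12}-x_{21})/2$,
whose variance equals the per-pixel noise variance for independent noise,
and summarizes it robustly with the MAD so that target edges do not inflate
the estimate. On the default phantom background (0.35) the speckle standard
deviation is $0.5227 \times 0.35 \approx 0.18$, i.e. δ ≈ 47 — the pipeline
therefore estimates δ per image rather than assuming 20.

### Implementation and its oracle

The production path is a straightforward C++ quadruple loop over pixels and
window offsets. `nlm_denoise_bruteforce()` is a deliberately plain pure-R
implementation of the identical contract; the test suite holds the two to
within $10^{-10}$ on batches of seeded random images (16×16 and 32×32), so
any future acceleration must reproduce the reference pixel-for-pixel.
Useful identities tested as limits: constant images are fixed points
(convex combination); $h \to \infty$ yields the search-window box mean;
$h \to 0$ under `include` yields the identity on images with unique
patches; flips commute with the filter.

## Comparison filters

- **Median** (`median_filter`): order-statistic filter over a
  $(2r+1)^2$ window; the window size is odd by construction so no
  tie-averaging arises. Default 3×3, the common default in image-processing
  toolboxes.
- **Adaptive Wiener** (`wiener_filter`): the local-adaptive (Lee-type)
  estimator
  $\hat I(i) = \mu_i + \frac{\max(\sigma_i^2-\nu,\,0)}{\max(\sigma_i^2,\,\nu)}(I(i)-\mu_i)$
  with window mean $\mu_i$, window variance $\sigma_i^2$ and noise variance
  $\nu$; when $\nu$ is not supplied it is the mean of the local variances,
  the classic adaptive rule. Flat regions collapse to the local mean;
  high-variance (edge) regions pass through. $\nu = 0$ reduces to the
  identity.

Both comparators run on the same $[0,1]$ scale and the same reflected
padding as NLM so CNR/COV comparisons are scale- and border-consistent.

## The synthetic data generator

The generator replaces acquired scans in every test:

- **Gray-scale phantom**: six circular targets on a 2×3 grid over a 0.35
  amplitude background, at amplitude contrasts +15, +6, +3, −3, −6, −15 dB
  (contrast is amplitude-referred: level $= 0.35 \cdot 10^{\mathrm{dB}/20}$).
  The set spans hyper- to hypo-echoic in the graded steps typical of the
  gray-scale region of a multipurpose QC phantom; the +15 dB disc exceeds
  1.0 and renders saturated, as a hyperechoic target does on a display.
  Each target gets a concentric ROI at half the target radius and a
  same-sized background ROI on the midline between the two rows, and
  reported CNR/COV are averages over the six pairs.
- **Thyroid-like scene**: an elliptical lobe (0.45) on a 0.22 background
  with an internal hypoechoic nodule (0.18) and an external near-anechoic
  vessel (0.03), with named ROIs; the seed jitters the geometry slightly.
  The lobe-vs-vessel pair drives the clinical-style CNR protocol.
- **Speckle**: each noise-free pixel $s$ is multiplied by an independent
  Rayleigh draw normalized to unit mean ($R/\mathbb{E}[R]$,
  $\mathbb{E}[R] = \sigma\sqrt{\pi/2}$), then clipped to $[0,1]$. Before
  clipping the output is conditionally unbiased with sd $0.5227\,s$; the
  Rayleigh scale cancels in the normalization, so the model has no strength
  dial — the sd/mean ratio *is* the fully-developed-speckle constant.
  Noise is applied in the linear intensity domain: it is the simplest model
  with the two defining properties (Rayleigh law, mean ∝ sd), and
  normalizing to unit mean makes the clean image the estimand, so any CNR
  loss is attributable purely to variance.

What the generator does **not** emulate: log compression and dynamic-range
mapping of real scan converters, spatial correlation of speckle (the
point-spread function makes real speckle grains several pixels wide; here
draws are i.i.d. per pixel), attenuation/TGC, probe geometry, and wave
propagation. Consequently, passing tests demonstrate the *algorithms'
contracts* and the expected qualitative behavior on piecewise-constant
scenes under signal-proportional noise — not performance figures for any
particular scanner's images.

### Clipping and the speckle closed forms

Clipping at 1.0 is not entirely negligible for the moment checks: at level
$s = 0.4$ the clip threshold in Rayleigh units is
$c = \sqrt{\pi/2}/0.4 = 3.133$ and $P(\mathrm{clip}) = e^{-c^2/2} = 0.0074$.
The clipped model still has closed-form moments —
$\mathbb{E}[\min(R,c)] = \mathbb{E}[R] - \sqrt{2\pi}\,(1-\Phi(c))$ and
$\mathbb{E}[\min(R,c)^2] = 2 - 2e^{-c^2/2}$ for $\sigma = 1$ — giving an
expected sample mean of 0.3993 and sd/mean of 0.5179 at $s=0.4$ (0.9% below
the unclipped 0.5227). The simulator tests assert against these exact
clipped-model values at three standard errors (delta-method SE with
Rayleigh moments), plus agreement with the nominal ratio to 1.5%; using the
unclipped value at a 3-SE tolerance would mistake a real property of the
clipped model for a sampling error.

## Numerical conventions

- **Intensity scale**: $[0,1]$ floating point internally; files quantize to
  $\mathrm{round}(p\,(2^b-1))$ with round-half-up, so a write/read round
  trip is within half a quantization step. δ-type parameters are quoted on
  the 0–255 scale because that is how exported ultrasound images are
  conventionally described. 16-bit export uses TIFF.
- **Borders**: reflected (symmetric, edge-repeated) padding for every
  window operation — zero padding would darken borders and bias edge ROIs.
- **ROI statistics**: population (divide-by-$n$) standard deviation, and
  center-in-region pixel membership for circles; both fixed so that results
  are bit-reproducible (with ≥ 9-pixel ROIs the $n$ vs $n-1$ choice is
  immaterial). Undefined metrics (zero denominator) raise typed errors
  rather than returning NaN, so an averaged report can never silently
  absorb an undefined pair. The coefficient-of-variation operation is
  exported as `roi_cov()` to leave `stats::cov()` unmasked.
- **Determinism**: every stochastic stage takes a seed; pipeline commands
  derive per-stage seeds from a master seed by name hashing
  (`stage_seed()`), so stages can be rerun in isolation and a manifest
  (which deliberately carries no timestamps) reproduces outputs
  byte-for-byte.
- **Problem sizes**: unit tests use 16–32 pixel images for brute-force
  cross-checks, 48–144 pixel scenes for pipeline behavior, and the
  replicate study uses ten seeds at the default 256×384 layout — sizes at
  which every distributional check has comfortable statistical power while
  the whole suite stays quick to run.

## Known limitations and observed behavior

- On these linear-domain speckle phantoms the noise variance grows with the
  square of the signal. A global-ν adaptive Wiener therefore passes noise
  through in bright targets (where local variance exceeds ν) and the
  saturated +15 dB disc strongly favors the median, whose order statistic
  is nearly noise-free under the one-sided clipped distribution. In the
  ten-replicate study the mean ranking that emerges is
  NLM ≫ median ≈ Wiener > noisy for CNR (median slightly ahead of Wiener)
  and NLM < Wiener ≲ median < noisy for COV — NLM is the best method on
  both metrics by a wide margin, but the median/Wiener order between the
  classical comparators is condition-dependent and, for CNR, opposite to
  what is typically reported on log-compressed display images, where
  speckle is approximately level-independent. This is a property of the
  simulation conditions, not of the filter implementations.
- NLM cost is $O(\text{pixels} \times \text{window} \times \text{patch})$;
  the C++ path handles the default presets comfortably at QC-image sizes
  but is not meant for volumetric or real-time use.
- `estimate_noise_sd()` assumes spatially independent noise; on real
  (correlated) speckle it underestimates the level, and δ should then be
  set from a manufacturer phantom protocol or visual tuning of the
  low/middle/high presets.
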