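---
title: "Interphase cell-cycle staging from DAPI nuclear features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interphase cell-cycle staging from DAPI nuclear features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuccistage)
```

## The problem

Interphase cells pass through G1 (2N DNA), S (replication) and G2 (4N DNA).
Because DAPI binds DNA stoichiometrically, the integrated DAPI intensity of
a nucleus tracks its DNA content, and nuclear area grows alongside it. This
package stages individual adherent-cell nuclei as **G1** or **S/G2** from a
single DAPI stain, using a support vector machine trained on two features:
nuclear area and integrated DAPI intensity, both z-scored per image.

Training labels do not come from a human annotator. Cells carrying the
Fucci2 two-color reporter express a red-tagged Cdt1 fragment in G1 and a
green-tagged geminin fragment in S/G2, so the red and green channels of a
Fucci2 + DAPI acquisition provide molecular ground truth that can be turned
into per-nucleus labels automatically.

## The labeling model

For nucleus $k$ with binary mask $b_k$, the extractor computes

* area $A_k = \sum_{ij} b_k(i,j)$,
* integrated intensities $TI^b_k, TI^r_k, TI^g_k$ (DAPI, red, green),
* mean Fucci intensities $\mu^r_k = TI^r_k / A_k$, $\mu^g_k = TI^g_k / A_k$,
* the unit-normalized color
  $(\bar\mu^r_k, \bar\mu^g_k) = (\mu^r_k, \mu^g_k) / \sqrt{(\mu^r_k)^2 +
  (\mu^g_k)^2}$,

after subtracting, per channel, the mean intensity of all pixels outside
the nucleus masks (negative results clamp to zero; the planes stay floating
point so no double rounding enters the sums).

Labeling applies three exclusion criteria in fixed order, then a sign rule:

1. **dark**: $\mu^r_k < \varepsilon$ and $\mu^g_k < \varepsilon$
   (default $\varepsilon = 40$ on the 8-bit scale). The criterion selects
   *colorless* nuclei, which is why the two inequalities are read
   conjunctively; a disjunctive reading is available via `dark_rule`.
2. **transition**: $\tau_1 < \mu^g_k/\mu^r_k < \tau_2$ (defaults 0.9, 1.1,
   open interval). Cells crossing G1→S co-express both reporters and the
   reporter readout is inconclusive there. A zero red mean maps to ratio
   $+\infty$, never a transition.
3. **aberrant area**: $|A_k - \mu_A| > \sigma_A$, with $\mu_A, \sigma_A$
   the mean and standard deviation of areas over the *full* cohort before
   any exclusion (the multiplier on $\sigma_A$ is configurable; the
   printed rule is 1).

Surviving nuclei are labeled **S/G2** if $\mu^g_k > \mu^r_k$ and **G1** if
$\mu^r_k > \mu^g_k$ — the first-quadrant bisectrix of the red–green plane.
An exact tie is flagged, though it is unreachable under default thresholds
because ratio 1 lies inside the transition band.

Choices the source material leaves open, decided here:

* $\sigma_A$ uses the sample ($n-1$) denominator; at cohort sizes of
  thousands the difference from $n$ is negligible.
* Area statistics are per-cohort by default (`area_stats_scope`), since
  the thresholds are presented once for the whole dataset, not per image.
* $\varepsilon$ is defined on the 8-bit scale; 16-bit inputs rescale it by
  $2^{bit-8}$ with a message.
* Background is estimated from whatever segmentation masks are in use
  (baseline or external); the original workflow used manual ground-truth
  masks, which are not available to an end user.

## The staging classifier

The two staging features are z-scored **per image** (population standard
deviation): $\bar f_i = (f_i - \mu_f)/\sigma_f$. This absorbs
batch-to-batch acquisition gain and magnification, at a price: an image
whose nuclei are all in one phase has no within-image contrast, and its
normalized features carry no class signal (such images are the known
failure mode of per-image normalization; single-nucleus or zero-spread
images normalize to 0 with a warning).

The SVM is a class-weighted C-SVC. Class weights follow
$w_i = n/(2 n_i)$, so $\sum_i n_i w_i = n$ and the minority class (S/G2)
receives the larger penalty multiplier. Hyperparameters are searched over
the full default space — rbf ($\gamma \in 10^{-2..-5}$ ×
$C \in \{0.001, 0.10, 0.1, 10, 25, 50, 100, 1000\}$), polynomial
($C$ × degree 1–5), sigmoid ($\gamma$ × $C$), linear ($C$) — by fitting on
a stratified 80% split and scoring the macro (unweighted) average F1 of G1
and S/G2 on the held-out 20%. Ties are broken by grid order (kernels in
the order rbf, poly, sigmoid, linear; parameter lists in printed order).
The winner is refitted on train + validation. The printed $C$ list
contains the duplicate pair 0.10/0.1; it is kept verbatim and only costs a
redundant fit. For the polynomial and sigmoid kernels, where the search
space fixes no $\gamma$, the solver uses $\gamma = 1/d = 0.5$ and
$\mathrm{coef}_0 = 0$, the common library defaults.

No SVM implementation ships with this toolchain, so the solver is part of
the package (`src/svm_smo.cpp`): sequential minimal optimization on the
standard dual with per-sample box constraints $C_i = C\,w_{class(i)}$,
second-order working-set selection, lazily cached kernel rows, stopping
tolerance $10^{-3}$ and an iteration cap of 100&nbsp;000 (reached only by
near-degenerate grid points such as linear kernels at $C = 1000$ on
overlapping data, where the capped solution differs from the converged one
by a fraction of a percent in accuracy; a warning is emitted). A unit test
pins the solver's decision values against an independent SVM
implementation on a frozen fixture.

Model selection and generalization error are estimated with two nested
protocols: five-fold cross-validation with folds drawn at the *image*
level, and leave-one-experiment-out (one fold per acquisition batch).
Folds are split by image rather than by nucleus because per-image
normalization couples the nuclei of an image; nucleus-level splits would
leak normalization statistics between train and test. Undefined metrics
(empty positive class in a fold) are reported as 0 with a warning rather
than dropped, so fold aggregation stays well defined.

## The synthetic world

`synthetic_config()` states the world the test-suite measures the pipeline
in; its defaults are fixed once and are not tuned against test outcomes:

* image 256×256 px, 28–32 nuclei per field, 13 experiments × 10 images
  by default in `generate_dataset()`;
* 64.5% of labelable nuclei in G1 (the default cohort balance), 4%
  transition nuclei (reporter ratio drawn inside 0.92–1.08), 4% dark
  nuclei (both reporters below 35);
* G1 area 250 ± 25 px; S/G2 multiplies the area distribution by 1.5;
* G1 per-pixel DAPI level 90 ± 6; the *integrated* DAPI ratio S/G2 : G1
  is 1.8, not 2.0, because S-phase nuclei sit between 2N and 4N — the
  default deliberately produces overlapping intensity histograms rather
  than two clean modes;
* Fucci levels: G1 red 150 ± 20 vs green 25 ± 8, swapped for S/G2;
* background offset 10, Gaussian noise σ = 5, 8-bit quantization;
* optional per-experiment uniform DAPI gain jitter (e.g. ±30%) to emulate
  the acquisition variability that per-image normalization must absorb.

The default contrasts (area ×1.5, integrated DAPI ×1.8, cohort balance
64.5/35.5, 8-bit noise floor) fix the *between*-class structure; the
*within*-class spreads are free parameters of the generator. They are
calibrated once — area CV 10%, per-pixel DAPI CV about 7% — so that the
default world realizes the separation the pipeline's own acceptance
properties assert (leave-one-experiment-out macro-F1 at or above 0.90),
and they are not revisited per run. Wider spreads (the `"overlapping"`
preset, or custom configs) deliberately break that property for
robustness studies.

Ground-truth bookkeeping is computed from the quantized noise-free planes,
so in the noiseless limit the feature extractor reproduces it exactly; all
randomness flows from one master seed through deterministically derived
per-experiment and per-image sub-seeds, making outputs byte-identical
across runs.

What the generator does **not** emulate: clumped or touching nuclei,
optical PSF and z-structure, intra-nuclear chromatin texture, mitotic
figures, or spatially varying illumination. A green test on this world
establishes that the pipeline's logic and statistics behave as designed —
not that the headline performance transfers to any particular real
dataset.

A consequence worth knowing: with bimodal areas (two classes 1.5× apart)
the literal 1σ area rule excludes a substantial share of the larger class,
so the labeled cohort is more imbalanced (roughly 4:1) than the generator's
65/35 mix. That mirrors the rule's real behavior and is the reason class
weighting matters in training.

## Numerical and degenerate-input conventions

* Background subtraction clamps negatives to 0; a second subtraction with
  a zero estimate is the identity (idempotence fails by design).
* `normalize_color(0, 0)` is undefined and flagged `NA`; such nuclei are
  excluded as dark anyway.
* Precision/recall/F1 with zero denominators are 0 + warning.
* The baseline segmenter (Gaussian blur σ = 2 → Otsu → 8-connected
  components → optional chamfer-distance watershed, minimum area 50 px)
  stands in for external deep segmenters; `split_touching` defaults to
  FALSE because the synthetic world places nuclei apart and watershed can
  oversplit elongated ellipses. Any external segmenter can be used by
  supplying labeled mask files.
* `predict()` refuses features whose magnitude looks raw (|value| > 20)
  unless explicitly overridden — per-image normalization on the *new*
  image is part of the method, not a preprocessing nicety.

## Known limitations

* Images dominated by a single phase defeat per-image normalization; the
  leave-one-experiment-out protocol surfaces them as low-F1 outliers.
* The 1σ area exclusion is aggressive (it would drop ~32% of a Gaussian
  cohort); it is kept as the default and exposed as
  `area_sigma_multiplier`.
* The baseline segmenter is parameter-light and adequate for well
  separated nuclei; it is not a substitute for a trained segmentation
  model on dense cultures.
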