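---
title: "Egg phenotyping and the detection of conspecific brood parasitism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg phenotyping and the detection of conspecific brood parasitism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conspecific brood parasitism (CBP) — a female laying an egg in the nest of
another female of her own species — is hard to detect in the field because
conspecific eggs resemble each other closely. Molecular parentage is reliable
but expensive; egg appearance is cheap but has historically been judged by
eye. This package implements a quantitative pipeline: it measures egg
phenotypes from calibrated UV–visible photographs, condenses them into a
small set of traits, quantifies how strongly those traits signal female
identity, and then uses them to flag parasitized clutches and to pick out
the parasitic egg within a clutch.

The pipeline rests on one biological premise: eggs laid by the same female
vary less among themselves than eggs laid by different females. Everything
downstream — the maximum-Euclidean-distance (MED) clutch statistic, the
weighted-distance ranking, and the supervised same/different classifier —
is a way of exploiting that within/between-clutch variance gap.

## Image analysis

`extract_features()` runs the full chain on a `egg_image` (five reflectance
rasters R, G, B, UV and luminance in [0, 1], a boolean egg mask, a pixel
scale and the blunt-pole orientation):

1. **Illumination correction** divides each channel by its heavily
   Gaussian-blurred version and rescales to preserve the within-mask mean.
   Division rather than subtraction preserves reflectance ratios. The
   default sigma (2048 px) corresponds to full-frame photographs at the
   30 px/mm working scale; on small single-egg crops the kernel is truncated
   to the image extent and the correction degrades gracefully toward a
   global rescale.
2. **Mask shrinking** erodes the egg mask by 3% of the egg width so darker
   egg edges do not masquerade as spots.
3. **Spot segmentation** uses the Phansalkar local threshold
   `T = m (1 + p e^{-q m} + k (s/R - 1))` with the original constants
   (p = 2, q = 10, k = 0.25, R = 0.5) over a 50 px disc neighbourhood, a
   method designed for low-contrast objects on normalised images. Connected
   spot components are labelled with 8-connectivity.
4. **Colour statistics** are channel means over spot and background pixels
   separately. A spotless egg copies the background means into the spot
   slots (with a warning) so the trait PCA never sees missing values.
5. **The luminance histogram** bins whole-egg luminance into ten levels
   (0–1 in 0.1 steps, last bin closed).
6. **The granularity spectrum** band-passes the luminance channel with a
   difference-of-Gaussians filter bank at 12 geometric scales,
   `(1/sqrt(2))^i` of the egg length (1 down to ~0.0221). The sigma of each
   band is chosen so the band's peak wavelength equals its scale fraction
   of the egg length (for a DoG with sigma ratio sqrt(2) the peak sits at
   ~5.34 sigma). Pattern energy is the s.d. of the filtered pixels, and
   pattern skewness their third standardised moment (0 when the s.d. is 0),
   which distinguishes dark-on-light from light-on-dark maculation. Both
   are reported for the whole egg and for the blunt, middle and sharp
   thirds — 12 x 4 energies and skewnesses. Pixels outside the egg are
   mean-filled before filtering so the egg outline itself contributes no
   pattern energy.
7. **Spot metrics**: mean spot area (mm²), percent coverage, and the mean,
   population s.d. (n = 3) and coefficient of variation of the per-zone
   coverages.
8. **Shape metrics**: length, maximum width, volume and lateral surface of
   the solid of revolution around the principal axis, the mean absolute
   radial deviation of the outline from the moment-equivalent ellipse
   (normalised by length), and the aspect ratio. The half-width profile is
   integrated on >= 200 stations after smoothing the *squared* profile with
   a spline — for an ellipse r² is exactly quadratic in the axial
   coordinate, so the spline is well behaved at the egg tips and volume and
   surface agree with closed forms to well under 1% at the working scale.

The blunt-pole side must normally be supplied in metadata;
`detect_blunt_end()` offers a wider-half heuristic but is only a flagged
convenience.

## From features to traits

`fit_trait_model()` standardises each feature column and fits five separate
PCAs: colour (10 variables), luminance (10 bins), pattern (the granularity
energies and skewnesses), pattern2 (the five spot metrics) and shape (6
variables). The retained component counts are fixed at (3, 1, 2, 2, 1) —
nine phenotypic traits in total. Fixed counts replace subjective scree-plot
inspection so that results are exactly reproducible; the counts are a
configurable argument. Because the composition of the pattern block admits
two readings (all scales x regions, or whole-egg spectra only), both are
available via `pattern_scope`; the default feeds all 96 pattern variables
into the pattern PCA. PCA signs are unrecoverable conventions, so each
component is oriented to make its largest-|loading| variable positive.

`rank_traits()` fits a 500-tree random forest classifying female identity
from the nine traits and returns each trait's permutation importance (mean
decrease in accuracy); negative importances are clamped to zero before use
as multiplicative weights. `weight_traits()` multiplies scaled traits by
these weights. The weights feed only the Euclidean-distance methods —
monotone per-feature scaling cannot change tree splits, so the supervised
classifier uses unweighted scaled traits. `reference_weights()` carries the
importance values estimated on the original barn-swallow population for use
when no labelled data are available.

## Identity signal

`clutch_variance_stats()` computes, on z-scored traits, the per-female mean
trait s.d. (within metric) and the across-female s.d. of clutch-mean
vectors (between metric), with a one-sample t-test of the 54 within values
against the between value. Sample (n − 1) standard deviations are used
throughout. `beecher_hs()` estimates Beecher's information statistic:
traits are decorrelated by a full PCA, each component is subjected to a
one-way ANOVA on female identity, and components significant at p < 0.05
contribute `0.5 * log2(F)` bits. F is capped at 1e6 so degenerate inputs
(zero within-clutch variance) stay finite. A label-shuffled control (seeded)
calibrates the no-signal baseline. `laying_order_deviation()` reports each
laying position's mean within-clutch distance — in many species, including
barn swallows, the first- and last-laid eggs deviate most, which is exactly
what makes purely phenotypic clutch screening unreliable.

## Detecting parasitism

* `med_statistic()` — all pairwise distances among a clutch's
  importance-weighted traits; each egg's mean distance; the maximum of
  those means is the MED. Clutches above the threshold (default 350) are
  flagged as parasitized. The threshold is meaningful only on the
  reference-weight scale; other provenances trigger a warning.
* `unsupervised_identify()` — game 1 (six eggs, no laying information):
  the egg with the highest mean distance to the rest is called parasitic;
  game 2 (four known host eggs + two same-day candidates): the candidate
  with the larger mean distance to the four known hosts is called. The
  candidate–candidate pair is excluded from the game-2 means: the pair
  contributes the same quantity to both candidates and would only dilute
  the host-referenced contrast. Exact ties are ambiguous, never broken.
* `supervised_identify()` / `evaluate_layouts()` — a random forest is
  trained on a balanced set of 265 'same' (within-female) and 265
  'different' (between-female) egg pairs, encoded as the absolute per-trait
  differences of the scaled traits. Absolute differences make the
  classifier symmetric under egg swap, which the two-directions-per-pair
  vote convention presupposes. Every within-clutch pair is classified;
  each 'different' verdict credits both eggs of the pair once per
  direction, so a game-1 egg accrues 2 x 5 = 10 comparisons per repeat. The
  procedure is repeated (default 10 times) with fresh training draws; the
  egg with most 'different' votes is called, and vote ties are reported as
  ambiguous and excluded from accuracy denominators. Under
  leave-one-clutch-out the training pool excludes every egg of the tested
  female; under leave-one-egg-out (game 2 only) the four regular-sequence
  host eggs join the pool and their six mutual pairs are forced into the
  'same' class. In leave-one-egg-out mode the known host eggs also remain
  available to the ordinary sampling pool, so they may additionally appear
  in 'different' pairs with other females' eggs.

All randomness flows from master seeds through `derive_seeds()`, so every
result is bit-reproducible.

## The synthetic generators

`synth_clutches()` draws female mean vectors from N(0, σ²_between I₉) and
eggs from N(mean, σ²_within I₉), with optional additive shifts on the
first-/last-laid egg. The defaults (54 females x 5 eggs,
σ_between = 0.82, σ_within = 0.58) reproduce the study population's scaled
variance metrics. Identity covariance is the default because real traits
are PCA scores and hence near-uncorrelated; this is also the generator's
main idealisation — real trait distributions are neither perfectly Gaussian
nor perfectly isotropic, and real clutches share environmental covariates
the generator omits. Passing tests on synthetic data therefore demonstrate
the correctness and calibration of the *procedures*, not field-level
accuracy on real eggs.

`render_egg_image()` draws a prolate egg with per-channel background and
spot reflectances, anti-aliased disc spots from a seeded point process with
per-zone density weights, and an optional multiplicative illumination ramp,
returning the exact spot mask as ground truth. It deliberately does not
attempt photorealism (no shell gloss, no 3-D shading); it exists to
exercise the imaging operators against known render parameters. The
trait-level and image-level generators are deliberately decoupled: the
statistical machinery is tested in trait space, the imaging machinery in
pixel space.

## Numerical choices and problem sizes

* Gaussian blurs use separable truncated kernels (half-width min(3σ, image
  extent)) with replicate padding, so a flat field is preserved exactly and
  sigma values far larger than the frame remain well defined.
* Band-pass energies use population s.d.; skewness of a (near-)constant
  band is defined as 0; thresholds, erosion radii and station counts are
  documented in the function signatures.
* Zero-spot eggs propagate background colour values rather than NAs.
* Vote ties are never broken — ambiguity is an explicit, reportable
  outcome.
* Test and validation runs in this package use reduced problem sizes chosen
  to keep the full suite fast while leaving every conclusion
  statistically identifiable: chance-level convergence uses 1,000
  zero-signal trials with 3 training repeats and 100 trees; the
  task-ordering comparison uses 500 shared trials and 200 trees, with the
  game-1 arm at 5 training repeats and the game-2 arms at the full 10
  repeats (the leave-one-egg-out margin effect is small and needs the
  lower-noise tallies); rendered-image oracles use 15 px/mm eggs. The
  study-scale settings (10 repeats, 500 trees, 30 px/mm) remain the
  package defaults.
* Paired comparisons of the two game-2 validation schemes are made on
  per-trial vote margins (Wilcoxon signed-rank) rather than on correctness
  indicators: at ~95% accuracy the correctness of the two schemes is
  concordant on nearly every trial, so a sign test on calls discards
  almost all of the paired information that the tallies contain.
* Accuracy estimates over simulated parasitism trials are clustered by host
  clutch; where the tests compare an accuracy against a nominal chance
  level they use a cluster-robust standard error rather than a binomial
  one.

## Known limitations

* The MED threshold (350) is an empirical calibration for the reference
  weight scale; with re-fitted weights it must be re-derived from a
  genotyped non-parasitized sample.
* Beecher's Hs is computed from the nine traits, not the raw features; Hs
  values are comparable across studies only under similar
  dimensionalities.
* `detect_blunt_end()`'s wider-half heuristic fails on nearly symmetric
  eggs; supply orientation in metadata whenever known.
* The supervised approach requires a genotyped (or otherwise
  identity-verified) training population; it identifies the most aberrant
  egg, and in game-1-style use the first/last-laid deviation can masquerade
  as parasitism.
* On the synthetic generator, leave-one-egg-out performs on par with
  leave-one-clutch-out rather than clearly better as on real eggs: the
  generator gives every female the same within-clutch covariance, so the
  clutch-specific pair structure that the known host eggs contribute on
  real data is absent by construction — all females are statistically
  exchangeable, and the forced host 'same' pairs add nothing the generic
  same-pairs do not already convey. A benefit from leave-one-egg-out
  should only be expected where females differ in how variable their own
  eggs are.
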