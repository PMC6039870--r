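---
title: "Scoring double-readout two-hybrid screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring double-readout two-hybrid screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luthy)
```

## The assay and its two readouts

A LuTHy experiment measures one candidate protein pair twice in a single
procedure. In intact cells, a NanoLuc (NL) luciferase fusion of protein X
and a ProteinA-mCitrine (PA-mCit) fusion of protein Y report direct
association through bioluminescence resonance energy transfer: when donor
and acceptor sit within ~10 nm, part of the luminescence is re-emitted at
the acceptor's longer wavelength. After lysis, the same wells are assayed
by luminescence-based co-precipitation (LuC): the PA tag captures the bait
on IgG-coated plates and the co-captured prey is quantified by its
luciferase activity. BRET favours direct, geometry-dependent proximity and
is comparatively insensitive to affinity; LuC favours complexes stable
enough to survive lysis and washing, i.e. high-affinity binding. The two
readouts are therefore complementary, and a pair positive in both is the
strongest evidence class.

## Scoring model

For each well, with `SWL` and `LWL` the luminescence in the short
(370–480 nm) and long (520–570 nm) windows:

* raw BRET ratio: `BRET = LWL/SWL − Cf`, where the bleed-through factor
  `Cf` is the mean `LWL/SWL` of wells expressing the donor-only PA-NL
  reference;
* precipitation reference: `PIR = NL_OUT / (v · NL_IN)` averaged over
  PA-NL wells, with volume factor `v = 3` by default (15 µl captured
  versus 5 µl of input lysate measured);
* raw LuC ratio: `LuC = (NL_OUT / (v · NL_IN)) / PIR`;
* corrected ratios: `cBRET = BRET − max(BRET_ctrl1, BRET_ctrl2)` and
  analogously `cLuC`, where control 1 is free NL with the pair's acceptor
  and control 2 the pair's donor with free PA-mCit.

Two identities pin these definitions and are enforced to machine precision
in the test suite: a PA-NL well scored against its own `Cf` has BRET ratio
0, and against its own `PIR` has LuC ratio exactly 1. Both ratios are
invariant to a common rescaling of a well's channels (gain independence),
and the control correction is translation-equivariant. Corrected ratios
may be negative and are never clipped; signs are handled at the calling
stage.

Three aggregation choices were genuinely open and are fixed as follows:

* **Correction scope.** `Cf` and `PIR` are computed per plate when that
  plate carries PA-NL wells, otherwise pooled per experiment
  (`cfScope = "plate"`, the default). Reference wells are measured
  alongside each experiment, but pooling behaviour is not dictated by the
  assay itself, so both scopes are available and the one used is recorded
  in the score table.
* **Mean of ratios.** `Cf` and `PIR` average per-well ratios rather than
  ratios of summed channels, so wells with different expression levels
  contribute equally and a single bright well cannot dominate.
* **Replicate aggregation.** Correction happens within a replicate
  experiment first; corrected values are then averaged across replicates.
  Raw channels are never averaged across independent transfections.

`mCit_OUT` is read and carried as a QC column but enters no score.

## Calling and calibration

Calls are made on aggregate corrected ratios with inclusive cutoffs:
`cBRET ≥ 0.01` and `cLuC ≥ 0.03` by default, tightened to `≥ 0.03` /
`≥ 0.05` when *both* proteins of a pair are membrane-associated — pairs
co-targeted to membrane surfaces can show proximity signal without
specific binding, so they are held to a higher bar. These published
cutoffs are shipped as configuration defaults rather than recomputed:
reproducibility of calls takes precedence over reverse-engineering the
optimality criterion behind them. For calibration on a labeled reference
panel, `rocAnalysis()` reports the full empirical ROC over all distinct
thresholds (score ≥ threshold, matching the inclusive convention), the
trapezoidal AUC with its Hanley–McNeil standard error, and the
Youden-optimal threshold as a suggestion only. The AUC equals the
concordant-pair (Mann–Whitney) statistic, which the tests verify against
brute-force enumeration. Fisher's exact test (minimum-likelihood
two-sided definition) serves the affinity sub-group recovery comparisons,
and replicate agreement is summarized by Pearson or Spearman correlation
with the asymptotic t-approximation p-value.

No multiple-testing machinery is applied to screen calls: calling is by
fixed cutoffs, not p-values.

## Titration fits

**Donor saturation.** Titrating the acceptor at fixed donor traces a
saturating BRET curve. The response is fit to a one-site rectangular
hyperbola `BRET(r) = BRETmax · r / (BRET50 + r)` in the acceptor/donor
ratio `r`; the functional form is the standard donor-saturation model and
matches the half-maximal semantics of BRET50. `r` is estimated from the
fluorescence/luminescence ratio normalized to the PA-mCit-NL tandem
fusion, whose 1:1 stoichiometry anchors the scale. Under the two-species
equilibrium the ratio at half-maximal occupancy is `(KD + D/2) / D`, so
BRET50 grows monotonically with KD — it is a *relative* affinity scale,
and only rank agreement with biochemical KDs is claimed (or tested). The
fit accepts raw BRET or corrected cBRET as the response; the assay
literature does not standardize this and the hyperbola is indifferent to
a constant offset absorbed in `BRETmax`.

Numerics: Levenberg–Marquardt least squares (`minpack.lm`) with relative
parameter tolerance 1e-10, initialized at `BRETmax = max(response)` and
`BRET50 =` the ratio nearest half-max, with quartile-ratio restarts on
failure. Flat series, series with fewer than 4 distinct ratios or less
than a 4-fold ratio span, and solutions pinned to the search bounds are
reported `converged = FALSE` with a diagnostic, never as a silent number.

**Dose response.** Compound effects are fit with a four-parameter
logistic on log10 dose, Hill slope constrained positive so `bottom`/`top`
are the low-/high-dose asymptotes; the direction (stimulation → EC50,
inhibition → IC50) is read from their order. Zero/vehicle doses are
mapped to a floor two decades below the lowest non-zero dose — a
log-axis convention, not a physical claim. Time-course and heat-shock
experiments are normalized pointwise against their untreated (or
non-heat-treated) control series, with exact time matching and no
interpolation, since the design normalizes like-to-like wells. Tagging
orientation matrices (the eight donor/acceptor terminal combinations of
one pair) are normalized to their maximum entry, preserving the sign of
negative entries.

## Differential profiles

Variant-versus-wild-type comparison classifies each partner per readout:
`lost`/`gained` on call flips, `decreased`/`increased` when the call is
retained positive in both profiles *and* the change is significant *and*
its magnitude clears an effect floor (defaults 0.01 for cBRET, 0.03 for
cLuC, mirroring the calling cutoffs), `unchanged` otherwise; partners in
only one profile are reported `incomparable`. The operational definition
of a "disturbed" interaction is not standardized, so floor, alpha and
readout weighting are configurable rather than fixed.

Significance is the delicate part: profiles typically carry two replicate
experiments per partner, and a within-partner permutation test on 2 vs 2
values has only six rearrangements (minimum two-sided p of 1/3).
The classifier therefore pools the replicate noise variance across the
whole partner panel (multiplicative noise makes this a reasonable
homogeneity assumption on ratio scales), forms a t-like statistic per
partner, and adjusts family-wise by the resampled distribution of the
maximum statistic (seeded max-T draws). With zero noise this reduces to
exact ground-truth classification, and swapping the two profiles swaps
the classes antisymmetrically.

For group-level many-to-one comparisons with adequate group sizes (e.g.
whole-profile distributions of several variants against wild type),
`resamplingManyToOne()` is a label-permutation max-T test against the
shared control — a resampling analog of one-way ANOVA with a many-to-one
post hoc comparison, chosen over the parametric multivariate-t machinery
because it is assumption-light and exact under exchangeability. Its
family-wise error is simulation-checked in the tests.

## The simulator: what it emulates, and what it does not

`simulateScreen()` generates the full plate structure: interaction wells,
the two shared single-tag controls per pair, and PA-NL plus tandem
reference wells on every 384-well plate. The generative chain is

* expressions: lognormal per construct and replicate (median donor
  1e-7 M, acceptor 1e-6 M — a ~10-fold acceptor excess matching the
  1:10–1:20 transfection ratio — CV 0.25; independent redraws per
  replicate model independent transfections);
* binding: exact two-species equilibrium occupancy from the pair's KD
  (positives drawn log-uniformly over 1 nM–10 µM; non-interacting pairs
  have occupancy 0);
* channels: `SWL ∝ D`, `LWL = SWL · (Cf_true + BRETmax · occ)`,
  fluorescence ∝ A, `NL_OUT = v · NL_IN · PIR_true · (background +
  capture · occ)` with `Cf_true = 0.2`, `PIR_true = 0.15`, capture 0.6,
  background 0.01, per-pair BRETmax uniform on 0.1–0.6;
* noise: multiplicative lognormal per channel (default CV 5%), since
  luminescence noise scales with signal.

Concentrations are abstract molar-scale scalars: every downstream score
is a ratio, so only relative magnitudes matter. The noise and expression
distributions are invented (no instrument-level noise model is published
for this assay) and are labeled as such; the capture model couples
co-precipitation linearly to occupancy, deliberately omitting saturation
of the capture surface. Crowding artefacts of co-membrane pairs — the
assay's stated false-positive risk — are not generated by default, so a
passing simulation benchmark demonstrates correctness of the *pipeline*,
not robustness of the *assay* to membrane artefacts. Real screens add
plate-position effects, construct-specific expression failures and
partial capture losses that the simulator does not model; recovery rates
on simulated panels are therefore upper bounds for real data.

The standing regression benchmark (fixed seed 42) uses 160 pairs, half
interacting, two replicates, 5% CV noise; calling at the default cutoffs
must reach sensitivity ≥ 0.9 on positives with KD ≤ 1 µM and specificity
≥ 0.95, with between-replicate Pearson r > 0.9. At the 0.01 cBRET cutoff
and a bleed-through of 0.2, a 5% ratio CV puts the negative-pair score
distribution's upper tail near the cutoff, so specificity sits by design
only a little above its bound — the cutoff is doing real work in the
simulation, exactly as intended. Problem sizes throughout the test suite
(desk-scale screens of tens to 160 pairs, 200 saturation series, 25
dose-response draws, 64×64 images) are chosen so the whole suite runs in
well under a minute while keeping every Monte Carlo assertion stable.

## Imaging

The dual-view bioluminescence image pair is handled in four fixed steps:
integer-pixel translation registration by exhaustive normalized
cross-correlation search (the dual-view offset is a rigid translation;
ties break toward the smaller shift, and an optimum on the search-window
boundary is flagged low-confidence), edge-replicated median filtering,
per-channel percentile background subtraction (default 5th percentile;
`b = 0` disables subtraction, since the 0th percentile is the image
minimum and would null a uniform field), and intensity thresholding on
the short channel before the pixel-wise long/short division. The
threshold has no published value and is a required user parameter; the
mask construction makes division by zero impossible for any positive
threshold. Subpixel registration, segmentation and pseudo-colour
rendering are out of scope.

## Worked micro-example

```{r example}
sim <- simulateScreen(simulationParams(nPairs = 6, noiseCv = 0.05, seed = 1))
scores <- scoreScreen(sim$screen)
calls <- callInteractions(scores)
labels <- with(unique(sim$truth[, c("pair_id", "label")]),
               stats::setNames(label, pair_id))
summarizeScreen(calls, labels)
```

## Known limitations

* Corrected scores inherit the noise of both control wells; with very few
  replicates the aggregate cBRET of a weak pair can sit on either side of
  the cutoff across reruns. The ROC tools exist precisely to choose
  cutoffs deliberately on reference data.
* BRET50 is only interpretable within an experiment series; absolute KD
  estimation is intentionally not offered.
* The panel-pooled variance in `compareVariantProfiles()` assumes
  comparable noise across partners on the ratio scale; strongly
  heteroscedastic panels would need per-partner replication well beyond
  the usual two experiments.
* The imaging module assumes the two spectral views differ by a pure
  translation; optical distortion or rotation is not corrected.
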