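---
title: "Methods: simulation and analysis of mitochondrial-toxicity screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of mitochondrial-toxicity screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## Overview

`mitoscreen` models a two-assay respirometry screening campaign for
electron-transport-chain (ETC) toxicants and analyses it end to end. This
vignette documents the generative model, the analysis conventions, the
numerical choices, and the limits of both.

## The flux model

All expected values live on the percent-of-basal-OCR scale. A compound's
occupancy of its target is a Hill sigmoid,

$$a(c) = \frac{(c/\mathrm{IC}_{50})^h}{1 + (c/\mathrm{IC}_{50})^h},$$

computed in ratio form to avoid overflow at extreme concentrations
(`hill_fraction()`). The same sigmoid family the generator uses for
occupancy is what the analysis side fits as a four-parameter Hill curve, so
potency recovery is well posed.

**Intact cells** (`simulate_mitostress_plate()`). A cell line is described
by a `cell_line_profile`: uncoupled capacity `maximal_ocr_pct`,
non-mitochondrial floor `nonmito_pct`, proton-leak share `leak_pct`, and
glycolytic parameters. With ETC capacity $g = 1 - a$ for CI/CIII and
downstream inhibitors ($g = 1$ for intact-cell-masked CII inhibitors and
inactive compounds) and uncoupling drive $u = a$ for protonophores, the
expected OCR per injection phase is:

| phase        | expected OCR (% basal)                                    |
|--------------|-----------------------------------------------------------|
| baseline     | $100$                                                     |
| compound     | inhibitors: $n + (100-n)\,g$; uncouplers: $\min(m,\; 100 + (m-100)\,u)$ |
| oligomycin   | $n + \ell\,g + (m-100)\,u$                                |
| FCCP         | $n + (m-n)\,g$                                            |
| rotenone/AA  | $n$                                                       |

with $n$ = `nonmito_pct`, $\ell$ = `leak_pct`, $m$ = `maximal_ocr_pct`. In
the noise-free limit, vehicle wells satisfy the decomposition identity
*basal = ATP-linked + leak + non-mitochondrial* exactly, and the FCCP phase
reproduces the configured maximal capacity — both are acceptance-tested.

ECAR follows a compensation model: the expected ECAR, as a fraction of the
glycolytic range (0 = basal acidification, 1 = oligomycin plateau), equals
the fraction of ATP-linked respiration lost, clipped at 1; oligomycin
forces 1; FCCP adds a configurable boost only for lines that increase
glycolysis further under uncoupling. Absolute ECAR is
`basal_ecar * (1 + glycolytic_reserve * fraction)`.

**Permeabilized cells** (`simulate_complex_assay_plate()`). Electron flow
is a product of per-complex capacities: stage 1 (CI substrates)
$\propto g_\mathrm{CI} g_\mathrm{CIII} g_\mathrm{CIV}$, stage 2
(succinate + rotenone) $\propto g_\mathrm{CII} g_\mathrm{CIII}
g_\mathrm{CIV}$, stage 3 (ascorbate/TMPD + antimycin A)
$\propto g_\mathrm{CIV}$, with $g_X = 1 - a$ only for the targeted
complex. Protonophores are inert in this ADP-stimulated preparation.

**Noise.** Each measurement is multiplied by a unit-mean lognormal factor
with coefficient of variation `cv`, and each well carries one lognormal
scale factor (`well_scale_sd`) emulating seeding differences. `cv = 0,
well_scale_sd = 0` gives exact expected values. All randomness flows from
the `noise_model` seed through an isolated RNG scope (`with_seed`), so
simulations are reproducible and do not disturb the caller's RNG stream.

## Built-in cell models and panel

Two profiles bracket screening phenotypes: a glycolytic hepatoma-like line
(maximal OCR 159.4% of basal, full glucose rescue of viability, no
FCCP-phase ECAR boost) and an oxidative renal proximal-tubule-like line
(337.4%, little glycolytic rescue, FCCP ECAR boost). The packaged panel
(`load_panel()`) holds 21 agrochemical ETC inhibitors — 8 CI, 5 CII, 8
CIII — with annotation plus two simulator-only columns (`sim_mechanism`,
`sim_potency_log10M`) that the analysis never reads.

Dose ladders: intact assays use 8 points of 1-in-5 dilution from 10 µM
(lowest 1.28e-10 M); the permeabilized assay uses 12 half-log points from
500 µM down to 1.58 nM. The wider top end reaches the weak CII class
(active only far above 10 µM); the low end resolves nanomolar CI/CIII
inhibitors instead of saturating them at every tested dose.

## Analysis conventions

**Normalization.** Kinetic traces are normalized to the mean of their own
pre-injection baseline (`normalize_to_baseline()`). ECAR is additionally
expressed on the plate's glycolytic range, anchored at the well's basal
acidification and the vehicle wells' oligomycin maximum
(`normalize_ecar_range()`). A second-pass re-anchoring to a compound's
non-effective low-concentration prefix is available
(`renormalize_to_noneffective()`); it is idempotent and falls back with a
flag when fewer than `k_min` concentrations qualify.

**Mitostress decomposition** (`decompose_mitostress()`). Compound-phase
basal uses the mean of the last two of five cycles (equilibrated
inhibition); oligomycin uses the phase minimum; FCCP the maximum;
non-mitochondrial the rotenone/antimycin mean. Uncoupling is flagged when
compound-phase OCR rises to ≥ 115% of baseline **and** oligomycin-phase
OCR stays at ≥ 100% (`detect_uncoupling()`): elevated respiration no
longer coupled to ATP synthesis.

**Complex classification** (`classify_complex()`). Stage summaries take
the *second* OCR measurement after each injection, as percent of the
pre-compound baseline. Against matched vehicle references, a stage counts
as inhibited below 0.7 of its reference and rescued at or above 0.7; the
five-case table (no inhibition / CI / CII / CIII / downstream, plus a
partial-rescue CIII band and an `ambiguous` catch-all) depends only on
stage *ratios* and is therefore invariant to common rescaling — a tested
property. Per-compound calls use a consensus rule across inhibiting
concentrations (modal call, ties to the higher dose), which is robust to a
single borderline dose where noise flips one stage across the threshold;
a lowest-inhibiting-dose rule is available as an option.

**Potency estimation** (`fit_hill4()`, `ic50_from_fit()`,
`ec50_pointwise()`). Inhibition endpoints get a bounded four-parameter
Hill fit in $x = \log_{10}$(concentration):
$Y = b + (t-b)/(1 + 10^{(x - L)s})$ for decreasing curves (the mirror
exponent for increasing ones), parameterized as (bottom, range ≥ 0, $L$,
slope) with slope ∈ [0.1, 10] and bottom ∈ [−10, 110]; Levenberg-Marquardt
(`minpack.lm::nlsLM`) with an `optim` L-BFGS-B fallback. Zero-concentration
vehicle points are excluded from the fit abscissa (log undefined) —
vehicle information enters through normalization. The IC50 is the solved
50%-absolute crossing; if the fitted curve does not cross 50% inside the
ladder the result censors to `"> log10(top)"` — or, when the caller
supplies the lowest tested dose and the curve is already suppressed past
50% there, to `"< log10(lowest)"`. Activation endpoints (ECAR, lactate,
PI) use a model-free point-to-point EC50: linear interpolation on a
1000-point uniform log-grid, first crossing of 50% from the low end
(tie-break for non-monotone curves; invariant to adding collinear interior
points); never reaching 50% renders `"NR"`. In summary matrices, untested
cells render `"NT"`.

Stage-attributed permeabilized potencies additionally apply a no-response
rule: a realized effect below 20% at the top dose reports `"NR"`. The
realized effect is measured against the 100% control anchor, not against
the fitted `top` parameter — on exactly flat curves the fitted `top` is
unidentified (the optimizer can park the midpoint below the ladder with an
arbitrary `top` at unchanged residual), whereas the control anchor is
data-identified.

**Statistics** (`dunnett_loec()`). Concentration groups are compared to
vehicle by Dunnett's many-to-one procedure (pooled variance,
multivariate-t critical values via `multcomp`); the LOEC is the lowest
significant concentration. A one-way ANOVA p-value is always reported but
is, by default, *not* used as a gate: Dunnett's procedure controls the
familywise error rate at $\alpha$ by construction, and conditioning on a
significant omnibus F makes the two-step procedure conservative — measured
null familywise error 0.024–0.030 at $\alpha = 0.05$ across 4–8 group
designs with 3–6 replicates, versus 0.047–0.053 ungated. `anova_gate =
TRUE` restores the gated legacy protocol.

**Integration** (`run_pipeline()`). The campaign simulates a mitostress
plate and a 24-h endpoint panel per cell model plus one permeabilized
plate, fits all potencies, assembles the compound-by-endpoint summary
matrix (pure, byte-stable rendering; conflicting duplicates are an error),
computes cross-assay OLS associations on per-(compound, concentration)
means, and calls a mechanism per compound by fixed precedence:
uncoupling flag → `uncoupler` (contradictory complex evidence is retained
in the evidence record); permeabilized CII pattern →
`etc_inhibitor_CII_masked`; CI/CIII/CIII-partial → corresponding
`etc_inhibitor_*`; stage-3 inhibition → `downstream_inhibitor`; otherwise
`inactive`.

## Design decisions and rationale

* **Hill sign convention.** Slopes are kept positive with `top ≥ bottom`;
  decreasing curves use a mirrored exponent. This avoids the classical
  ambiguity of negative-slope parameterizations while keeping the bounds
  meaningful.
* **Uncoupler potency routing.** A compound whose basal OCR rises above
  115% at the top doses is routed from a (meaningless) inhibition fit to
  an activation EC50 on the normalized OCR rise.
* **CII masking is a model primitive.** `cii_masking = 1` makes CII
  inhibitors exactly vehicle-like in intact cells; lowering it exposes
  partial inhibition for sensitivity analyses.
* **Consensus dose rule for complex calls.** At a dose where one stage
  ratio sits at the threshold, a single noisy measurement can flip a CIII
  pattern to CII; the modal call across inhibiting doses is stable while
  preserving the lowest-inhibiting-dose concentration in the output.
* **Ungated Dunnett by default** — see Statistics above; the calibration
  study is part of the acceptance suite.

## What the generator does and does not emulate

Emulated: dose-graded basal/maximal inhibition, intact-cell CII masking,
protonophore signatures (basal rise, oligomycin resistance, preserved FCCP
response), compensatory ECAR/lactate, substrate-stage rescue patterns,
glucose/galactose viability shifts, 3D-culture attenuation of glycolytic
rescue, repeated-exposure sensitization, and realistic multiplicative
plate noise.

Not emulated: proton-motive-force dynamics (no mechanistic coupling
between leak, potential and flux), injection transients and mixing
artifacts, oxygen-diffusion limits of the measurement chamber, edge
effects and spatial plate gradients, compound degradation or partitioning
into plastic, and cell-density normalization error. The endpoint coupling
(viability, membrane potential, PI) is a deliberately simple
deficit-switch model, not a kinetic cell-death model.

## Limitations

* The uncoupling flag requires oligomycin-phase OCR at or above baseline,
  which is only reachable in models with high spare respiratory capacity:
  at maximal capacity 159.4% the fully-uncoupled oligomycin phase sits
  near 74% of baseline and the flag cannot fire. The pipeline therefore
  pools the flag across cell models; campaigns using only low-spare
  models would need a lowered `oligo_resistance` threshold, at the cost
  of specificity.
* The five-case complex table cannot separate CIV from CV inhibition
  (`CIV_CV_downstream`), mirroring the assay's real ambiguity.
* Potencies censored at either ladder edge are bounds, not estimates;
  half-maximal conventions (50% absolute crossing) are not benchmark-dose
  estimates with uncertainty bands.
* The Dunnett contract assumes pooled variance; strong
  heteroscedasticity across doses is tolerated but not modelled.
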