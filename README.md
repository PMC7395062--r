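# mitoscreen

Simulation and analysis of plate-based mitochondrial-toxicity screening:
kinetic oxygen-consumption (OCR) and extracellular-acidification (ECAR)
traces, sequential-injection respiration decomposition, permeabilized-cell
electron-transport-chain (ETC) complex localization, censored dose-response
potency estimation, and integrated mechanism-of-action calls for compound
panels.

## The scientific problem

Many agrochemicals and drugs act as ETC inhibitors or protonophore
uncouplers. Plate-based respirometry screens them with two complementary
kinetic assays:

* **Intact-cell mitostress assay** — cells receive the test compound, then
  oligomycin (ATP-synthase inhibitor), then FCCP (uncoupler), then
  rotenone/antimycin A (complete ETC block). The trace decomposes basal
  respiration into ATP-linked, proton-leak and non-mitochondrial components
  and reveals maximal (uncoupled) capacity. Compensatory glycolysis appears
  as an ECAR rise.
* **Permeabilized-cell complex assay** — permeabilized cells respire on
  complex-I (CI) substrates, receive the compound, then succinate+rotenone
  (feeds CII, blocks CI), then ascorbate/TMPD+antimycin A (feeds CIV,
  blocks CIII). The stage at which OCR recovers localizes the inhibited
  complex. This assay is essential because **CII inhibition is invisible in
  intact cells**: CI-fed electron flow bypasses succinate dehydrogenase, so
  CII inhibitors are "masked" until the substrate is switched.

The package pairs every analysis stage with a first-class synthetic trace
generator so that the full campaign — 21-compound panel, two cell models,
dose ladders, 24-h cytotoxicity endpoints — can be simulated with known
ground truth, analysed blind, and scored.

## Core model

The simulator is phenomenological, on the percent-of-basal scale. A
compound's target occupancy follows a Hill sigmoid
`a = c / (IC50 + c)`. Inhibitors scale the ETC capacity factor `1 − a`
(per-complex in the permeabilized assay: stage-1 flux ∝ g(CI)·g(CIII)·g(CIV),
stage-2 ∝ g(CII)·g(CIII)·g(CIV), stage-3 ∝ g(CIV)); uncouplers raise basal
OCR toward the FCCP maximum and resist oligomycin suppression; ECAR rises
with the fraction of ATP-linked respiration lost, saturating at the
oligomycin plateau. Measurement noise is multiplicative lognormal per
measurement plus a lognormal per-well scale factor; everything is
deterministic given a seed.

The analysis side never sees ground truth: it normalizes traces to their
own baselines, decomposes mitostress parameters, classifies complex
specificity from stage ratios against vehicle references, fits bounded
four-parameter Hill curves in log10-concentration space with explicit
censoring (`"-6.62"`, `"> -5.00"`, `"< -8.80"`, `"NR"`, `"NT"`), and
synthesizes per-compound mechanism calls by a fixed precedence rule
(uncoupler > complex-specific inhibitor > downstream inhibitor > inactive).

## Worked example

Simulate three mechanistically distinct compounds on a high-spare-capacity
cell model and decompose the traces:

```r
library(mitoscreen)

panel <- load_panel()
pick  <- panel[panel$name %in% c("Rotenone", "Thifluzamide", "Cyazofamid"), ]

traces <- simulate_mitostress_plate(
  pick, dilution_preset("intact_default"), rptec_profile(),
  noise = noise_model(cv = 0.03, well_scale_sd = 0.05, seed = 7)
)
params <- decompose_plate(traces)
dplyr::filter(params, conc_M == 1e-5) |>
  dplyr::select(compound, compound_basal_pct, maximal_pct, oligo_pct, uncoupling)
#>   compound     compound_basal_pct maximal_pct oligo_pct uncoupling
#> 1 Thifluzamide              103.        340.       21.9 FALSE
#> 2 Cyazofamid                329.        345.      242.  TRUE
#> 3 Rotenone                   10.3        12.0      10.1 FALSE
```

At 10 µM the CI inhibitor rotenone has collapsed respiration, the CII
inhibitor thifluzamide is indistinguishable from vehicle (masking), and the
protonophore cyazofamid has driven basal OCR to the uncoupled maximum with
oligomycin unable to suppress it. Potency fitting reflects the same
pattern:

```r
mitostress_potencies(potency_curves_from_plate(traces))
#>   compound     endpoint    kind  value censored         display
#> 1 Cyazofamid   ecar        EC50  -5.57 none             -5.57
#> 2 Cyazofamid   ocr_basal   EC50  -5.94 none             -5.94
#> 3 Cyazofamid   ocr_maximal IC50  -5    above_top_tested > -5.00
#> 4 Rotenone     ecar        EC50  -7.17 none             -7.17
#> 5 Rotenone     ocr_basal   IC50  -7.38 none             -7.38
#> 6 Rotenone     ocr_maximal IC50  -7.48 none             -7.48
#> 7 Thifluzamide ecar        EC50  NA    no_response      NR
#> 8 Thifluzamide ocr_basal   IC50  -5    above_top_tested > -5.00
#> 9 Thifluzamide ocr_maximal IC50  -5    above_top_tested > -5.00
```

The permeabilized complex assay unmasks thifluzamide and localizes each
lesion:

```r
cx <- simulate_complex_assay_plate(
  pick2 <- panel[panel$name %in% c("Rotenone", "Thifluzamide", "Antimycin A"), ],
  dilution_preset("permeabilized_extended"),
  noise = noise_model(0.03, 0.05, seed = 11)
)
calls <- complex_calls_from_plate(cx)
complex_call_per_compound(calls)
#>   compound     call  call_conc_M
#> 1 Antimycin A  CIII  1.58e-8
#> 2 Rotenone     CI    1.58e-8
#> 3 Thifluzamide CII   1.58e-5

complex_potency(calls)
#>   compound     stage    log10_potency censored    display
#> 1 Rotenone     CI               -7.52 none        -7.52
#> 2 Rotenone     CII/CIII         NA    no_response NR
#> 3 Rotenone     CIV              NA    no_response NR
#> 4 Thifluzamide CI               NA    no_response NR
#> 5 Thifluzamide CII/CIII         -4.74 none        -4.74
#> 6 Thifluzamide CIV              NA    no_response NR
#> 7 Antimycin A  CI               -7.74 none        -7.74
#> 8 Antimycin A  CII/CIII         -7.74 none        -7.74
#> 9 Antimycin A  CIV              NA    no_response NR
```

The full campaign — both cell models, endpoint panels, the summary matrix
and mechanism calls — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$moa[res$moa$compound %in% c("Rotenone", "Thifluzamide", "Cyazofamid"),
        c("compound", "call")]
#>   compound     call
#> 1 Rotenone     etc_inhibitor_CI
#> 2 Thifluzamide etc_inhibitor_CII_masked
#> 3 Cyazofamid   uncoupler
```

A command-line front end covering simulation, per-assay analysis, potency
fitting and the full pipeline is installed at
`system.file("cli", "mitoscreen.R", package = "mitoscreen")`; see
`?mitoscreen_cli`.

## License

MIT — see `LICENSE`.
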