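# arcplan

Fully automated, desk-scale VMAT (volumetric modulated arc therapy)
planning for pelvic radiotherapy, in R.

Radiotherapy for locally advanced rectal cancer must cover a large,
concave target — the mesorectum and pelvic nodes wrap posteriorly around
the bladder and small bowel — while sparing those organs and the femoral
heads. VMAT does this well, but manual plan optimization is slow and
planner-dependent. `arcplan` implements a scripted planning pipeline
that takes a density volume and contoured structures and produces a
finished, evaluated single-arc plan with no human interaction: it checks
ROI names, inserts a virtual couch, derives helper structures (organs
minus target, an anterior "bowel-bag" control shell), places the
isocentre, builds goal-driven objectives with dose fall-off, optimizes
in stages (two fluence passes, hotspot extraction and three correction
passes, coverage escalation, a final direct-aperture optimization),
sequences the MLC leaves, and grades the result against a clinical goal
table. It ships a seeded synthetic pelvic phantom in place of patient
CT data, so everything runs self-contained.

The evaluation toolbox stands alone as well: exact cumulative DVHs with
Dx/Vx readout, conformity index `CI = TV_PIV² / (TV · PIV)`, homogeneity
index `HI = (D2 − D98) / D_Rx`, plan sums, 3%/2 mm global gamma analysis,
the VMAT modulation complexity score (MCS), and an exact two-sided
Wilcoxon signed-rank test for paired plan comparisons.

Dose is computed with a transparent linear pencil-beam model
(exponential attenuation at radiological depth, inverse-square,
Gaussian penumbra) rather than a clinical engine — fast, deterministic,
and sufficient for every workflow algorithm; see the methods vignette
(`vignettes/automated-vmat-planning.Rmd`) for the model, parameters and
design rationale.

## Worked example

```r
library(arcplan)

ph  <- generate_phantom(phantom_spec())   # seeded synthetic pelvis
res <- run_autoplan(ph$density, ph$structs)

s   <- ph$structs
dvh <- cumulative_dvh(res$dose_initial, s[["PTV_initial"]])
round(c(D93_pct = 100 * dose_at_volume(dvh, 93) / 45,
        D2_pct  = 100 * dose_at_volume(dvh, 2) / 45,
        CI      = conformity_index(res$dose_initial, s[["PTV_initial"]], 45),
        HI      = homogeneity_index(dvh, 45)), 3)
#> D93_pct  D2_pct      CI      HI
#>  98.172 108.800   0.607   0.129

blad <- cumulative_dvh(res$dose_sum, s[["Bladder"]])
round(volume_at_dose(blad, 45)$pct, 1)    # bladder V45 on the plan sum, %
#> [1] 12.8

subset(as.data.frame(res$goal_report),
       select = c(roi, metric, parameter, threshold, units, achieved, status))
```

`res$goal_report` lists every clinical goal (target D93 > 98% and
D2 < 110% of prescription for both plans; small-bowel V35/V40/V45 in cc;
bladder and femoral-head V40/V45/V50) with the achieved value and a
pass / fail / flagged status — "flagged" marks organ limits exceeded
only inside the organ's overlap with the target, which is clinically
tolerated. `res$log` is the timed stage log of the whole workflow, and
`plot_dvh(res$dose_sum, ph$structs)` draws the composite DVH.

A thin command-line front end covers the same pipeline
(`inst/scripts/arcplan`): subcommands `phantom`, `autoplan`, `evaluate`,
`qa`, `compare`.

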