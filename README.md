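# grindqsar

Alignment-free 3D-QSAR and pharmacophore screening for small-molecule
antagonist panels, built for datasets like competitive IP3-receptor
inhibitors: tens of structurally diverse compounds with micromolar IC50
values, no common scaffold and no trustworthy alignment.

The package implements the full pipeline as tested, reusable components:

* **Activity curation** — molar `pIC50 = -log10(IC50 [M])`, lipophilic
  efficiency `LipE = pIC50 - clogP`, a configurable activity threshold
  (default 160 µM), fragment (MW < 200 Da) and duplicate removal,
  template selection by the clogP 2–3 / LipE > 5 rule, and MaxMin
  diverse 80/20 train/test splitting.
* **Molecular interaction fields** — Lennard-Jones + electrostatic +
  directional hydrogen-bond energies of four probes (DRY, O, N1, TIP) on
  a 0.5 Å grid around each molecule (C++ kernel).
* **Grid-independent descriptors (GRIND)** — energy/spread node
  filtering with per-probe cutoffs, then auto/cross correlograms: per
  probe pair and 0.4 Å distance bin, the maximal node–node energy
  product. Molecules are canonicalized to their principal-axes frame
  first, so the descriptors are invariant under rigid motion.
* **QSAR modelling** — NIPALS PLS1, LOO / leave-many-out `Q²` and
  `SDEP = sqrt(PRESS/n)`, latent-variable selection,
  fractional-factorial-design (FFD) variable selection with dummy
  variables, and signed coefficient correlograms for interpretation.
* **Validation** — MCC / sensitivity / specificity, Roy's
  `r_m² = r²(1 − √(r² − r₀²))` external-predictivity metric, and the
  standardization-approach applicability domain.
* **Pharmacophore screening** — distance-geometry models (ten built-in
  hypotheses; model 1: hydrophobic centre, HBAs at 2.62/4.79 Å, HBDs at
  5.56/7.68 Å, tolerance 1.5 Å), rule-based feature perception,
  backtracking conformer matching and dataset screening.
* **Synthetic data** — a generator producing pseudo-compound panels with
  planted pharmacophore geometry and activities that are a known sparse
  linear function of the compound's own correlogram variables, so every
  stage is testable against ground truth.

Structures are read and written as SDF V2000 (via ChemmineR) with
partial charges and feature flags in data fields; activity tables are
plain CSV.

## Worked example

```r
library(grindqsar)

cfg <- generator_config(n_compounds = 40, seed = 7)
ds  <- simulate_qsar_dataset(cfg)
head(ds$records[, c("compound_id", "class", "ic50_um", "pic50", "lipe",
                    "is_active")], 4)
#>   compound_id class      ic50_um    pic50      lipe is_active
#> 1      SYN001     A 234.71737661 3.629455 9.8156326     FALSE
#> 2      SYN002     M 336.97310488 3.472405 2.7324180     FALSE
#> 3      SYN003     M   0.28492275 6.545273 2.8619722      TRUE
#> 4      SYN004     B   0.02484206 7.604812 0.6030366      TRUE

sel <- ffd_select(ds$descriptors$X, ds$records$pic50, n_latent = 2,
                  cycles = 2, seed = 7)
sel
#> <ffd_result> 2 cycle(s), 108 variable(s) retained
#>         q2        r2      sdep n_vars dummy_scale cycle
#>  0.8799906 0.9047999 0.8931786    426          NA     0
#>  0.9345400 0.9497365 0.6596576    212 0.001654036     1
#>  0.9553886 0.9643119 0.5445700    108 0.002290120     2

X2  <- ds$descriptors$X[, sel$retained, drop = FALSE]
fit <- fit_pls(X2, ds$records$pic50, n_latent = 2)
cv  <- cross_validate(X2, ds$records$pic50, n_latent = 2)
sprintf("LV-2 model: R2 = %.2f, Q2(LOO) = %.2f, SDEP = %.2f",
        fit$r2, cv$q2, cv$sdep)
#> "LV-2 model: R2 = 0.96, Q2(LOO) = 0.96, SDEP = 0.54"

scr <- screen_pharmacophore(ds$molecules, ds$records$is_active,
                            builtin_models()$model1)
sprintf("model-1 screening: MCC = %.2f, sensitivity = %.2f, specificity = %.2f",
        scr$metrics$mcc, scr$metrics$tpr, scr$metrics$tnr)
#> "model-1 screening: MCC = 0.90, sensitivity = 0.90, specificity = 1.00"
```

Reading the numbers: each FFD cycle prunes variables whose exclusion
does not degrade the cross-validated error (426 → 212 → 108 here) and
improves `Q²` from 0.88 to 0.96 while `SDEP` drops from 0.89 to 0.54
pIC50 units. Screening the built-in 5-feature pharmacophore against the
same panel recovers the planted active motif with MCC 0.90. On synthetic
data with a known linear truth these statistics are intentionally
optimistic; see the methods vignette
(`vignettes/grind-qsar-methods.Rmd`) for what the generator does and
does not emulate.

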