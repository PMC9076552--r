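# thiolex

Differential thiol-labeling proteomics and active/deactive state analysis
for respiratory complex I.

Mitochondrial complex I switches between a catalytically active A-state
and a deactive D-state, and the solvent exposure of a cysteine on the ND3
subunit loop (Cys39) has historically been the biochemical marker of that
transition. `thiolex` is an R toolbox for everyone who measures that kind
of cysteine chemistry quantitatively: it computes stable-isotope labeled
peptide masses and MRM transitions, turns extracted-ion-chromatogram peak
areas into per-cysteine exposure fractions, runs a structure- and
conservation-based survey of all cysteines in a complex, extracts enzyme
rates from plate-reader time courses, and simulates the four-pool
A/D/alkylation kinetic model. Seeded generators produce every input with
known ground truth, so the whole pipeline is testable offline.

## The core quantities

* **Exposure fraction.** Exposed thiols get label 1 in the native state;
  denaturation + reduction expose the rest for label 2. Per replicate,
  `f = A1 / (A1 + A2)` from XIC peak areas; replicates are averaged with
  SEM dispersion. Light/heavy iodoacetamide differ by exactly
  2×(¹³C−¹²C) + 2×(²H−¹H) = 4.01926 Da.
* **m/z convention.** Monoisotopic masses from an embedded atomic table,
  `m/z = (M + z·1.00728)/z`.
* **Gamma-S SASA.** Shrake-Rupley accessibility of the cysteine γ-sulfur,
  exposed when strictly above 5 Å².
* **Rates.** Beer-Lambert conversions (ε₃₄₀₋₃₈₀ = 4.81 mM⁻¹cm⁻¹ for NADH,
  ε₄₁₂ = 13600 M⁻¹cm⁻¹, ε₂₄₀ = 43.5 M⁻¹cm⁻¹) and sliding-window maximal
  linear rates, with rotenone-background subtraction and a 50%-of-max
  reactivation-lag rule.
* **A/D model.** First-order pools {A, D, A-alk, D-locked} with exact
  matrix-exponential propagation; alkylated D is locked forever, alkylated
  A stays fully active.

## Worked example

```r
library(thiolex)

# 1. Reference masses of the bovine ND3 Cys39 peptide, light vs heavy IAM
mass_table("TSPYECGFDPMGSAR", labels = c("IAM-light", "IAM-heavy"),
           charges = 2L)
#>          sequence     label z       mz
#> 1 TSPYECGFDPMGSAR IAM-light 2 837.8480
#> 2 TSPYECGFDPMGSAR IAM-heavy 2 839.8576

# 2. Exposure from a synthetic peak-area table (truth: 65% / 93%)
g <- gen_peak_table(c(A_state = 0.65, D_state = 0.93),
                    n_replicates = 6, cv = 0.05, seed = 7)
estimate_exposure(g$peaks, two_label_scheme())
#>   species_id exposed_fraction      se n_replicates prop_exposed prop_occluded
#> 1    A_state            0.654 0.00883            6        0.654        0.3460
#> 2    D_state            0.931 0.00128            6        0.931        0.0686

# 3. Alkylating the D-state locks the enzyme: substrate at t = 60 min
#    cannot reactivate it
tr <- simulate_ad(ad_params(k_d = 0.15, k_a = 0.4, k_x = 0.5),
                  data.frame(t_min = c(0, 60, 60),
                             event = c("add_alkylator", "quench_alkylator",
                                       "add_substrate"),
                             value = c(1, NA, NA)),
                  dt = 10, horizon = 90, init = c(0, 1, 0, 0))
tr[tr$time %in% c(0, 30, 60, 90), c("time", "A", "D", "D_locked", "activity")]
#>    time A D D_locked activity
#> 1     0 0 1        0        0
#> 4    30 0 0        1        0
#> 7    60 0 0        1        0
#> 10   90 0 0        1        0
```

The exposure estimates land on the programmed truths within the noise of
six replicates; the simulator shows the D-locked pool absorbing the whole
population, so activity stays 0 even after substrate re-addition.

## Command line

```sh
Rscript inst/cli/thiolex.R masses --sequence TSPYECGFDPMGSAR --charge 2
Rscript inst/cli/thiolex.R exposure --peaks peaks.csv --scheme two-label
Rscript inst/cli/thiolex.R survey --alignment aln.fasta --reference mouse \
        --structures active=a.pdb,deactive=d.pdb
Rscript inst/cli/thiolex.R simulate --what peaks --seed 1
```

## Package layout

* `R/composition.R`, `R/peptide_chem.R` — elemental compositions, label
  registry, peptide/fragment m/z, tryptic digestion, transition lists
* `R/exposure_quant.R` — XIC integration, labeling schemes, exposure
  estimation, standard curves
* `R/cys_survey.R`, `R/io.R` — conservation, detectability, Shrake-Rupley
  SASA, survey summaries; FASTA/PDB I/O
* `R/kinetics.R` — NADH/citrate-synthase/Amplex rates, reactivation lag,
  GSH labeling kinetics
* `R/ad_analysis.R` — activity-exposure regression, A/D/alkylation
  simulator
* `R/synthetic_data.R` — seeded generators with ground-truth sidecars
* `vignettes/thiolex-methods.Rmd` — models, assumptions, numerical
  conventions, limitations
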