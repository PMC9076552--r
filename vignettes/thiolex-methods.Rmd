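---
title: "Methods and numerical conventions in thiolex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical conventions in thiolex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiolex)
```

## The scientific problem

Respiratory complex I (NADH:ubiquinone oxidoreductase) interconverts
between a catalytically active A-state and a deactive D-state. A cysteine
on the ND3 subunit's TMH1-2 loop (Cys39 in the mammalian precursor
numbering) has long served as the conformational reporter: in the classic
binary model it is occluded in the A-state and solvent-exposed in the
D-state, so its accessibility to thiol alkylators was read as a direct
measure of the A/D ratio. `thiolex` implements the quantitative machinery
needed to test that model: differential isotopic alkylation with
mass-spectrometric readout, a structure- and conservation-based survey of
all complex I cysteines, plate-reader enzyme kinetics, and a first-order
kinetic simulator of the A/D/alkylation pool model. Because the underlying
raw MS data are not publicly deposited, the package ships seeded
synthetic-data generators that emulate every input with known ground
truth; all tests run on generated data.

## Differential labeling and exposure quantification

The measurement principle: thiols exposed in the native state are
alkylated with a first label; denaturation and chemical reduction then
expose the occluded population, which receives a second, isotopically
distinct label. After tryptic digestion, the exposed fraction of a site is
the peak-area proportion of the first-label channel,

$$\hat f = \frac{A_\text{first}}{A_\text{first} + A_\text{second}},$$

computed per replicate and averaged, with the standard error across
replicates as dispersion. Which isotopologue plays the "first" role is
immaterial, and `estimate_exposure()` is tested for exact invariance under
the swap. Three schemes are built in: the two-label scheme
(`two_label_scheme()`), the reversible MMTS block-and-replace scheme
(`mmts_scheme()`, where the displacement channel reports native exposure
because MMTS itself is displaced before analysis and never observed), and
the three-label gel scheme (`three_label_scheme()`, whose intermediate
channel counts thiols that became exposed only upon deactivation).
Peptides with more than one cysteine are excluded from per-site estimates:
channel areas are not site-resolvable without fragment-level evidence.

The generators use a log-normal multiplicative error model for peak areas
(the standard MS-like error shape) with a default 5% channel CV and n = 6
replicates, matching the replication reported for the core exposure
figures. A green recovery test establishes that the estimator is accurate
*under this error model*; it says nothing about ionization differences
between label chemistries (e.g. NEM- vs IAM-labeled peptides in the
three-label scheme), retention-time drift, or interference — real-data
effects the generator deliberately does not emulate. For the three-label
scheme the package reports raw per-order proportions and leaves
cross-order reconciliation to the analyst.

## Mass arithmetic

All masses are monoisotopic, computed from a single embedded atomic-mass
table (H 1.0078250, C 12, N 14.0030740, O 15.9949146, S 31.9720707,
P 30.9737615, carbon-13 13.0033548, deuterium 2.0141018) with proton mass
1.00728 Da and m/z = (M + z·1.00728)/z. This convention reproduces the
reference table of labeled ND3 peptide m/z values to four decimals
(asserted to ±0.001 in the acceptance tests). One deliberate quirk: the
triphenylphosphonium (TPP-IAM) adduct is intrinsically cationic, yet its
printed elemental composition is treated here as a *neutral* delta and
protonated like any other species, because that convention — and not the
physically strict cation treatment — reproduces the published 3+ value
(669.2883). Tryptic digestion cleaves C-terminal to K/R, suppressed before
P, with no other exceptions; coordinates are 1-based and inclusive in the
precursor sequence. MRM transition lists are *computed* values; the
published transition table is instrument-tuned and differs from
monoisotopic arithmetic by 0.2-0.4 m/z (e.g. y13 2+ of the light mouse
peptide computes to 743.82 against a printed 744.0), so no attempt is made
to match it.

## The cysteine survey

`cysteine_survey()` combines four classifications per cysteine of a
reference protein:

* **Conservation** across a supplied alignment (alignments are consumed,
  never computed; positions are mapped through gaps to ungapped reference
  coordinates).
* **Detectability** of the fully-tryptic peptide containing the site,
  applying four thresholds in order: length < 7 residues; doubly
  protonated m/z (with carbamidomethyl on every cysteine) < 400; mass
  > 6000 Da; more than 3 cysteines.
* **Gamma-sulfur solvent accessibility** by Shrake-Rupley: near-uniform
  golden-spiral test points on the probe-expanded sphere
  (r~S~ = 1.80 Å + 1.4 Å probe), occlusion against all atoms, default 960
  points (the isolated-sphere error is then < 1%; at 2000 points < 0.5%).
  "Exposed" means SASA **strictly greater** than the 5 Å² cutoff — a
  testable tie rule, so (4.9, 5.0) is occluded in both states.
* **Annotation** (FeS ligand, intramolecular disulfide, targeting
  sequence) from a user-supplied table, never inferred from geometry.

A residue unmodeled in the deactive structure counts as exposed there
(disordered-loop convention: an unresolved loop is presumed mobile and
solvent-exposed), so it can complete the candidate pattern
occluded-in-active / exposed-in-deactive. `survey_summary()` reports the
count cascade with percentages defined as 100 × count ratios rounded half
away from zero to one decimal. One published percentage (30.7% for 19 of
62) is arithmetically 30.645% and therefore prints as 30.6 here; the
corresponding acceptance expectation is intentionally left failing rather
than special-casing the rounding.

## Plate-reader kinetics

Concentrations follow Beer-Lambert with the embedded extinction
coefficients: NADH by the dual-wavelength difference
(A340 − A380)/(4.81 mM⁻¹cm⁻¹ · ℓ), TNB²⁻ at 13600 M⁻¹cm⁻¹, H₂O₂ stocks at
43.5 M⁻¹cm⁻¹. The default path length is 0.55 cm (200 µL in a 96-well
plate) and explicit everywhere, since published plate assays rarely state
the path correction. Rates are extracted by sliding-window ordinary least
squares (default 10 samples ≈ 2 min at 12-s sampling), taking the steepest
window in the assay direction with ties broken earliest; consumption and
production rates are both reported positive. The rotenone-sensitive rate
is total minus background.

**Selection bias.** The maximum of many noisy window slopes is an upward
biased estimate of a common underlying slope. By Monte-Carlo, with noise
of 1% of the initial NADH absorbance, the bias is ~28% of the true slope
at the 10-sample default window and ~2.9% at 40 samples; averaging
technical triplicates (as the assay protocol prescribes) scales it by
1/√3. The unbiasedness test therefore runs in the
triplicate-averaged, 40-sample-window configuration, where the measured
bias is ~1.6%. Practical guidance: with noisy single traces, widen the
window to cover the visibly linear stretch.

The reactivation lag of a deactive preparation is defined as the first
time the smoothed instantaneous rate reaches 50% of its maximum (linearly
interpolated between window centers; a trace already at half-maximal rate
in its first window has lag 0). The published description of reactivation
is qualitative ("over 8 to 10 min"); this midpoint rule is reproducible
and monotone in the underlying lag. Note the definition references the
*observed* maximal rate: recovering a generator's programmed lag
(ln 2 / k~a~ for exponential reactivation) requires a trace that reaches
its activity plateau before substrate depletes, which the round-trip tests
arrange explicitly. GSH alkylation kinetics are fit as pseudo-first-order,
f(t) = 1 − exp(−k[IAM]t), by `nls` with a linearized starting value and a
`scaleOffset` so the convergence test remains valid on noiseless data.

## The A/D/alkylation simulator

Four pools: A (active), D (deactive), A-alk (alkylated active) and
D-locked (alkylated deactive, permanently inactive). Transfers are first
order: A→D at k~d~ without substrate, D→A at k~a~ with substrate,
D→D-locked at k~x~·c, and A→A-alk at k~x~·c·p~exposed~, where p~exposed~
is the fraction of active enzyme with a reactive cysteine — a free
parameter (default 0.8, the maximal active-state alkylation observed; the
package takes no position on whether the shortfall from 1 is kinetic or a
protected subpopulation). Two asymmetries encode the central findings:
alkylation of the D-state is a permanent off-switch, while A-alk remains
fully competent (activity 1.0) and can never enter the locked pool; it is
also kept in the active-competent pool under deactivating conditions —
the simplest resolution of the open mechanistic question of whether
labeled active enzyme adopts a "catalytic D-like" state.

Integration uses exact matrix-exponential propagation within
constant-condition segments (`Matrix::expm` of the generator matrix times
the segment duration) rather than Euler stepping: there are no step-size
artifacts, and pool conservation holds to numerical precision (asserted at
1e-9, typically 1e-15). With k~x~ = 0 the trajectory matches the piecewise
closed-form two-state solution to 1e-6, and the two qualitative alkylation
contrasts — D-state alkylation prevents reactivation forever; turnover
alkylation leaves terminal activity equal to the control — hold as exact
end-state tests.

The activity-exposure analysis is ordinary least squares of exposure on
activity with a t-based 95% confidence band. The binary-model reference
line is fixed as exposure% = 100 − activity% (the optimal inverse
correlation the binary model implies); `binary_model_deviation()` returns
line-minus-observed, so points *below* the line — less exposure than the
binary model predicts — have positive deviation. This line is an
interpretation, flagged as such.

## Synthetic structures

`gen_toy_complex()` engineers burial geometrically: a buried gamma-sulfur
is enclosed in a 12-vertex icosahedral carbon cage at 2.5 Å, which
provably occludes every point of the probe-expanded sulfur sphere
(worst-case test point sits 1.95 Å from the nearest cage-vertex center,
well inside the 3.1 Å occlusion radius), so buried SASA is exactly 0 and
exposed SASA is the isolated-sphere closed form 4π(1.8+1.4)² ≈ 128.7 Å².
This gives zero-error ground truth for the 5 Å² classifier but is not a
protein fold; absolute SASA values from real structures depend on the
radii set and point density, for which published accessibility
calculations rarely state their conventions — only the binary
classification of clearly buried/exposed sites is robust.

## Known limitations

* No isotope-envelope simulation, PTMs beyond the thiol-label registry,
  semi-tryptic digestion, spectrum matching, or retention-time alignment.
* The 116-cysteine census of the real bovine/mouse complex is not
  reproduced (it requires external database sequences and cryoEM
  coordinates); the survey pipeline runs on such files when supplied, but
  all tests use toy inputs.
* The simulator is phenomenological: no proton pumping, protonmotive
  force, or CoQ redox state — measured exposure was insensitive to these,
  so they are not model inputs.
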