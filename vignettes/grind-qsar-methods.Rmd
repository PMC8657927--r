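---
title: "Grid-independent descriptors and pharmacophore screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-independent descriptors and pharmacophore screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: an
alignment-free 3D-QSAR pipeline (molecular interaction fields to
grid-independent correlogram descriptors to PLS with variable selection)
combined with distance-geometry pharmacophore screening, plus the
synthetic data generator that makes every stage testable end to end.

## The modelling problem

Given a panel of competitive channel antagonists with micromolar IC50
values, we want (i) a predictive model linking 3D structure to potency
that does not depend on a molecular alignment, and (ii) an interpretable
hypothesis -- which interaction features, at which mutual distances,
drive inhibition. Activities are modelled on the molar pIC50 scale,
`pIC50 = -log10(IC50 [M])`; a compound is "active" when its IC50 is at or
below 160 uM, the gap in the activity landscape the panel exhibits.
Lipophilic efficiency, `LipE = pIC50 - clogP`, balances potency against
lipophilicity and drives template selection: the preferred template has
clogP in [2, 3] and LipE above 5 (the rule is relaxed, with a flag, when
no compound reaches 5 -- the canonical template sits at LipE 4.6).

## Molecular interaction fields

For each molecule a regular grid (0.5 A spacing, 5 A margin -- the box is
the molecular bounding box grown by the margin) is probed with four
chemical prototypes: DRY (hydrophobic), O (carbonyl-oxygen hydrogen-bond
acceptor), N1 (amide-nitrogen hydrogen-bond donor), TIP (molecular
shape). The energy at a grid point is the sum of three terms:

* Lennard-Jones: `eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with
  Lorentz-Berthelot mixing against a small editable per-element parameter
  table (`element_parameters()`). The table is a generic published-style
  set, not a proprietary force field: downstream the energies matter only
  through node filtering and products, so physically reasonable
  magnitudes preserve the method's structure.
* Electrostatics: `332.06 q_p q_a / (eps(r) r)` with the
  distance-dependent dielectric `eps(r) = 4r`, charges in e, energies in
  kcal/mol.
* Hydrogen bonding: a 6-4 radial well
  `eps_hb (2 (r0/r)^6 - 3 (r0/r)^4)`, depth 4 kcal/mol at r0 = 2.9 A,
  weighted by `cos^2` of the angle between the atom's idealized
  interaction direction (pointing away from its bonded neighbours, or
  away from the molecular centroid for bondless pseudo-atoms) and the
  atom-to-probe vector. Donor probes pair with acceptor-flagged atoms and
  vice versa.

Numerical edge cases: a probe-atom pair closer than 0.1 A contributes a
flat +5 kcal/mol (the core clamp) instead of its diverging terms;
elsewhere the raw r^-12 repulsion keeps atomic cores strongly positive,
so the negative-energy nodes selected later can never sit inside an
atom. Component additivity (`E = E_lj + E_el + E_hb`) holds exactly at
every point, and the electrostatic component is exactly linear in the
partial charges.

The TIP probe's published functional form is not available, so the shape
field is a documented surrogate, isolated behind `probe_spec` so it can
be swapped: the steric LJ field defines a molecular body at the +0.5
kcal/mol iso-level; body voxels touching the exterior form the shape
shell; each shell voxel scores `-1` times its convexity (the fraction of
its 26-neighbourhood outside the body, rescaled to [0, 1] over the
shell). Convex protrusions -- steric hot spots -- score most negative.

## From fields to grid-independent descriptors

Each probe field is discretized into at most 100 nodes: grid points at or
below the probe's energy cutoff (TIP -0.75, DRY -0.5, O -2.6, N1 -4.2
kcal/mol) are filtered greedily, starting from the global minimum and
repeatedly adding the candidate maximising
`(1 - w) |E|/|E|max + w dmin/dmax` with spread weight `w = 0.5` --
an energy/coverage compromise in the spirit of field-discretization
algorithms whose exact published form is proprietary.

Node pairs are then encoded into the 10 auto- and cross-correlograms
(DRY-DRY, O-O, N1-N1, TIP-TIP and the six cross pairs): for each
half-open 0.4 A distance bin `[b w, (b+1) w)` up to 24 A, the descriptor
value is the maximum node-node energy product over pairs falling in the
bin (two favourable, negative energies give a positive product;
self-pairs are excluded in auto blocks). The 0.4 A bin width reproduces
the conventional reporting intervals (6.4-6.8, 6.8-7.2, 7.6-8.0,
10.4-10.8 A are consecutive bins). A consistently-selected variant
(`encode_clacc`) re-chooses, per variable, each compound's contributing
pair among those within 90% of its bin maximum so as to minimise the
variable's coefficient of variation across compounds (at most 10 sweeps);
the maximum-product encoder is the default, and the CLACC-style variant
is a documented approximation of an algorithm whose published form is not
restated here.

Alignment independence -- the defining property of these descriptors --
is guaranteed by construction: before the grid is built, each molecule is
rigidly moved into a canonical frame (centroid at the origin, principal
axes of the coordinate covariance ordered by variance, signs fixed by
projection skewness, right-handed completion). Any rigid motion of the
input then yields identical grids, nodes and descriptors up to
floating-point error; the test suite asserts equality to 1e-6. Molecules
with (near-)degenerate principal variances keep their centred input
axes, for which the invariance is only approximate -- randomly generated
and real molecules are almost never degenerate.

## PLS, cross-validation and variable selection

The descriptor matrix (all-zero columns dropped, with the mask recorded)
is linked to pIC50 by single-response NIPALS PLS on centred data.
Centring-only is the default because correlogram variables share an
energy-product scale; unit-variance scaling is available. Model quality
is tracked by training R^2, leave-one-out (or seeded leave-many-out,
default group size 5) `Q^2 = 1 - PRESS/SS_tot` and
`SDEP = sqrt(PRESS/n)`. `select_lv` picks the latent-variable count
maximising Q^2 (ties to the smaller model) and warns when `R^2 - Q^2`
exceeds 0.3, the conventional overfitting alarm.

Variable selection uses a fractional-factorial design: dummy variables
(20% of the live count) are appended; a balanced two-level design with
six rows per variable includes each variable in exactly half the rows;
each row's reduced model is scored by cross-validated SDEP; a variable's
effect is the mean SDEP of rows excluding it minus rows including it.
Dummies are inert, so their mean absolute effect estimates the noise
floor, reported per cycle. Two removal rules are implemented:

* `"nonhelpful"` (default): remove a variable when its effect is
  negative -- excluding it does not degrade prediction. This is the
  remove-uncertain-variables variant of the method.
* `"harmful"`: remove only when the effect is below minus the dummy noise
  floor.

The conservative rule removes too little to be useful on
energy-product correlograms (on planted data it removes under half of
pure-noise columns); the default rule removes the bulk of noise columns
while retaining informative ones, which is what the selection step exists
to do. Two cycles are the default, mirroring the usual
"complete / FFD1 / FFD2" reporting.

Interpretation uses the signed coefficient correlogram
(`coefficient_correlogram`): coefficients on the original variable scale,
grouped by probe pair and ordered by distance bin; positive values mark
variables directly correlated with potency. Because adjacent 0.4 A bins
of the same probe pair are near-collinear aliases, variable selection may
legitimately prune a planted informative bin while keeping its
neighbours; when recovery of a specific variable's sign is assessed (as
in the acceptance suite), the coefficient is read from the post-selection
model when the variable survived and from the pre-selection full model
otherwise.

## Pharmacophore models and screening

A pharmacophore is an ordered feature list (hydrophobic / HBA / HBD, each
with a reporting radius) plus a symmetric inter-feature distance matrix
and one global tolerance (1.5 A). Ten built-in models ship with the
package; model 1 (hydrophobic centre with acceptors at 2.62 and 4.79 A
and donors at 5.56 and 7.68 A) is the selected final hypothesis. The
triangle inequality is checked on construction; one built-in printed
matrix (model 3) violates it beyond tolerance and warns on load --
printed tables are rounded and internally imperfect, and the package
surfaces rather than silently repairs that.

Matching reduces to pairwise-distance compatibility: a backtracking
search over kind-compatible assignments prunes any partial assignment
whose implied distance deviates from the model by more than the
tolerance, returns the first admissible complete assignment
(deterministic feature order) and scores it
`1 - RMS(deviations)/tolerance`. Proprietary scoring internals
(feature direction vectors, exclusion volumes) are out of scope; an
exclusion-volume slot is reserved in the model schema. Feature perception
takes pre-assigned flags verbatim when present; otherwise donors are O/N
bearing an explicit hydrogen, acceptors are carbonyl/ether oxygens
(hydroxyls act as donors -- the convention used for the template
molecule's attribution) and nitrogens with an open valence, and
hydrophobic features are centroids of ring systems and of heteroatom-free
aliphatic carbon clusters. Screening declares a compound a hit when any
conformer matches (first-match stop) and crosses hits with activity
labels into a confusion matrix: `MCC`, `TPR = TP/(TP+FN)` (sensitivity)
and `TNR = TN/(FP+TN)` (specificity), with vanishing denominators
reported as undefined rather than zero.

## External validity metrics

For a test set, `rm_squared` reports the squared Pearson correlation
r^2, the through-origin determination coefficient r0^2 (slope
`k = sum(o p)/sum(p^2)`), and the external-predictivity summary
`rm2 = r^2 (1 - sqrt(max(r^2 - r0^2, 0)))`, with 0.5 the conventional
"good external predictability" threshold. The applicability domain uses
the standardization approach: scores `s_ki = |x_ki - mu_i|/sigma_i`
against the training distribution; a compound is inside when its maximum
score is at most 3, outside when even the minimum exceeds 3, and
otherwise decided by `S_k = mean(s_k) + 1.28 sd(s_k) <= 3` (1.28 is the
90th-percentile normal quantile of the cited method). A worked
consequence of the rule worth knowing: with 20 descriptors, one
descriptor 8 sigma from the training mean leaves a compound inside
(S = 2.69) while 10 sigma pushes it out (S = 3.36).

## The synthetic data generator

The generator emulates the statistical structure of the curated panel so
that every downstream stage has a known ground truth: about 40
pseudo-compounds in four scaffold classes with weights 12:6:3:19, IC50
spanning 0.0029-20,000 uM, a 160 uM activity threshold, and Gaussian
assay noise of 0.3 pIC50 units. Pseudo-compounds are deliberately not
chemically valid molecules -- they are 15-60 atom point sets with typed
charges and feature flags, sufficient because every downstream operator
consumes geometry, types and charges only; this removes any dependence on
conformer generation.

Half the compounds (configurable `motif_fraction`) carry the "active
motif": the five features of pharmacophore model 1 planted at a 3D
embedding of its distance matrix (classical MDS; the printed matrix
embeds in three dimensions to 0.004 A) with 0.03 A coordinate jitter,
plus a second hydrophobic centre 6.6 A away. The rest carry an
unfavourable arrangement (a short donor pair and a long acceptor-acceptor
axis). Class-specific decoration (phosphate-like clusters, macrocycle
rings, biphenyl-like rings, random blobs) adds realistic diversity
without informative geometry; clogP is drawn per class in its typical
range, so template selection behaves as on the real panel.

Activities are a known sparse linear function of the compound's own
correlogram variables: `pIC50 = 2.6 + sum(beta x) + N(0, 0.3)`, censored
to the assay dynamic range (an IC50 outside the configured span would not
be reportable). The six informative variables are the narrative probe
pairs at their conventional distances -- DRY-DRY 6.4-6.8 A (+),
DRY-N1 7.6-8.0 A (+), DRY-TIP 5.6-6.0 A (+), O-O 10.4-10.8 A (+),
O-O 2.4-2.8 A (-), N1-N1 9.2-9.6 A (-) -- with coefficients
(1.5, 0.25, 1.2, 0.11, -0.06, -0.08) calibrated once against the default
geometry so that the noiseless pIC50 spans the assay range, motif
compounds are active, and screening the planted motif with model 1 lands
in the MCC 0.65-0.85 regime. The coefficient signs follow the
generator's own geometry (each informative variable's group alignment),
which is what makes their recovery a well-posed test. One master seed is
split into independent geometry / charge / noise substreams so changing
one does not shift the others.

What the generator does **not** emulate -- and hence what passing tests
do and do not show about real data: real conformational ensembles and
their energy-minimization artefacts, protonation and stereochemistry,
correlated assay errors, and the chemistry-specific relationship between
scaffold class and activity. Tests passing on synthetic data demonstrate
that the pipeline's machinery is correct and that its statistics behave
as designed under a known truth; they do not certify predictive accuracy
on any real chemical series.

## Problem sizes and numerical choices in the test suite

The suite runs the full pipeline at the emulated study size (40
compounds, 0.5 A grids, 100 nodes per probe, 600 correlogram variables)
and repeats the regime experiments over 25 seeds; oracle comparisons
(brute-force pair enumeration, literal leave-one-out refits, naive
field loops) use smaller instances (up to 30 nodes, grids of a few
thousand points) where exhaustive computation is exact and fast.
Tie-breaks are fixed throughout for reproducibility: greedy node
selection prefers the lowest candidate index, template selection breaks
LipE ties by lower IC50 then lexicographic id, MaxMin splitting breaks
distance ties by row order, and latent-variable selection prefers the
smaller model.

## Known limitations

* The LJ/HB parameter table and the TIP shell surrogate are physically
  reasonable stand-ins, not fitted force fields; absolute energies are
  meaningful only relative to the probe cutoffs.
* The CLACC-style encoder and the FFD design are reconstructions of
  methods whose published forms are not freely available; both are
  documented above and kept behind options.
* At 0.4 A resolution adjacent bins alias; interpretation should read
  hotspot regions, not single bins.
* Pharmacophore matching ignores exclusion volumes and feature
  directionality; fit scores are comparable within a model, not across
  models.
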