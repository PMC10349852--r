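---
title: "Predicting arene C-H position-selectivity from physical-organic descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting arene C-H position-selectivity from physical-organic descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiosel)
```

## The problem

Non-directed (directing-group-free) arene C–H functionalization leaves the
catalyst to choose among several chemically distinct C–H positions. Which
isomer dominates — ortho, meta, para, or an α/β position of a heteroarene —
is set by the relative free energies of the competing pathways, and
predicting that preference from the substrate's electronic and steric
profile is what makes reaction planning practical: a reliable model spares a
bench chemist from running and separating every isomer.

`regiosel` frames the task as *pairwise competition between
symmetry-distinct sites* of one arene. For every pair of competing site
classes it builds a feature vector from per-site physical-organic
descriptors plus molecule-level context, learns the apparent free-energy
preference between the two sites, and converts model output back to isomer
distributions through Boltzmann statistics.

## Sites, symmetry and statistical factors

Sites are aromatic carbons bearing a hydrogen. Aromaticity is approximated
purely topologically: rings of size 5 or 6 over C/N/O/S whose carbons are
all sp2-like (graph degree ≤ 3), perceived on a bond graph inferred from
covalent radii. Symmetry classes come from Weisfeiler–Lehman color
refinement of the molecular graph — a canonical-ranking scheme that, for
molecules of this size, coincides with the orbits of the element-colored
graph automorphism group (the test suite checks this against an independent
automorphism oracle built on igraph/BLISS). Working from topology alone is
deliberate: 3D rotamer noise can never split a class that the 2D structure
says is symmetric.

A class of k equivalent C–H positions carries statistical factor
(multiplicity) k. All conversions between observed product fractions and
per-site free energies divide these factors out, so the regression target
reflects intrinsic per-site reactivity:

$$\Delta\Delta G_{\mathrm{app}} = RT \,
  \ln\!\frac{f_A/m_A}{f_B/m_B}, \qquad R = 1.9872\times10^{-3}
  \ \mathrm{kcal\,mol^{-1}\,K^{-1}}$$

The target unit is kcal/mol at the measurement temperature. The observed
ortho/para ratio of 17:1 at 333.15 K, for example, corresponds to 1.876
kcal/mol. We chose an energy target (rather than a raw or log ratio)
because it makes the reported MAE interpretable on the scale chemists use
for selectivity arguments; a delta-encoded or log-ratio target remains a
configuration flag away.

## The 28-dimensional pairwise encoding

Each competing pair is encoded as

```
[ site A block (13) | site B block (13) | redox potential (1) | temperature (1) ]  = 28
```

The per-site block holds four steric descriptors computed from 3D geometry
— percent buried volume and Sterimol L, B1, B5 — and six electronic
descriptors ingested from external quantum-chemical tables — Fukui f(+),
f(−), f(0), the dual descriptor f(+)−f(−), atomic partial charge, and the
C–H bond dissociation energy — plus three named extension slots that absorb
any additional columns a descriptor table provides (zero-filled when
absent). The exact roster beyond the named families is configurable through
`descriptor_schema()`; the default arithmetic 2×13 + 1 + 1 = 28 is checked
in the tests. QM descriptors are *ingested, never computed*: the package
contains no quantum chemistry.

Pair order is canonicalized (lexicographic class label, ties by atom index)
and the sign of the target follows the ordering. Antisymmetry of the
learned relation is enforced by *swapped-pair augmentation* at training
time: every training row is duplicated with the site blocks exchanged and
the target negated. For linear models this provably makes predictions
exactly antisymmetric; for tree ensembles it holds to within model noise,
and a property test asserts both.

## Steric descriptors

**Percent buried volume** is the fraction of a probe sphere (default radius
3.5 Å) centered on the site carbon occupied by the scaled van der Waals
spheres of all other atoms. We use Bondi radii scaled by 1.17 — the common
convention of buried-volume calculators — with the center atom excluded and
hydrogens included, and integrate by deterministic regular-grid counting at
0.05 Å pitch. The grid estimate is pinned against an independent
10⁶-point Monte-Carlo integration to within 0.5 percentage points across
the fixture set.

**Sterimol L, B1, B5** follow Verloop's definitions with unscaled Bondi
radii: L is the maximal axial extent from the base atom along the
attachment axis (plus radius), B5 the maximal perpendicular half-width, B1
the minimal half-width over in-plane directions. B1 is found by an angle
scan, 0.1° by default. We chose the scan over exact support-function
minimization for transparency; at 0.1° its discretization error is well
below the 0.01 Å at which the tests pin it against a brute-force oracle,
even where the width function has a kinked minimum (a 1° scan does not
reliably reach that bound, which is why the finer default was adopted).

For a ring C–H site the Sterimol axis runs from the carbon to its hydrogen
and the substituent is the hydrogen plus all atoms within a configurable
graph radius of the carbon (default 2 bonds). This site-local convention is
well-defined for every site of every arene — including unsubstituted
benzene — and varies smoothly with the flanking substitution pattern, which
is exactly the information the steric block must carry; measuring each ring
substituent from its ipso carbon instead is available through
`compute_sterimol()` directly.

## Models and validation

The registry covers the families a practitioner would shortlist for a
few-hundred-row tabular problem: extremely randomized trees, random forest
(both via ranger), gradient-boosted trees (xgboost), RBF support-vector
regression (e1071), k-nearest neighbors (caret), and closed-form
ridge/ordinary least squares. Hyperparameters are fixed, documented
defaults — extra-trees uses 100 trees, one random split per candidate
feature over all features, no bootstrap, minimum node size 10 — because the
workflow reports none of the tuning that would make nested selection
meaningful at this data size.

Validation is leave-one-out at the pair level (the literal reading of
"leave-one-out data splitting"), with a grouped leave-one-arene-out mode
for the prospective setting, and `oos_evaluate()` for explicit held-out
arene lists; in grouped and OOS modes a structural assertion guarantees no
training row shares an arene with an evaluated row. Pearson R is computed
over the concatenated held-out predictions, since size-one folds admit no
per-fold correlation; an undefined correlation (constant targets) is
reported as NaN rather than silently dropped. Greedy forward feature
selection maximizes LOO Pearson R with a stopping tolerance of 10⁻³ and
lexicographic tie-breaks; impurity importances are normalized to sum to 1,
and permutation importance reports mean R degradation over 10 shuffles.

## What the synthetic benchmark emulates — and what it does not

The deposited experimental dataset behind the published accuracy figures
requires a download, so the package ships a generator whose ground truth is
known exactly. Each synthetic arene has 2–4 site classes; per-site
descriptors are drawn from loosely physical distributions (e.g. %V_bur ~
N(35, 8) truncated to [0, 100], f(−) ~ N(0.08, 0.03) clipped at 0, BDE ~
N(112, 3) kcal/mol); the true per-site energy is a fixed linear map over
descriptors, dominated by the reacting site's Fukui electrophilicity
descriptor f(−) (40 kcal/mol per e-unit, about 1.2 kcal/mol of target
spread) with smaller steric, BDE and charge terms; pair targets are the
energy differences plus Gaussian noise of 0.25 kcal/mol at 333.15 K. The
molecule-level and temperature weights default to zero so targets are
exactly antisymmetric under site exchange — both features are still
emitted, as honest distractors. A `nonlinear` variant adds threshold
interactions to give tree ensembles a structural advantage, which is how
the algorithm-ranking test avoids rewarding the linear model by
construction.

At these conditions (150 pairs, σ = 0.25) the extra-trees LOO Pearson R has
a 20-seed median around 0.94 — a scaled analogue of, not a substitute for,
the published accuracy. Passing synthetic tests shows the machinery is
correct and well-calibrated under a known mechanism; it does not show that
real electronic-structure descriptors carry the same signal, that real
selectivity is linear in them, or that measurement error is Gaussian. The
acceptance thresholds (median R ≥ 0.85; the Fukui feature ranking first in
≥ 18/20 seeds) were set from the generator's stated conditions, not tuned
to the observed results.

Problem sizes throughout the suite (150 pairs, 20 seeds, 10⁶ Monte-Carlo
points, 0.05 Å grids) were chosen as the smallest at which the checked
properties are stable run-to-run; they are the package's declared study
conditions, restated in `scripts/acceptance.R`.

## Numerical and design choices

* **Gauge of site potentials.** `aggregate_site_scores()` solves the
  pairwise least-squares problem for per-site potentials; the solution is
  defined up to a constant, fixed by a zero-sum gauge (arbitrary but
  deterministic). Disconnected comparison graphs are an error that names
  the components rather than a silent partial answer.
* **Zero fractions.** An unobserved isomer makes the free-energy target
  infinite; `ratio_to_ddg()` errors by default and offers an explicit
  epsilon clamp. Unmeasured minor isomers are renormalized away over the
  measured classes.
* **Degenerate inputs.** Coincident Sterimol axis atoms, empty occupancy
  sets, constant targets, unknown registry names and schema violations all
  fail loudly with the offending name in the message; `validate_inputs()`
  collects cross-file violations into a table instead of stopping at the
  first.
* **Determinism.** Every fit is single-threaded and seeded; reports carry
  the seed and a configuration hash, and re-running a pipeline
  configuration reproduces byte-identical artifacts.
* **Indices.** Internally 1-based (R convention); the CSV interchange
  format uses 0-based atom indices with an `index_base` argument as the
  converter.

## Known limitations

Only aromatic C–H sites are modeled; aliphatic positions are out of scope.
Ring perception is topological, so exotic aromaticity (fused systems beyond
5/6-rings, charged rings) is not recognized. Structures are taken as given
— no conformer search — and all quantum-derived descriptors must be
supplied. The generator's linear mechanism is a deliberately simple
stand-in: conclusions about relative algorithm performance on real data
should rest on the real data, for which the pipeline accepts standard XYZ /
SDF structures and CSV descriptor tables. Secondary processes that enrich
one isomer after the selectivity-determining step (e.g. follow-up oxidation
of one product) are not modeled; observed ratios are taken as the ground
truth to learn.
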