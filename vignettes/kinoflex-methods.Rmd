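---
title: "Flexibility and activity in kinase ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexibility and activity in kinase ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinoflex)
```

# The scientific setting

Protein tyrosine kinases populate active and inactive conformations whose
hallmark is the geometry of the activation loop (A-loop), the segment that
begins at the DFG motif. A recurring observation in kinase dynamics is that
the active state is conformationally stricter — less flexible — than the
many ways of being inactive. `kinoflex` operationalises that observation as
a reproducible pipeline: per-residue fluctuation profiles, a one-rule
classifier on those profiles, pocket-network statistics, and
conformational clustering of the A-loop.

Real inputs to such an analysis are microsecond molecular-dynamics
trajectories, which can neither ship with a package nor be regenerated at
desk scale. The package therefore treats a synthetic-data generator as a
first-class module: every statistical claim the test suite makes is a claim
about data with *known* planted structure, and the pipeline is validated by
whether it recovers that structure.

# Fluctuation model and RMSF estimation

## The generator

`gen_trajectory()` draws every atom's coordinates i.i.d. per frame from an
isotropic Gaussian centred on the atom's mean position, with per-coordinate
standard deviation σ set per residue (in Å). This is the minimal
fluctuation model with a closed-form answer: the root-mean-square
fluctuation of an isotropic 3-D Gaussian atom is exactly σ√3. That closed
form is what makes the whole fluctuation stack testable — an estimator that
returns 0.866 Å on a σ = 0.5 Å trajectory is demonstrably measuring the
right thing.

What the generator deliberately does *not* model: bonded structure, excluded
volume, solvent, correlated collective motions, or anything resembling
force-field physics. Mean positions default to an ideal α-helical layout
(`helix_residues()`) purely so that rigid-body fitting is well conditioned
(never collinear). Consequently, passing tests show that the estimators are
correct on well-specified ensembles; they do not show that 500 ns is enough
sampling for a real kinase, nor that real RMSF profiles are Gaussian.

## The estimator

`compute_rmsf()` implements the conventional protocol:

1. discard an equilibration prefix — by default the first 500 ns when frame
   times exist (mirroring typical μs-scale practice), else the first 1/6 of
   frames;
2. superpose every retained frame onto the first retained frame over the
   selection (backbone = atoms named N, CA, C, O);
3. compute the mean structure, re-fit all frames onto it, and repeat this
   fit → mean refinement until the per-residue RMSF moves by less than
   `tol` (default 1e-8 Å, usually 2–3 passes);
4. per-atom RMSF about the converged mean; per-residue RMSF as the
   root-mean-square over the residue's selected atoms.

We iterate the refinement rather than stopping after one pass because the
fixed point, not the pass count, is the defensible convention: a single
pass leaves a residual drift of order 1e-6–1e-5 Å between successive means
on small systems, visible against the package's own 1e-6 Å fixed-point
check. Iteration makes the estimator insensitive to the arbitrary choice
of initial reference frame at negligible cost.

Superposition is the Kabsch algorithm via SVD with the determinant
correction, so reflections are never returned; masks with fewer than three
atoms or collinear geometry (second singular value ≤ 1e-8 of the first) are
rejected. All internal units are Å.

Two known biases are worth stating. Fitting 6 rigid-body degrees of freedom
to 3N coordinates deflates RMSF by a factor ≈ √(1 − 6/3N); at the 160 atoms
used in the closed-form checks this is ~0.6%, inside the 2% tolerance those
checks use. And per-residue aggregation is the RMS of atom RMSFs — the
alternative (fluctuation of the residue centroid) is systematically smaller
and is not what "backbone RMSF" conventionally means.

# The fluctuation panel and its planted signal

`gen_fluctuation_panel()` emulates the kinases × alignment-columns matrix
the classifier consumes. Defaults are the study conditions: 43 kinases
(19 active, 24 inactive — the class split is a package choice; a mild
inactive majority matches how curated kinase panels tend to lean), 223
columns, signal column 120 with class means 0.6 Å (active) and 1.3 Å
(inactive) at within-class sd 0.18 Å, background columns at 0.8 ± 0.25 Å,
and a two-column correlated block at ρ = 0.95 mimicking the residues
immediately downstream of the DFG motif, whose fluctuations track the
signal residue. All draws are truncated below at zero because an RMSF
cannot be negative; truncation uses the inverse-CDF so generation stays
exactly seed-deterministic.

The correlated block is built as ρ·z(signal) + √(1−ρ²)·ε on the
standardised scale and rescaled to the background spread. Two consequences
matter:

* a block column carries *almost* as much class information as the signal
  (effective separation ≈ 3.2 within-class sds against 3.9 for the signal),
  which is precisely what makes the ablation cascade interesting; and
* because Gini ties are broken toward the lowest column index, the block
  sits at indices *above* the signal column (121, 122 by default). With the
  block below the signal, any training split that both columns separate
  perfectly would be awarded to the backup column by the tie-break alone —
  an artifact of index order, not of information.

For the parameter-recovery experiments (`scripts/acceptance.R`) panels are
generated *without* the block: those runs measure whether the stump finds a
single planted residue, and a near-equipotent backup column would conflate
"missed the signal" with "chose the 95%-correlated twin". The ablation
experiments use the block deliberately.

# The one-rule classifier

`fit_stump()` searches every (column, threshold) pair exhaustively;
candidate thresholds are midpoints between consecutive distinct sorted
values, the criterion is weighted Gini impurity, and ties break to the
lowest column index, then the lowest threshold. Determinism here is not
cosmetic: the test suite requires exact agreement — including tie-breaks —
with a brute-force double-loop oracle on hundreds of random matrices.

The fitted rule predicts the majority class of the below-threshold side
(ties to "active") and the complementary class above. With the planted
direction (inactive = more flexible), recovered rules read "fluctuation
below t ⇒ active", and t lands between the class means.

`resampled_evaluation()` repeats a simple random train/validation split
(train size ⌊0.7·n⌋; with n = 43 that is 30/13 every repeat), fits on the
training rows and scores balanced accuracy — the mean of sensitivity and
specificity, insensitive to the class imbalance — on the validation rows.
Design choices:

* splits are simple random, not stratified; a draw leaving *either* side
  single-class is redrawn (bounded retries). The fit is undefined without
  both classes in training, and balanced accuracy is undefined without both
  classes in validation, so the redraw rule is the minimal one that keeps
  every repeat scoreable.
* the reported spread is the population standard deviation over repeats;
* repeat r uses RNG seed `seed + r`, so reports are reproducible and
  individual repeats can be replayed in isolation.

`ablation_cascade()` removes the modal (most frequently selected) column
after each evaluation round and refits. On panels with the correlated
block, the expected trace is: signal column first, then the two block
members in either order, and only then background columns, with accuracy
decaying toward chance once the informative group is exhausted — the
qualitative analogue of a DFG+3 → DFG+2 → DFG+1 cascade. Because the block
is only slightly less informative than the signal, roughly one panel in ten
genuinely prefers a block column in round one; the acceptance check is
calibrated at that measured boundary (≥90% of 20 panels strict pattern).

`lasso_select()` corroborates the stump with an L1-penalised logistic
regression (glmnet) on internally standardised columns, ranking nonzero
coefficients by magnitude. Logistic loss is the coherent Lasso variant for
a binary label; the penalty → 0 limit is pinned against an unpenalised
`glm()` fit in the tests.

# Pocket networks

`events_to_matrices()` counts ordered merge events into α and split events
into β exactly as recorded (the matrices may be asymmetric).
`connection_matrix()` computes

γ = ½·( (α + αᵀ)/2 + (β + βᵀ)/2 ),

which is symmetric with zero diagonal and conserves total events:
Σγ = (Σα + Σβ)/2. γ is left as raw counts by default; a `per_ns` argument
exists for comparing runs of different lengths.

`time_averaged_volumes()` averages per-frame volumes over *all* frames with
undetected frames counted as 0 Å³ — so a never-detected pocket has a
well-defined average of zero, and "absence" is data rather than a missing
value. `connection_distribution()` pools, per pocket and per activity
class, the off-diagonal entries of the pocket's γ row across systems
("each row corresponds to a single pocket"), and reduces each system's row
to its sum as the scalar connection statistic handed to group testing.
Systems missing a pocket contribute zero rows for it.

The pocket simulator draws per-frame presence as Bernoulli, volumes as
lognormal (median `volume_mu` in Å³, log-sd `volume_sigma`; strictly
positive and right-skewed, as pocket-volume histograms are), and merge and
split events as independent Poisson streams per ordered pocket pair. The
default panel is the seven-pocket TK set (ATP ≈ 550 Å³ median and always
present; six allosteric sites smaller and intermittent).

# Group statistics

`welch_t_test()` is the unequal-variances t-test with Welch–Satterthwaite
degrees of freedom and two-sided p-values; sample variances use n − 1.
Sidedness is a convention choice — two-sided matches how pocket-wise
p-values are customarily reported against a 0.05 threshold.
`compare_groups()` runs one test per (pocket, metric) cell, reports
untestable cells (a class entirely missing) explicitly rather than dropping
them, and applies no multiple-testing correction by default — pocket-wise
raw p-values are the reporting convention here; a Bonferroni switch exists.
The implementation is the closed formula, and `stats::t.test()` serves as
an independent oracle in the tests, together with a quadrature-based tail
probability.

# Conformational clustering

`pairwise_rmsd()` computes superposition RMSD between every frame pair over
the analysis selection. The fit uses the same segment as the distance by
default (`fit_on = "segment"`): fitting on the loop isolates loop
conformation from whole-domain motion, which is the point of clustering
A-loop geometries; `fit_on = "whole"` is available. RMSD after per-pair
superposition need not satisfy the triangle inequality, so only symmetry
and zero diagonal are asserted. Mass-weighting is not applied.

`k_medoids()` is the Voronoi-iteration variant: greedy farthest-point
initialisation from a seed-chosen first medoid (deterministic, and immune
to empty initial clusters), then alternating nearest-medoid assignment and
within-cluster medoid update until a fixed point. Both tie-breaks
(assignment toward the lower medoid frame index, update toward the lower
frame index) are pinned so runs are exactly reproducible. The objective —
the sum of distances to assigned medoids — is non-increasing per iteration,
and the per-iteration trace is kept so that property is checked on every
run rather than assumed. A full PAM swap search would give marginally
better optima at quadratic extra cost; the monotone Voronoi variant is the
documented and tested choice, with k = 10 as the conventional default for
A-loop ensembles.

`transition_graph()` counts consecutive-frame cluster changes as undirected
edge weights; edge weights plus persistences always sum to n − 1, and nodes
carry cluster cardinality and mean per-frame activity.

# Problem sizes and what the checks mean

The shipped experiments run at these sizes, chosen so that each statistical
check has clear resolution: 43 × 223 panels with 25–100 holdout repeats;
200 random matrices for exact oracle agreement; 100 panels for signal
recovery; 50 label shuffles for the permutation null (expected 50% ± a few
points); 20 panels for the ablation pattern; 10 000-frame trajectories for
the σ√3 check at 2%; 20 seeds for planted two-bundle k-medoids recovery;
and a full pipeline run executed twice to byte-identity for determinism.
Monte-Carlo rates quoted in the tests (e.g. type-I error within
[0.01, 0.10] at α = 0.05 over 100 nulls) are calibrated to these sizes.

# Known limitations

* The Gaussian trajectory model has no kinematics: superposition-related
  subtleties that arise from genuine collective motion (fit-set choice,
  reference drift) are exercised only weakly.
* The activity series consumed by `label_from_activity()` is an external
  classifier's output; the package never computes activity from structure.
* The 0.9 Å scale of the real-kinome threshold is not reproducible from
  synthetic data — recovered thresholds are meaningful relative to the
  planted class means, not in absolute terms.
* Alignment handling assumes the ungapped sequence length equals the
  residue-profile length per kinase; insertions relative to the structural
  model must be resolved upstream.
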