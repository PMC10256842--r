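---
title: "Methods: metabolomics-guided off-target discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomics-guided off-target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarescue)
```

`metarescue` implements a five-stage workflow for locating the metabolic
off-targets of a growth-inhibitory compound: differential metabolomics,
mechanism-of-action classification, constraint-based supplementation-rescue
analysis, structural candidate ranking, and validation-assay quantification.
This vignette records the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic study system can and
cannot show.

## Differential metabolomics

Treated-vs-control contrasts are summarized per metabolite and time point by
the log2 ratio of arithmetic replicate means (`log_fold_change()`) and a
one-sided Mann–Whitney rank test (`mann_whitney_one_sided()`). Choices worth
knowing:

* **Log base.** Fold differences are reported in log2 by default; the base
  is an argument because "log scale" conventions differ between groups.
* **Replicate aggregation.** The ratio uses arithmetic means of raw
  intensities, not means of logs; MS intensity summaries are conventionally
  taken on the raw scale before the ratio.
* **Pseudocount.** Default 0 with a hard error when a group mean is zero,
  rather than a silent fudge. When zeros are expected, half the smallest
  positive intensity is a sensible pseudocount.
* **Exact vs approximate test.** The one-sided p-value is computed by full
  enumeration of rank arrangements (midranks for ties) for pooled sizes up
  to 12, and by a tie-corrected normal approximation with continuity
  correction beyond that. The continuity correction is needed for the
  approximation to track the exact tail to within 0.02 at pooled size 12;
  its visible cost is that identical samples give p ≈ 0.5002 rather than
  exactly 0.5 on the approximate path.
* **Direction.** The tested direction ("accumulation" vs "depletion")
  defaults to the side of the observed median difference and is recorded per
  row, since a fixed convention would silently halve power for one sign.
  With 3-vs-3 replicates the smallest attainable exact one-sided p is 0.05
  (one arrangement in twenty); stars below that level require pooling
  across replicates or time points, which the package deliberately does not
  do implicitly.

## Mechanism-of-action classification

Profiles are per-drug log2 fold-change vectors over a shared metabolite
namespace, filtered to annotation score > 50 (high-confidence identities),
with zero-time rows excluded and replicates averaged per compound
(`filter_profiles()`).

The classifier (`train_mechanism_model()`) is a multinomial softmax
regression minimizing total cross-entropy plus an L2 penalty of strength
`lambda` (default 1.0, the conventional "default hyperparameter" strength)
on standardized features; intercepts are unpenalized. The optimizer is BFGS
with analytic gradients, relative tolerance 1e-6, at most 1000 iterations,
initialized at zero — so the fit is deterministic given the data, with no
random restarts. Feature standardization uses the training fold only; the
stored center/scale are applied to new profiles at prediction time.

Performance is estimated by leave-one-out cross-validation
(`evaluate_loocv()`); classes with one member are flagged untrainable in
their own fold rather than silently dropped. The *residual drug-specific
signature* (`residual_signature()`) removes a class signature by orthogonal
projection in the standardized feature space, `r = x − (⟨x,w⟩/⟨w,w⟩)w`,
which guarantees ⟨r, w⟩ = 0. Coefficient-wise subtraction of the weight
vector is the obvious alternative; projection was chosen because it is
scale-free in `w` and leaves exactly the component the class model cannot
explain.

For inspection, profiles are embedded in two dimensions (`embed_2d()`) and
clustered with DBSCAN (`dbscan_cluster()`, hand-implemented with standard
core-point/density-reachability semantics). The embedding algorithm is
pluggable behind a determinism contract; the default is classical
multidimensional scaling, which is deterministic by construction and
neighborhood-preserving at panel scale (a stochastic neighbor-embedding
method can be slotted in where available — the `n_neighbors = 14`,
`random_state = 42` interface parameters anticipate exactly that). DBSCAN's
`eps` and `min_samples` are exposed in the configuration (defaults 0.5 and
5); the number of clusters found is data-dependent and is never treated as
an invariant.

## Constraint-based supplementation-rescue analysis

The core computation asks: *which pathway inhibition, imposed on a metabolic
model, best reproduces the experimentally observed pattern of
growth-rescuing supplements?*

Flux balance analysis (`fba()`) maximizes biomass flux subject to
steady-state mass balance `S v = 0` and bounds. Among degenerate optima a
secondary LP minimizes total absolute flux (parsimonious FBA), giving a
unique reference flux distribution — needed because the "fraction of optimal
flux" caps below are defined against a reference that must not depend on
solver whims.

Inhibition scenarios (`inhibition_scenario()`):

* `pathway_fraction` — cap each target reaction's flux magnitude at
  `fraction` (default 0.9) of its parsimonious reference flux. A reference
  flux of zero gives a cap of zero (documented, not an error).
* `cofactor_drain` — add an enforced charged→discharged cofactor reaction
  (e.g. 5,10-methylene-THF → THF). The default drain magnitude is half the
  reference folate-charging flux: large enough to bind, small enough to stay
  feasible; it is a configuration knob, not a fitted quantity.
* `knockout` — constrain target reactions to zero flux.

Supplements (`supplement()`) open the metabolite's exchange lower bound to
−rate (uptake is negative by the usual exchange convention) at 0.1
mmol/gDW/hr by default. The growth benefit is
`Δμ = μ(inhibited + supplement) − μ(inhibited)`; since a supplement is a pure
bound relaxation it can never be negative beyond solver tolerance, and the
suite asserts this.

Wild-type expression corrections (`apply_expression_shutoff()`) evaluate
each reaction's boolean gene rule against a set of unexpressed genes and
close false reactions. The scope can be global or restricted to a
`k`-step neighborhood of the supplement metabolites — the neighborhood
option exists because in genome-scale models a global shutoff typically
abolishes growth outright; on the toy model the global scope is safe and is
the default in the pipeline. `close_spontaneous()` closes all
spontaneous-flagged reactions in one call.

Scenario ranking (`rank_scenarios()`) is the Pearson correlation between the
scenario's benefit vector and the experimental supplement growth rates,
with zero-variance benefit vectors ranked last and ties broken by scenario
id. Because correlation is scale-invariant, only the *pattern* of benefits
matters — which is also why the null comparison against all single-reaction
knockouts (`random_inhibition_null()`) is informative. Where a pathway
hypothesis comprises several constrained-reaction variants, their scores are
combined as the mean benefit per supplement across variants.

### The toy folate network

`make_toy_model()` builds the smallest network (~30 reactions, 30
metabolites) expressing the distinctions the analysis depends on: a single
carbon currency from glucose (uptake bounded at 10 mmol/gDW/hr, a realistic
glycolytic magnitude); a catalytic folate cycle charged only by the
serine→glycine reaction; pyrimidine synthesis through a folate-dependent
thymidylate step with thymidine salvage below it and uridine entry above
it; purine synthesis through a folate-dependent transformylase with IMP
salvage reaching both end products while AMP reaches the adenine pool only
through a spontaneous phosphorylation and the guanine pool only through a
gene-gated cryptic deaminase; a gene-gated citrate transporter; and a
unit-coefficient biomass reaction (only relative growth changes are
meaningful).

Two deliberate design choices:

* **Growth ceiling.** Biomass is capped at 0.99× the carbon-limited optimum,
  standing in for the non-carbon growth ceilings (proteome, ribosome
  capacity) a small carbon-only network lacks. This makes supplements
  worthless to unstressed cells — matching the experimental control
  observation that supplements alone do not change wild-type growth — and
  prevents trivial carbon-sparing benefits from confounding the
  scenario-vs-knockout comparison.
* **Unit biomass stoichiometry.** Precursor coefficients are 1; the workflow
  only ever interprets growth-rate *changes* and correlations, which are
  invariant to the absolute scale.

## Structural candidate ranking

Global similarity (`global_similarity_matrix()`) z-scores each structural
property across proteins and correlates the normalized per-protein vectors
(Pearson). Zero-variance properties are dropped with a warning. Pocket-level
similarity keeps the 5 largest binding pockets per protein
(`select_top_pockets()`, size ties broken by pocket id) and scores each
candidate by the Tanimoto coefficient between its pockets' interaction
fingerprints and the reference protein's (`rank_candidates()`). Pockets are
aggregated by the maximum pairwise coefficient — the most reference-like
cleft is what matters for a shared ligand — with the mean available by
argument. Fingerprint bits are treated as opaque indices; whole-structure
alignment p-values, if available from external tools, merge in as an
annotation column and never enter the score.

## Validation assays

* **Growth.** `fit_logistic_growth()` fits
  `OD(t) = K/(1 + exp(−r(t − t_m)))` by Levenberg–Marquardt least squares on
  a 30-minute grid over 15 h. The lag is reported by the tangent-intercept
  construction (tangent at the inflection, intersected with the fitted
  initial OD); a threshold-crossing alternative is an argument. Flat curves
  short-circuit to `r = 0` with the lag flagged undefined. The simulator
  places the inflection so the tangent-intercept lag equals the requested
  value anchored at the nominal initial OD; because the fitted lag re-anchors
  at the *fitted* curve's initial OD, noise-free lag recovery is exact only
  up to that anchoring (≈0.15 h on the default curve), whereas `r` and `K`
  recover exactly.
* **Dose-response.** `percent_activity()` linearly rescales ATP-proportional
  luminescence between the no-reaction control (activity 0%) and the
  zero-inhibitor control (100%); values are intentionally not clipped to
  [0, 100], since clipping would bias the fit. `fit_ic50()` fits a
  four-parameter logistic on percent activity with asymptotes bounded to
  [−10, 110]%. Starting values are deliberately perturbed away from any
  exact interpolant: on noise-free data a perfect start makes the initial
  Jacobian singular. The percent-activity formula is invariant to affine
  re-gaining of the luminometer, so gain drift between plates cancels.
* **Cheng–Prusoff.** `ki_cheng_prusoff()` converts IC50 to the competitive
  inhibition constant `Ki = IC50/(1 + [S]/Km)`; Ki is strictly below IC50
  and decreases with substrate concentration, the signature of competition.
* **Cell lengths.** `compare_cell_lengths()` reports medians, means, the
  10/25/75/90 percentile box summary and the shared one-sided rank test;
  lengths are floored at the imaging resolution limit in the generator
  (0.5 µm), which produces the tied minima real segmentations show.

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* the methods rely on:
shared metabolite namespaces with per-class log2 perturbation signatures,
multiplicative log-normal intensity noise (the standard assumption for MS
abundances; the true noise law of any given instrument is unknown and may be
heavier-tailed), replicates and time points, annotation-score mixtures,
logistic growth with additive OD noise, four-parameter-logistic
luminescence, log-normal cell lengths, and pocket fingerprints with planted
overlap. Passing tests therefore demonstrate that the *algorithms* are
correct and well-calibrated under these assumptions — not that any
particular real compound behaves this way. In particular, the toy metabolic
network is a caricature built to make the rescue distinctions structural;
genome-scale models add thousands of alternative pathways whose expression
state must be handled as a first-class input, and the neighborhood-scoped
shutoff exists for exactly that setting.

## Numerical choices

* LP solves use a dense two-phase primal simplex written for this package
  (the available general-purpose R solvers proved numerically unreliable on
  degenerate flux LPs of even this size): Dantzig pricing with a switch to
  Bland's rule under suspected cycling, pivot tolerance 1e-9, artificial
  variables driven out of the basis after phase 1. Solutions satisfy mass
  balance to 1e-9 and agree with an independent interior-point solve to
  better than 1e-8 on every tested instance.
* Softmax fitting: BFGS, zero initialization, reltol 1e-6, max 1000
  iterations; non-convergence warns with the iteration cap rather than
  failing.
* Deterministic tie-breaks everywhere a ranking is emitted: metabolite id in
  feature importance, pocket id in top-k selection, protein id in candidate
  ranking, scenario id in scenario ranking.
* Degenerate inputs have defined behaviour: flat growth curves (r = 0, lag
  NA), zero-variance profiles (NA correlations, named warning), zero
  reference fluxes (cap 0), infeasible inhibited models (benefit NA,
  flagged), empty bit sets (error for 0/0, score 0 against non-empty).
* All randomness flows through per-call seeds (`withr::with_seed`), so no
  generator disturbs the caller's RNG stream, and the pipeline derives each
  stage's stream from one master seed recorded in the report.

## Known limitations

* The toy network's benefit magnitudes (order 0.01–0.1 1/hr) are not
  calibrated to any organism; only their pattern across supplements is
  meaningful.
* The classifier assumes class signatures are linear in log fold-change
  space; strongly non-additive drug responses would need a richer model.
* MDS preserves global geometry rather than local neighborhoods; for very
  large panels a dedicated neighbor-embedding backend should be plugged into
  `embed_2d()`.
* The rank-sum evidence combination in the pipeline weights pocket
  similarity and pathway membership equally; it is a reporting convention,
  pluggable by design, not an inference.
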