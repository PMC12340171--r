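---
title: "Modeling inborn errors of cobalamin metabolism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling inborn errors of cobalamin metabolism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cblflux` studies how defects in cobalamin (vitamin B12) absorption,
transport, processing and utilization reshape the space of feasible
metabolic fluxes, and how transcriptomes of individual patients further
personalize that space. This vignette explains the models, the parameters
that matter, the synthetic data, and the design decisions — including what
the passing test suite does and does not demonstrate about real data.

## The constraint-based model

All analyses operate on a stoichiometric network at steady state: a flux
vector $v$ must satisfy $S v = 0$ with $lb \le v \le ub$, where $S$ is the
metabolite-by-reaction stoichiometry. Flux balance analysis (FBA) maximizes
one reaction (here the biomass pseudo-reaction) over that polytope; flux
variability analysis (FVA) reports, per reaction, the minimal and maximal
flux subject to the biomass flux staying at or above a *fraction of its
optimum*. The fraction defaults to **0.99** everywhere, and the constraint
is imposed as an added matrix row (`objective − slack = 0`, slack bounded in
`[0.99·opt, opt]`), which stays exact even if the objective reaction carries
a nonzero lower bound. Steady-state modeling predicts flux *capabilities*,
not concentrations or kinetics; a "blocked" reaction means no steady-state
flux is possible, and a "reduced span" means reduced capability, not a
measured rate.

Gene deletions act through gene-protein-reaction (GPR) rules — boolean
AND/OR expressions over gene identifiers. A knockout closes (bounds
`(0,0)`) every reaction whose rule evaluates false; reactions without gene
association are never disabled. Keywords are case-insensitive, gene
identifiers case-sensitive.

## The toy fibroblast network and its cobalamin pathway

The fixture model is a hand-curated miniature of fibroblast central
metabolism (132 reactions, 105 metabolites, 60 genes): a lumped glycolysis,
a TCA segment around succinyl-CoA, valine/isoleucine catabolism into
propionyl-CoA and methylmalonyl-CoA, methionine and folate cycles, a heme
branch fed by succinyl-CoA and glycine, ketone-body and carnitine handling
that consume succinyl-CoA, and a biomass reaction consuming ATP, amino
acids, one-carbon units and a methylation demand. It is *not* a reduction
of a genome-scale reconstruction; structural counts and pathway topology
are the things it shares with the full-scale setting, not stoichiometric
identity. Currency metabolites (ATP/ADP, NAD(P)H, protons, water, gases,
phosphate, CoA) live in one pool to keep the network small; pathway
intermediates keep their compartment. Metabolites carry neutral-form
formulas so the validator can check elemental balance of every internal
reaction; heterogeneous pools (protein-bound cobalamin, the degraded
cobalamin pool) deliberately carry no formula and are skipped.

The cobalamin extension adds exactly 24 reactions, 10 metabolites and 7
genes on top of the base network (the other four disease genes — *MMUT*,
*MTR*, *MTRR*, *MMAA* — are base genes whose reactions become functional
only with the extension). Two design points deserve emphasis:

- **Cofactor loss forces uptake.** In steady-state FBA a catalytic cofactor
  that is only interconverted can be recycled for free in a closed loop, so
  nothing would force the absorption chain to run. The two
  cofactor-explicit catalytic reactions therefore lose a small
  stoichiometric fraction (0.01 per turnover) of their cobalamin into a
  dead-end degraded pool with a sink. This makes methionine-synthase and
  mutase activity require continuous flux through
  TCN2 → CD320 → LMBRD1/ABCD4 → MMACHC, so every transport knockout and
  the deficiency scenario block both cobalamin-dependent enzymes.
- **No cobalamin-conserving cycles.** The extension contains no directed
  cycle that returns a cobalamin species to an upstream compartment;
  otherwise the deficiency scenario (closed uptake, intact genes) could
  keep "transport" reactions spinning on a conserved internal pool and the
  deficiency would no longer have the broadest affected set.

Capacities were chosen once, as study conditions: the medium is a DMEM-like
uptake table (glucose 300, valine/isoleucine 30, serine 60, glycine 80,
methionine 4, cysteine 5, folate 2, iron 10, acetoacetate 40, carnitine 40,
adenosine 5, hydroxocobalamin 10 flux units), methionine deliberately below
remethylation capacity so the methionine cycle matters in the wild type;
the TCA-derived succinyl-CoA supply is capped (2-oxoglutarate dehydrogenase
ub 5) so the propionate pathway carries a large share of succinyl-CoA
production and mutase-side knockouts visibly starve the heme branch; and
2-oxobutanoate dehydrogenase is capped (ub 2) so transsulfuration cannot
couple remethylation knockouts into the propionate pathway above the 5%
affected threshold. Biomass does not require heme, and amino acid uptake
covers biomass needs, so all battery knockouts remain viable — knockouts
reshape flux spans rather than abolish growth, and the 99%-of-optimum
anchor is comparable across scenarios.

## Affected fluxes and scenario clustering

A reaction is *affected* by a scenario when its minimal or maximal flux
moved by at least a threshold times the wild-type span scale
(`max(|min_wt|, |max_wt|, 10^-6)`). The default threshold is **0.10**; the
more sensitive **0.05** reporting style is written alongside by the
pipeline, and both are exposed as a parameter. Displayed *fractions of wild
type* are the scenario/wild-type ratio on the bound of larger wild-type
magnitude; wild-type-zero bounds use an absolute floor of `10^-6`.

Scenarios are clustered with Euclidean distance and complete linkage; flat
clusters come from cutting at the largest gap between consecutive merge
heights, with ties broken deterministically. The feature matrix contains
the *flux-span deviations from wild type in flux units* (minimum and
maximum columns concatenated, over all reactions affected in at least one
scenario). Flux units — rather than per-reaction ratios — weight each
reaction by the amount of flux it loses. This is a deliberate choice: with
unit-weighted ratios, scenarios that silence the same central pathways can
be pushed apart by differences on low-flux bookkeeping reactions (drains,
transport variants), and the largest-gap cut then cannot separate the
biologically meaningful groups. With flux-unit features the within-cluster
merge heights and the between-cluster heights differ by roughly an order of
magnitude, so the automatic cut is robust.

## Transcriptome personalization

The per-sample pipeline is: RPKM → TPM (`TPM_i = RPKM_i / Σ RPKM · 10^6`);
gene-symbol mapping onto model genes (identity for the synthetic cohort;
collisions summed, unmapped genes dropped with a count); cohort-level
active-gene calling; reaction scoring; context extraction; biomass
gap-filling; eFlux.

**Active-gene calling** fits a two-component Gaussian mixture to the pooled
`log2(TPM+1)` of the whole cohort (one fit, reused for every sample).
Values with posterior ≥ **0.9** for the expressed component are *active*,
≤ 0.1 *inactive*, in between *unknown* — unknown genes are neither forced
into the extraction core nor forbidden. A degenerate fit (modes closer than
two pooled standard deviations) falls back to a percentile threshold with a
message. Reaction scoring maps gene statuses through the GPR with AND → min
and OR → max over `active > unknown > inactive`; gene-free reactions are
unknown.

**Context extraction** removes inactive reactions, reduces to the
flux-consistent sub-network (a reaction is consistent when it can carry
`|v| ≥ ε` with ε = **10^-4**), reports — rather than silently keeps — core
reactions that became inconsistent, and then extracts a sub-network
containing every remaining core reaction plus a near-minimal support set,
by the classic alternating scheme: one LP maximizes the number of core
reactions carrying at least ε, a second minimizes the L1 flux through
non-core reactions, with bound flipping for reversible core reactions. The
biomass objective is always included in the core. In mut0 samples this is
what removes the mutase reaction: *MMUT* is called inactive, the reaction
is dropped before extraction, and the stranded epimerase is reported as
inconsistent core.

**Gap-filling** tests whether the context supports biomass at ε and, if
not, adds a near-minimal set of reactions (L1-sparse LP followed by a
deterministic greedy prune). Candidates come from the *full* parent model,
not the inactive-reduced one: an expression outlier on an essential gene
(for example a folate enzyme) must not leave a sample without a viable
model — restoring biomass may override an inactive call, which is recorded
in the provenance. Because biomass never requires the mutase, gap-filling
never reintroduces it into mut0 contexts.

**eFlux** rescales the bounds of internal reactions by relative expression:
the reaction score maps expression through the GPR with AND → min (limiting
subunit) and OR → *sum* (isozymes add capacity — a quantitative convention,
intentionally different from the qualitative OR → max used in activity
calling); the score is normalized by the sample's maximum reaction score,
and bounds become `(-cap·ρ, +cap·ρ)` with cap = **1000**, intersected with
the original reversibility (irreversible reactions keep a zero lower
bound). Gene-free internal reactions get the full cap. Exchange and sink
bounds — the medium — are preserved: rescaling them would erase the uptake
environment the flux analysis is supposed to run in. eFlux is applied after
gap-filling (to the final network); applying it before would make support
search depend on the bounds it is about to overwrite.

## The synthetic cohort

The generator emits RPKM over the fixture-model genes with per-gene
baseline means at an unexpressed mode (log2 ≈ 1) or expressed mode
(log2 ≈ 8, between-gene spread 0.5) and per-sample log-normal noise
(σ = 1 on the log2 scale) — parameters chosen so the two expression
populations are unambiguous for the mixture caller. Default group sizes
mirror the emulated study design: 19 controls, 72 mut0, 71 mut−, 59
other-MMA (221 samples). Planted effects: mut0 samples have *MMUT* at the
unexpressed mode; mut− samples at **0.25×** the control mean — a value
chosen so eFlux yields reduced-but-nonzero mutase bounds (partial enzyme
activity), as no molecular quantity is available to calibrate against;
other-MMA samples have normal *MMUT* but a reduced alternative causal gene
(default *SUCLA2*, succinyl-CoA ligase). Nine symptom/treatment flags are
drawn per patient as independent Bernoulli variables (failure to thrive
0.40, reduced consciousness 0.26, muscle hypotonia 0.21, all others 0.20 —
the three named prevalences follow reported meta-analysis figures, the rest
are a round default); failure to thrive additionally scales twelve
energy-pathway genes by 0.7, acting on expression, upstream of the whole
pipeline, so recovering it exercises the entire inference chain. A
`plant_effects = FALSE` design yields null cohorts for type-I calibration.

What passing tests on this cohort show: the pipeline recovers planted
expression differences as flux differences with correct direction and
calibrated false-positive behaviour *under the generator's assumptions*
(clean bimodality, independent genes, no library-size or GC artefacts, no
covariates). Real RNA-seq violates all of these to some degree; the tests
validate the machinery, not clinical performance.

## Statistics

Group comparisons use two-sided Wilcoxon rank-sum tests per retained
feature (`min|reaction`, `max|reaction`, or `production|metabolite` rows;
a feature is retained when nonzero in at least one model, with a `10^-9`
zero snap). The exact distribution is used when the smaller group has at
most eight observations and the data are tie-free; otherwise the normal
approximation with tie and continuity correction. Features constant across
the union of compared samples are excluded before correction and do not
count toward the number of tests. FDR control defaults to
Benjamini–Hochberg for determinism at this feature count; a Storey-style
variant (π₀ by spline smoothing) is available but unstable on small
feature sets. Significance defaults to q < 0.05. Symptom associations run
within a stratum (mut-type or other-MMA), comparing carriers to
non-carriers per symptom with at least **8** carriers; symptom absence
means absent *or not reported*. Symptom information never modifies the
models.

## Numerical design

The LP engine is a dense bounded-variable two-phase primal simplex
(compiled), appropriate because every problem here has tens of rows and a
few hundred columns. Determinism and robustness choices: Dantzig pricing
with an automatic switch to Bland's rule on stalling; artificial variables
can never re-enter the basis; a two-pass ratio test takes the shortest step
and then the largest pivot magnitude among near-ties; the tableau is
refactorized from the basis every 100 pivots; and every reported optimum is
verified against the original constraints (residual and bound check at
`10^-6`), with a from-scratch Bland restart on failure. Warm-started sweeps
(FVA, consistency testing) re-optimize from the previous basis, and fall
back to verified cold solves when a warm step degrades. Tolerances:
steady-state residual and zero-flux threshold `10^-9`, consistency ε
`10^-4`, verification `10^-6`. Repeated runs are bit-reproducible.

Problem sizes in the shipped tests were chosen to exercise every code path
at desk scale: random oracle networks have at most 25 reactions, recovery
runs use the control and mut0 arms of the default cohort across 20 seeds,
and calibration pools several hundred features from three null cohorts.

## Known limitations

- The fixture is a didactic miniature; absolute fluxes, affected-reaction
  counts and cluster *contents* are properties of this network, not
  predictions for genome-scale reconstructions.
- Steady-state FVA describes capability envelopes; two scenarios with equal
  spans can differ in realized fluxes.
- The cofactor-loss coefficient (0.01 per catalytic turnover) is a modeling
  device for steady-state cofactor dependence, not a measured turnover
  number.
- The mixture caller assumes a shared expression scale across samples
  (TPM); strong sample-specific distributional shifts would bias calls.
- No covariate adjustment (age, sex) is performed in the statistics.
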