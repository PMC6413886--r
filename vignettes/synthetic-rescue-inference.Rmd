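---
title: "Inferring synthetic-rescue interactions: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring synthetic-rescue interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A tumor that loses the activity of a *vulnerable* gene V should lose
fitness — unless a *rescuer* gene R changes activity in a direction that
compensates. Such **synthetic rescues** (SR) are a principal route to drug
resistance: a drug that inhibits V selects precisely for tumor cells in
which R is already, or becomes, rescuing. `synrescue` infers V→R rescue
pairs of two types — **DU** (rescue by up-regulation of R after
down-regulation of V) and **DD** (rescue by co-down-regulation) — from
four independent lines of statistical evidence, applied as sequential
filters so that the expensive tests only run on survivors.

## The four screens

### 1. Conditional essentiality in cell-line panels

If R rescues the loss of V, then in a panel of cell lines the knockdown
of V should be better tolerated where R is high. With `y` the
(growth-convention) fitness readout of the V knockdown and `g` the
molecular level of R, we fit

\[ y \sim g + (1\,|\,\text{cancer type}) \]

with cancer type as a random intercept, because baseline essentiality
differs systematically by lineage and would otherwise confound the slope.
Both `y` and `g` are inverse-normal transformed (Blom scores), making the
slope comparable across genes and robust to heavy tails. The fixed-effect
p-value is a 1-df likelihood-ratio test against the
intercept-plus-random-effect null; both models are fitted by maximum
likelihood, since REML likelihoods of models differing in fixed effects
are not comparable. With a single lineage the model degrades to ordinary
least squares. Two conditions are required, each sign-gated: (i) V-knockdown
fitness **rises** with R's level, and (ii) R-knockdown fitness **falls** as
V's level falls. For DD pairs, condition (i)'s sign flips, and the second
condition is a one-sided Wilcoxon comparing V-knockdown fitness between
R-low and R-high cell-line tertiles, because a linear slope is not the
natural statistic for a rescue that acts through co-inactivation.
Condition p-values are combined across panels with Fisher's method and
Benjamini–Hochberg corrected across pairs per modality; a pair passes at
FDR < 0.2 in expression **or** copy number — the lenient OR reflects that
panels often lack one modality for many genes, and the later screens are
strict.

Because the bulk screen fits tens of thousands of structurally identical
mixed models, the package includes a profiled-likelihood solver
specialized to the single-random-intercept case: for a fixed variance
ratio the GLS estimate is closed-form from group-wise sufficient
statistics, leaving a one-dimensional optimization. It reproduces
`lme4::lmer(REML = FALSE)` deviances and slopes to optimizer precision
(asserted in the test suite against lme4 directly), at roughly 1/50 of
the cost. `fit_conditional_essentiality(engine = "lme4")` calls lme4.

### 2. Molecular survival of the fittest

Positive selection leaves a census signature: among tumors with V
underactive, those with R in its rescuing state should be
over-represented. Activity states are per-cancer-type tertiles — a gene is
underactive (−1) below the type's 33rd percentile, overactive (+1) above
the 67th (linear-interpolation quantiles, strict inequalities, ties and
missing values falling to "normal"). The *rescued* and *non-rescued*
joint states are then tested with one-tailed hypergeometric tests
(enrichment of rescued, depletion of non-rescued), pooling cancer types
into one cohort-level table after the per-type state calls. The four test
families (2 states × 2 modalities) are BH-corrected separately and a pair
needs all four at FDR < 0.05 — here the strict AND is affordable because
tumor cohorts carry both modalities for essentially all genes.

### 3. Clinical survival

A rescue that matters clinically must show in patients: rescued-state
tumors should carry *worse* survival, non-rescued-state tumors *better*.
For each pair-state indicator \(I\) we fit the stratified Cox model

\[ h_g(t) = h_{0g}(t)\,
   \exp(\beta_1 I + \beta_2 g(V) + \beta_3 g(R) + \beta_4\,\text{age} +
        \beta_5\,\text{GII} + \beta_6\,\text{TP}) \]

with one baseline hazard per stratum of the full cancer type × race × sex
cross, Efron tie handling, and all continuous covariates inverse-normal
transformed (the indicator stays binary: normalizing a 0/1 variable would
destroy its interpretation). GII is the genomic instability index — the
fraction of genes with |SCNA log-ratio| strictly above 1 — and TP the
tumor purity; additional purity estimates can be added as covariates via
`add_purity_controls()`. Significance of \(\beta_1\) is a 1-df
likelihood-ratio test against the model without \(I\); a Wald p-value is
reported alongside. Strata with fewer than 10 events are pooled so their
baselines remain identifiable; non-converged fits count as non-significant
rather than being dropped, keeping FDR denominators stable. A pair passes
when the rescued indicator has \(\beta_1 > 0\) and the non-rescued
indicator \(\beta_1 < 0\), both at BH FDR < 0.05, in both modalities.

### 4. Phylogenetic similarity

Functionally coupled genes co-evolve. The genes × species conservation
matrix is factorized by non-negative matrix factorization (multiplicative
Frobenius updates, rank 20 by default, 500 iterations, relative tolerance
1e-6, seeded initialization; no NMF implementation is assumed from other
packages) and each gene is represented by its L2-normalized membership
row. A candidate pair passes if the Euclidean distance between its two
membership rows falls below the empirical 5% quantile of distances among
10,000 random gene pairs drawn from the same universe.

Two phrasings of this screen circulate — "top 5% most similar among the
candidates" and "empirically significant against a random background" —
and they disagree whenever the candidate list is small and already
enriched for genuinely co-evolving pairs: a hard top-fraction cap would
then discard pairs that are unambiguously similar by the genome-wide
background standard (and a cap of ⌈5%⌉ of, say, 25 survivors would keep
2). The background criterion is therefore the default gate, and the cap
is available as `cap_fraction` for users who want the stricter
conjunction. With fewer than 20 candidates the screen passes through with
a warning rather than estimate a quantile from almost nothing.

## Scores and downstream analyses

Within each screen, the representative p-value of a pair is the **worst**
of that screen's required sub-tests (the gate is a conjunction), and these
are rank-normalized to [0, 1] across all pairs tested (0 = most
significant). The **interaction score** is the plain sum over the four
screens, on [0, 4], lower = stronger. Pairs eliminated before a screen
carry that screen's worst rank (1) in the audit table so scores remain
comparable along the funnel; network edges proper were tested by every
screen. In ICB mode (immune-checkpoint vulnerable genes) the in-vitro
screen is omitted — cell-line panels lack the immune context — and the
three-screen sum is rescaled by 4/3 to stay on the same scale.

Downstream, `drug_sr_score()` computes the per-patient fraction *C* of a
drug's targets' rescuers that are upregulated (tertile state +1 in mRNA
or SCNA; the OR is chosen for sensitivity and can be restricted to
mRNA-only), `survival_association()` relates *C* to treated patients'
survival with the stratified Cox model (covariates *C*, age, GII),
`recist_compare()`/`unsupervised_auc()` compare *C* between RECIST
responders and non-responders, and `synergy_call()` scores the sparse
1×5 combination design under Bliss independence:
Ratio(X) = combo/primary, Ratio(Y) = single/untreated,
Synergism = Ratio(Y)/Ratio(X), median over the 10 dose-replicate points,
rank-sum test of Ratio(Y) vs Ratio(X), BH across grids, synergy at
> 1.25 and antagonism at < 0.75 with FDR < 0.05. The untreated and
primary-alone denominators use the mean of their replicates; a zero combo
count would make a point infinite and is capped (default 100) and
flagged.

## The synthetic-data generators

Every screen is exercised end-to-end on generated data with planted
truth; all generators are pure functions of their parameters and a seed.

**Cohorts.** Expression is per-cancer-type location-shifted Gaussian;
copy number shares a latent factor with expression (correlation 0.5,
scale 0.7 so that GII lands in a realistic 0.1–0.25 band). For planted
pairs, per-sample joint activity states are drawn from a 3×3 table with
uniform tertile marginals and the rescued cell inflated by the planted
factor (feasible up to 3, where the rescued state fills the entire
vulnerable-underactive row; the generator errors beyond), then values are
sampled from the matching tertile in both modalities — this realizes the
enrichment exactly in mRNA and SCNA simultaneously, which post-hoc
resampling of generated matrices cannot guarantee. Survival is
exponential per cancer-type stratum with the log hazard shifted +β1 per
rescued and −β1 per non-rescued pair state and ~30% independent
censoring; the default β1 is 0.7, a hazard ratio of two, typical of
strong clinical prognostic factors. Both survival directions are planted
because the clinical screen gates on both; planting only the harmful
direction would leave the protective contrast near −0.2 and make the
non-rescued gate untestable at any cohort size a desk run can afford.

Two multi-pair subtleties deserve honesty. First, the planted pairs'
states are coupled through a shared per-sample "selection pressure"
latent (high-pressure samples sit in the rescued state of every planted
pair). With thirty pairs planted independently in one cohort, the other
pairs act as an unobserved frailty of variance ≈ β1²·29·0.32 on each
pair's fit, and because Cox effects are non-collapsible this caps every
pair's *observable* hazard contrast near half the planted value no matter
the coefficient — the planted condition would be unrealizable. Coupling
removes the cross-pair frailty while leaving each pair's own joint-state
table, both marginals, and all value-level noise untouched. Second, even
then the conditional and marginal coefficients differ, so the generator
calibrates the shared coefficient by an internal root-find (on its own
draws, seeded) until a reference pair's marginal rescued-state log hazard
ratio equals β1. What is planted is thereby exactly what the screen is
supposed to measure. The cost of the coupling is realism: in real tumors
rescue states of different pairs are only weakly correlated, and decoy
pairs that combine genes from two different planted pairs inherit
planted-like census and survival signals. Such decoys are blocked by the
in-vitro screen (panel readouts are planted per pair, not per latent) and
by the phylogenetic screen (only true pairs share profiles), which the
end-to-end false-edge count verifies — but recovery fractions on this
fixture overstate what correlated real cohorts would give.

**Panels.** Every gene gets a knockdown readout per cell line: a
cancer-type random intercept (SD 0.5) plus unit noise; planted pairs add
±1 SD per standardized unit of the partner's expression, the spec of a
strong conditional dependency. **Profiles.** A 10-block non-negative
model over 87 species; a planted rescuer copies its partner's profile
with 5% relative noise. **Dose grids.** Counts are Bliss-independent
expectations divided by the planted synergy level under 5% multiplicative
lognormal noise, in the 1×5 design (one primary dose × five inhibitor
doses × two replicates, plus five replicates of the single-agent
references).

The default bundle — 1,000 samples, 500 genes, 3 cancer types, 100 cell
lines, 20 DU + 10 DD planted pairs, 5,000 candidate pairs — runs through
the full pipeline in about a minute on one CPU; the problem sizes used in
the tests (and the 400-sample bundle shared by the unit tests) were
chosen so the whole suite stays comfortably within a coffee break while
still giving every calibration check ≥ 500 replicates.

## Numerical choices and degenerate inputs

* Quantiles are type-7 (linear interpolation); both activity thresholds
  are strict, so boundary-equal values are "normal". Constant genes and
  cancer types below 10 samples are all-normal.
* The inverse-normal transform uses the Blom offset
  \(\Phi^{-1}((r - 3/8)/(n + 1/4))\) with average ranks on ties; it
  errors on all-equal input rather than invent an ordering.
* GII uses the strict indicator |s| > 1.
* Fisher combination clamps non-positive p-values at 1e-300 with a
  warning.
* `hypergeom_tail` validates `0 ≤ k ≤ min(n1, n2) ≤ N` and errors
  otherwise; degenerate SoF marginals give p = 1 with a flag.
* Degree-preserving shuffles reject permutations that recreate an
  original edge or a self-pair, up to 1,000 retries.
* Random-control networks relabel genes injectively into the universe,
  preserving the degree sequence exactly.

## Known limitations

* The generators do not mimic batch effects, platform noise, gene–gene
  co-expression beyond the planted structure, or SCNA spatial
  correlation along chromosomes; passing tests show the screens behave
  correctly under their stated assumptions, not that those assumptions
  hold in any particular cohort.
* Genome-wide runs (hundreds of millions of pairs) are cluster-scale by
  nature; this implementation targets the desk-scale regime of explicit
  candidate lists.
* UD/UU rescue types are not implemented; the state logic only covers
  DU and DD.
* Drug readouts are mapped to targets by a user-supplied table; no
  attempt is made to model polypharmacology beyond fanning a drug's
  readout out to each of its non-agonist targets.
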