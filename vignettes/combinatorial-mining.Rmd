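---
title: "Combinatorial disease-signature mining: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial disease-signature mining: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

combsig implements a combinatorial case–control analysis for genotype
data: instead of testing SNPs one at a time, it searches for
*disease signatures* — combinations of up to five SNP genotype states that
are jointly over-represented in cases — validates them against a
label-permutation null, aggregates them into *critical SNPs* and patient
*communities*, and maps the SNPs to genes by a positional cascade. This
vignette explains the underlying models, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The statistical model

A *feature state* is a pair (SNP, ordinal genotype), with genotypes coded
0/1/2 = copies of the minor allele. A sample *carries* a signature iff its
genotype equals the required state at every member SNP; a missing genotype
at a member SNP makes the sample a non-carrier (the conservative default;
`evaluate_combination(..., missing = "exclude")` drops such samples
instead). Every signature is summarized by the 2×2 carrier-by-status
table, its cross-product odds ratio (Haldane–Anscombe corrected only when
a cell is zero) and a two-sided exact Fisher p-value.

### Mining

`mine_signatures()` searches the space of state combinations in two modes.

* **Exhaustive** enumerates all combinations up to `max_order`, with
  depth-first pruning on the case-prevalence floor (carrier sets only
  shrink as states are added, so a subtree below the floor can be skipped
  exactly). A budget guard (default 2·10⁶ evaluations) refuses runs that
  would not finish interactively; order-3 panels up to roughly 40 SNPs fit
  in the default budget.
* **Greedy stochastic** (the default) seeds up to `n_random_starts` starts
  from singleton and pair states passing the filters — best-scoring first,
  the remainder sampled under the seed — and extends each start by the
  single state that most improves the search score, stopping when no
  extension improves it or `max_order` is reached. All starts advance in
  lock-step, so each extension round costs one matrix cross-product
  regardless of the number of starts. By default every combination
  *visited* along a path is reported (`report = "all_layers"`), mirroring
  a layer-wise search over singletons, pairs, triplets, …;
  `report = "maximal"` keeps only the endpoints.

The greedy search score is the one-sided hypergeometric enrichment tail
(−log₁₀ p), chosen because it is exactly vectorizable over all candidate
extensions; reported signatures are always re-tested with the two-sided
exact Fisher p. The score is pluggable (`score = "fisher"` or any
function of the four table cells). Only case-enriched combinations
(OR > 1) are reported by default; `direction = "protective"` flips this.

Reported signatures satisfy `p_value <= p_max` (default 0.05),
`case_prevalence >= min_case_prevalence` (default 0.05) and the order
bounds `min_order:max_order` (defaults 1:5). `min_order = 3` restricts
output to the high-order regime in which purely combinatorial signal
lives; single SNPs and pairs are then still used as search starts but not
reported.

### Permutation validation and the P1000 score

The strength filters alone admit large numbers of chance combinations, so
validation is by permutation of the case/control labels
(`compute_p1000()`): the mining procedure is re-run, with identical
parameters, on `n_perm` label-shuffled copies of the cohort (case:control
counts preserved exactly). A signature scores a *hit* in a permutation iff
the permuted result set contains **any** combination with odds ratio ≥ the
signature's observed odds ratio **and** case-carrier count ≥ its observed
case-carrier count. The hit count is the P1000 score (named for the
conventional 1000 cycles). This any-combination rule makes the null the
distribution of the *maximum* of the whole search procedure, which is what
controls selection bias: a chance combination that looks strong only
because the search maximized over many candidates is matched by equally
strong maxima in the permuted searches and scores a high P1000. (The
alternative rule — requiring the *same* combination to recur — would give
selection-biased noise a near-zero P1000 and destroy the negative-control
behaviour; it was analyzed and rejected.)

Empirical p-values use the add-one correction, `(P1000 + 1)/(n_perm + 1)`,
and `validate_signatures()` applies Benjamini–Hochberg FDR (default 0.05)
across all mined signatures plus the case-prevalence floor. Signatures
with `P1000/n_perm` below 5% are additionally flagged.

**How many permutations are enough?** BH can only reject when the smallest
empirical p-value, `1/(n_perm + 1)`, is below `alpha * k / M`, where `M`
is the number of mined signatures and `k` the number of genuinely
non-random ones. The permutation count therefore has to satisfy
`n_perm ≳ M / (alpha * k)`. At the conventional `n_perm = 1000` and FDR
0.05 this holds for any realistic `M` once two signatures sit at the
floor; scaled-down runs must respect the bound — the package's test
experiments use 300–600 permutations with mined sets of 25–60
combinations for exactly this reason, and the pipeline default is 500.

### Evaluation, architecture, annotation, stratification

*Critical SNPs* are SNPs appearing in at least `critical_min` (default 2)
validated signatures. They are scored by a random forest (500 trees,
√-features per split) on the critical-SNP genotype columns under
stratified five-fold cross-validation; the per-SNP score is the
fold-normalized mean decrease in Gini impurity, and accuracy is pooled
out-of-fold. Gene priorities are plain cumulative sums of the scores of
the SNPs assigned to each gene; a SNP assigned to several genes
contributes its full score to each.

The *disease architecture* is the graph whose nodes are the feature
states of validated signatures; every signature induces a clique, and
edges are weighted by the Jaccard similarity of the states' case sets (a
state's case set is the union over validated signatures containing it).
Communities are found by seeded Louvain modularity maximization at
resolution 1 (connected components are available as a method), with
labels canonicalized by descending community case count so the partition
is independent of node insertion order. A signature is assigned to the
community holding most of its states, each state's vote weighted by the
number of validated signatures containing it — a signature follows its
canonical states, not its private noise states. Community statistics
(odds ratio, Fisher p, cases represented) treat a sample as a community
carrier iff it carries at least one member signature. Pairwise community
overlap is `|A ∩ B| / min(|A|, |B|)` (the smaller community as
denominator; Jaccard available), a deliberate convention documented with
its nested-set consequence: a community nested in another has overlap 1.

SNP-to-gene annotation is a positional cascade: (1) SNPs inside a coding
interval are assigned to the gene(s) directly; (2) otherwise the
strand-aware window [body − 2 kb upstream, body + 0.5 kb downstream]
(mirrored on the − strand) is searched and the closest gene(s) assigned,
ties included; (3) otherwise the SNP is unassigned. Windows anchor on the
gene body by default (`anchor = "tss"` is available); boundaries are
inclusive; BED input is converted from 0-based half-open to the internal
1-based closed convention at the boundary.

Patient stratification compares a subgroup of cases against the remaining
cases: pooled two-proportion z-tests for categorical features,
Mann–Whitney U (exact below n = 8 per group without ties, tie-corrected
normal otherwise) for continuous ones, BH across the features tested, and
missing values excluded pairwise. Cohort-level forest data use percentile
bootstrap CIs (default 1000 iterations). The single-SNP baseline is the
allelic 1-df chi-squared test on the 2N allele table (Fisher exact
optional), with the genome-wide threshold 5·10⁻⁸.

## The synthetic cohort generator

`generate_cohort()` emulates a matched case–control study: `n_cases`
cases, controls at a fixed ratio (default 2:1), biallelic SNPs with
minor-allele frequencies uniform on `maf_range` (default 0.05–0.5), and
genotypes drawn from Hardy–Weinberg proportions independently across SNPs
(no LD by default; an AR(1) Gaussian-copula block-LD option exists but is
off, matching reported panels whose associated SNPs were not in LD).

Planted signatures follow a liability model:
log-odds(case) = baseline + Σₛ βₛ·I(carries s). For each signature, βₛ is
solved by root finding against the closed-form expected case–control
carrier frequencies so the expected odds ratio meets the target
(tolerance 10⁻⁶ on the OR scale), and the member-SNP state probabilities
are solved (water-filling within the feasible range implied by
`maf_range`) so the expected carrier fraction among cases meets the
target prevalence. Unreachable targets raise an error naming the
signature. Sampling to fixed case/control counts draws genotypes
conditional on status — the case–control-sampled equivalent of the
liability model. With several signatures, carrier states are drawn
jointly from the exact 2^S distribution; a per-pair damping factor
(default 0.5) induces the mild negative dependence that keeps planted
patient subgroups sharing well under 20% of their case carriers, and a
fixed-point recalibration of (qₛ, βₛ) against that joint distribution
keeps every signature's OR and prevalence on target (without it, damping
biases realized ORs low).

Marginal-effect-free signatures are planted differently: the member-SNP
joint genotype distribution in cases puts elevated mass on the exact
target state and the complement cells are refitted by iterative
proportional fitting so each member SNP's *marginal* genotype
distribution equals the control distribution. Such signatures are
invisible to single-SNP association tests by construction; their pairwise
margins retain association (they are single-marginal-free, not
pair-marginal-free), which is precisely what lets a search seeded from
pairs discover them. A fully pair-marginal-free construction would be
undiscoverable by any singleton/pair-seeded search and is intentionally
not the default.

The truth set records, for every planted signature, its realized carrier
sets and odds ratio — recomputed by scanning the emitted matrix, so truth
and data cannot disagree. Everything is bit-reproducible from the spec
and seed.

**What the generator does not emulate:** realistic human LD structure,
ancestry admixture, genotyping batch effects, imputation uncertainty, sex
chromosomes, and genuine biological pleiotropy. Passing recovery tests on
these cohorts shows the pipeline's statistical machinery works under its
own model; it does not show that real cohorts satisfy that model.

## Scaled-down experiments and their design

The package's end-to-end tests run the full pipeline on desk-scale
cohorts (hundreds of cases, 50–200 SNPs) rather than biobank scale
(thousands of cases, half a million SNPs). Two scale effects matter and
are worth understanding:

* **The search null is relatively stronger at small n.** The permutation
  null of the mining procedure is the distribution of the *best*
  combination the search can find on label-shuffled data. At a few
  hundred cases, greedy search over even 200 SNPs occasionally overfits a
  pure-noise triple to an odds ratio near 4 at a 10% case prevalence, so
  a genuinely planted signature of similar strength can collect an
  occasional permutation hit that would be unreachable at ten times the
  sample size. The recovery experiments therefore either plant effects at
  the upper end of the reported community range or restrict the search to
  the planted order, and the permutation-hit count of a strongly planted
  signature should be read as "at the floor of the null", i.e. 0 or very
  close to it, at desk scale.
* **BH needs permutation resolution.** See the bound above; each
  experiment's `n_perm` was chosen from it (and from runtime), not from
  observed outcomes: 40 permutations suffice for a negative control
  (validation must simply remain empty), while 300–600 are needed before
  a handful of true signatures can clear BH among dozens of mined
  candidates.

Experiment sizes used by the test suite: null cohorts at 500/1000 × 100
SNPs; order-3 recovery at 1000 cases × 100 SNPs (target OR 3.5,
prevalence 0.12); the marginal-free contrast at 500/1000 × 60 SNPs
(OR 4.3, prevalence 0.18, 600 permutations); community recovery at
800/1600 × 50 SNPs (ORs 4.30–4.45, prevalences 0.11–0.13, 300
permutations). These are the package's chosen study conditions for
demonstrating each property at interactive runtimes.

## Numerical and convention choices

* Seeds: every stochastic operation takes an explicit seed; sub-streams
  derive from one global seed via `derive_seed()` (a multiplicative mix,
  always below 2³¹), so a single integer reproduces a full pipeline run
  byte-for-byte. RNG state is always restored on exit.
* The mining hot path uses a vectorized exact two-sided Fisher
  (hypergeometric enumeration per table); tests pin it to `fisher.test`
  at 10⁻¹⁰. Zero-carrier combinations get p = 1 by convention.
* Ties in mining output are ordered (p ascending, OR descending, order
  ascending, key lexicographic); sub-combinations with identical carrier
  sets therefore rank immediately before their supersets.
* The exact Hardy–Weinberg QC test conditions on allele counts and sums
  probabilities ≤ the observed configuration's, with a 1 + 10⁻¹²
  tie-tolerance factor.
* QC order is fixed: autosome restriction, sample missingness, SNP
  missingness, MAF, HWE-in-controls; the procedure is idempotent. The
  default thresholds (MAF ≥ 0.01, missingness ≤ 5%, HWE p ≥ 10⁻⁶) are
  field-standard stand-ins, all configurable.
* Greedy extension requires a strict score increase; the first-best
  candidate wins ties (column order: SNP, then genotype), making the
  search deterministic given its seed.

## Known limitations

The stochastic search is an explicit stand-in for a proprietary
large-scale search scheduler and makes no completeness claim; exhaustive
mode is bounded by the evaluation budget. The liability generator is a
stand-in for an unknown real generative process. Covariate-adjusted
association models, eQTL/chromatin gene assignment, pathway enrichment
and drug-target annotation are out of scope. Communities produced by
modularity maximization on small graphs can split dense noise clusters or
absorb hybrid signatures; the weighted signature-vote assignment
mitigates but does not eliminate this.
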