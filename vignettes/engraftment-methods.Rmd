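---
title: "Methods: quantifying donor engraftment after FMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying donor engraftment after FMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtengraft)
```

# The problem

Fecal microbiota transplantation transfers a processed donor stool
community into a recipient's gut. Whether the donor community *engrafts* —
and at what taxonomic depth — is the central mechanistic question: a
recipient may adopt donor species wholesale, retain their own community
with cosmetic changes, or (at the strain level) end up hosting donor and
indigenous strains of the same species side by side. `fmtengraft`
quantifies engraftment in donor–recipient cohorts profiled by shotgun
metagenomics at three levels: community composition, species sources, and
strain-resolving single-nucleotide variants (SNVs). This vignette explains
each model, its assumptions and tunable parameters, the numerical
conventions, and what the validation on synthetic cohorts does and does not
establish.

# Species-source partitioning

For each post-FMT sample we compare three relative-abundance profiles on a
common taxon index: the recipient's baseline (pre-FMT), the post-FMT
sample, and the paired donor. A single detection gate — relative abundance
of at least `threshold` (default 0.001, inclusive) — applies uniformly to
all three profiles; taxa below it are treated as undetected, which guards
against classifying sequencing noise as colonization. Every taxon detected
post-FMT then falls into exactly one of four categories:

| detected in donor | detected at baseline | category |
|---|---|---|
| yes | no  | donor-specific |
| no  | yes | recipient-specific |
| yes | yes | common |
| no  | no  | new |

Fractions are computed over the detected post-FMT taxa only, in two
flavors: *count* fractions (each taxon weighs equally) and
*abundance-weighted* fractions (renormalized to the detected mass). Both
are first-class outputs because they answer different questions — "how many
species came from the donor" versus "how much of the community came from
the donor" — and can differ substantially when engrafted taxa are rare.
Cohort summaries report the arithmetic mean and sample standard deviation
(n − 1) of the donor-specific fraction per disease subtype; a group of one
reports SD 0 with an explicit flag rather than NA, so downstream tables
stay numeric.

Note one subtlety of the uniform gate: the category of a taxon is a pure
function of its detection pattern in the (donor, baseline, post) triple,
and raising the gate can change that pattern in any of the three profiles
— e.g. a taxon barely detected in the baseline can become donor-specific
under a stricter gate. The package therefore pins the category rule
exhaustively over all presence patterns at boundary abundances in its
tests, rather than asserting that categories are invariant to the gate.

# Community metrics

Alpha diversity is the Shannon index in natural-log units, computed on the
renormalized profile. Community change is measured by Bray–Curtis
dissimilarity on log-transformed abundances; the transform is shared by all
distance computations and set in one place (`transform_spec()`):

- `shifted_log` (default): $x' = \log(1 + x/x_0)$ with pseudo-count
  $x_0 = 10^{-6}$. This preserves the pseudo-count convention and
  monotonicity while mapping zero abundance to zero, so Bray–Curtis stays
  within $[0, 1]$.
- `raw_log`: $x' = \log(x + x_0)$, kept for fidelity experiments. It maps
  zero abundance to $\log x_0 \approx -13.8$; Bray–Curtis on
  negative-valued inputs is ill-behaved (it can leave $[0,1]$), which is
  why this variant is not the default. Whether published analyses of this
  kind ran on the raw or a shifted transform is often unknowable from
  methods text, so both are implemented.

Cosine similarity is computed on raw relative abundances (it is a
correlation-like measure of compositional resemblance; no transform is
applied). Directionality of change is summarized by the three Euclidean
distances among baseline, post-FMT, and donor profiles on transformed
values; callers interpret movement toward the donor versus back toward
baseline. Multi-group diversity comparisons use the tie-corrected
Kruskal–Wallis test with a $\chi^2_{k-1}$ reference; the fully degenerate
case (all observations identical) is defined as $H = 0$, $p = 1$.

# Strain tracking via determinant SNV positions

Species-level profiles cannot distinguish a recipient keeping their own
*Faecalibacterium* strain from adopting the donor's. The strain model works
from per-position biallelic SNV tables (species, 0-based reference
position, reference/alternative allele, and per-sample read coverage and
alternative-allele frequency — a tabular reduction of metaSNV-style
output).

**Presence calls.** A position's allele state in a sample is called from
(coverage, frequency) alone: *present* if coverage ≥ `cov_min` and
frequency ≥ `present_min`; *absent* if coverage ≥ `cov_min` and frequency ≤
`absent_max`; otherwise *unresolved*. Defaults are `cov_min = 5`,
`present_min = 0.10`, `absent_max = 0.05`. The rationale: at a typical 20×
coverage and ~1% per-read error (of which about a third of miscalls produce
the specific alternative base), a single stray read yields frequency 1/20 =
0.05. Requiring ≥ 0.10 to call presence demands at least two supporting
reads, putting the call above the error floor, while allowing ≤ 0.05 to
call absence keeps single-error positions out of the unresolved class —
important because unresolved positions are excluded from retention
denominators, and an asymmetric unresolved class would bias retention
upward. All three thresholds are exposed in the configuration.

**Determinant sets.** For each donor–recipient pair and species, the
*determinant positions* are defined from the two baseline samples only:
donor-specific positions are present in the donor and absent in the
recipient's baseline; recipient-specific positions are the reverse;
positions unresolved in either sample are dropped. A species whose
determinant set has fewer than `min_positions = 20` members is excluded
with a logged reason — this operationalizes "sufficiently and consistently
detected" and automatically rejects pairs whose baselines are
indistinguishable, which is exactly the autologous-control situation
(a subject re-infused with their own microbiota has no determinant
positions against themselves).

**Retention and classification.** In each post-FMT sample, the donor
(resp. recipient) retention is the fraction of donor-specific (resp.
recipient-specific) positions called present, over those not unresolved
there. The joint pattern is classified with two conventional thresholds
(`hi = 0.8`, `lo = 0.2`, both configurable, boundaries inclusive):
*coexistence* if both retentions ≥ `lo`; *donor takeover* if donor ≥ `hi`
and recipient < `lo`; *recipient persistence* in the mirror case; otherwise
*indeterminate*. Coexistence is evaluated first, so a 0.9/0.5 pattern is
coexistence, not takeover. Newly arising variation is tracked separately as
the fraction of positions absent at baseline and present post-FMT, over
positions evaluable in both samples.

**Cohort summaries** average in two levels — species within recipient
first, then recipients within (subtype, day) — so a recipient with many
tracked species cannot dominate a cell. Means are reported with the sample
SD across recipients.

# Per-taxon engraftment prediction

The prediction module asks whether post-FMT composition is *computable*
from what is known before the transplant. For every taxon that passes a
prevalence filter (detected in ≥ 3 samples, to avoid degenerate
single-class targets), two random-forest models are fit on one shared
feature matrix — the donor's taxon abundances, the recipient's baseline
abundances, and the recipient's baseline clinical indexes, each column
carrying a provenance label: a presence classifier (target: detected at the
prediction day, default day 3) and an abundance regressor. Donor clinical
metadata can be added through the same provenance mechanism but is off by
default, as recipient-side clinical data is the better-attested input.

Because such cohorts are small (~15 recipients), no held-out split is
defensible; all evaluation is out-of-bag (OOB). The classifier's AUC is
computed from OOB class-vote fractions with a fixed direction (higher
vote for "present" scores higher), so an uninformative model sits near 0.5
and label flipping exactly complements the AUC. `mtry` is selected per
model by 5-fold cross-validation over a halving grid ($p, p/2, \ldots, 1$),
ties to the smaller value. Regression performance is pooled: OOB
predictions from all regressors are rank-correlated with observations
(Spearman ρ, asymptotic p, optional permutation p). Feature importance is
permutation importance (mean decrease in OOB accuracy / increase in MSE);
models with AUC > 0.9 contribute their rank-normalized importance vectors,
averaged per feature, and the top 40 features are reported with provenance.

Two small-sample honesty notes, both surfaced by the implementation. First,
with ~15 recipients the framework flags the run as small-sample: OOB AUCs
are then noisy. Second, `randomForest` never leaves the sole member of a
class out of bag, so a taxon absent in exactly one recipient has an
undefined OOB vote for that recipient and its AUC is reported as `NA`
rather than silently mis-scored. Defaults: 500 trees, seed mandatory.

# Clinical-correlation networks

For every recipient with both visits, deltas are formed: Δtaxon =
abundance(day 3) − abundance(baseline), and Δindex likewise from the
clinical table (recipients missing either visit drop out of the affected
columns; physical characteristics such as age or disease duration enter the
same machinery as any other index). Every (taxon, index) pair with at least
`min_n = 4` complete observations and non-constant columns gets a
tie-corrected Spearman ρ with a two-sided asymptotic p-value; below four
observations rank p-values are vacuous, so such pairs are skipped with a
recorded reason, not imputed. Benjamini–Hochberg adjustment is applied
across all tested pairs, and edges with q strictly below `q_max = 0.05`
form a bipartite taxon–index network (edge weight |ρ|, sign attribute),
exportable as GraphML or SIF. A stricter raw-p preset (p < 0.01) can be
configured where that convention is wanted.

# The synthetic cohort generator

The generator exists so that every stage can be validated against known
ground truth; it emulates the *profiled outputs* of an FMT study, not reads.

- **Species level.** A pool of `n_taxa` taxa; each subject includes a taxon
  with probability 1 − `sparsity` (default 0.5, which populates both the
  shared and the exclusive categories) and detected taxa get log-normal(0, 1)
  magnitudes, renormalized to sum to one. The post-FMT profile at every
  time point is the renormalized mixture $d \cdot \text{donor} +
  (1 - d - g)\cdot \text{recipient} + g \cdot \text{environment}$, with the
  environmental component supported on taxa seen in neither baseline. The
  defaults encode the study conditions used throughout the package's
  validation: 15 pairs (11 CD, 4 UC), 6 donors shared round-robin,
  $d = 0.3$, $g = 0.05$. The truth record stores each pair's planted $d$,
  $g$, and realized donor-exclusive mass for recovery tests.
- **Strain level.** Each simulated species is attached to one pair; half
  its positions are donor-specific, half recipient-specific. Post-FMT, each
  donor-specific allele is established with probability $f$ and each
  recipient-specific allele retained with probability $r$ — one Bernoulli
  draw per position, shared across post time points, treating engraftment
  as a persistent state. Coverage is Poisson(`mean_coverage`);
  alternative-allele reads are Binomial with success probability
  $1 - e$ where the allele is carried and $e/3$ where it is not
  (a miscall hits the specific alternative base a third of the time).
  Positions are independent: no linkage, matching the position-wise (not
  haplotype) treatment of the analysis. Default arm contrast where one is
  wanted: $f = 0.6$ (UC-like) versus $f = 0.1$ (CD-like), $r = 0.9$,
  20× coverage, 1% error.
- **Clinical level.** Baseline index values are Normal(50, 5); changes are
  independent standard normals except for planted (taxon, index, ρ) effects,
  generated by a Gaussian copula against the recipient's realized Δtaxon so
  the requested rank association holds approximately.

Determinism is a contract: identical spec + seed give bit-identical
outputs, the global RNG stream is left untouched (`withr::with_seed`), and
the pipeline derives per-stage sub-seeds from the single configured seed.

**What passing these tests shows — and does not.** Recovery of planted
$d$ and $f$ shows the estimators are consistent and (for retention,
within ±0.01 at the calibration conditions) unbiased *under this
generator*. Real cohorts differ in ways the generator deliberately omits:
taxa are phylogenetically correlated, abundances drift longitudinally,
strains recombine and share linkage, and clinical indexes co-vary. In
particular, because simulated taxa are independent, the only informative
features for predicting taxon *t* are the donor and baseline abundances of
*t* itself; with 15 recipients and hundreds of features, per-taxon OOB AUCs
on the synthetic cohort sit near chance, whereas the same classifier
recovers a deterministic donor-OR-baseline presence rule essentially
perfectly at n = 200 (the package validates both, and the acceptance script
reports both). High AUCs reported on real cohorts plausibly ride on
cross-taxon structure that the generator does not claim to reproduce.

# Numerical choices and problem sizes

- Detection gate boundaries are inclusive ("at least 0.001"); q-value
  cutoffs are strict ("smaller than 0.05"). Both are pinned by tests.
- All fractions summing to one are validated to 1e−9; abundance columns to
  1e−6 on ingest (compositional data frequently carries rounding slack).
- TSV emission prints doubles in the shortest representation that survives
  a parse round trip, so write-then-read is bit-identical; missing values
  are written as empty strings and accepted as "", "NA", or "NaN" where a
  missing value is legal.
- Validation suite sizes were chosen to keep the default run at a few
  minutes on one CPU: 1000 random instances per statistical primitive
  against brute-force oracles; 200 replicates × 4 displacement levels
  (~1000 determinant positions each) for retention recovery; 200 null and
  100 planted replicates for FDR control and edge recovery; 50
  permuted-label refits for the null AUC band.

# Known limitations

- Strain calls are binary per position; fractional strain mixtures within a
  sample are only seen through the coexistence classification, not
  deconvolved.
- The prevalence filter bounds presence, not absence, so singleton-absence
  taxa can still reach the classifier (their AUC is then honestly `NA`).
- Clinical values are consumed as given; no unit harmonization or outcome
  scoring (remission indices are inputs, not outputs).
- Genus-level narratives, ordination plots, and network drawing are out of
  scope; the package exports the graph and the tables instead.
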