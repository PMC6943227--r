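# fmtengraft

Quantifying bacterial engraftment after fecal microbiota transplantation
(FMT) from shotgun-metagenomic profiles.

After an FMT, a recipient's gut community is a mixture: species and strains
carried over from their own baseline microbiota, species and strains
established from the donor, and newcomers from neither. `fmtengraft`
implements the species- and strain-level bookkeeping needed to quantify that
mixture in a donor–recipient cohort (for example IBD patients with Crohn's
disease or ulcerative colitis treated by single-dose FMT), together with the
downstream prediction and correlation analyses, as a tested, reusable R
package:

- **Species-source partitioning** — each post-FMT community, gated at a
  relative-abundance detection threshold (default ≥ 0.001), is split into
  *donor-specific*, *recipient-specific*, *common*, and *new* species by
  comparing it against the paired donor and pre-FMT baseline profiles; both
  count fractions and abundance-weighted fractions are reported, with
  per-subtype mean ± SD summaries of the donor-specific ("donor gain")
  fraction.
- **Community metrics** — Shannon diversity *H* = −Σ pᵢ ln pᵢ;
  Bray–Curtis dissimilarity BC = Σ|aᵢ′−bᵢ′| / Σ(aᵢ′+bᵢ′) on log-transformed
  abundances with pseudo-count x₀ = 10⁻⁶; cosine similarity on raw
  abundances; Euclidean baseline/post/donor distance triples; Kruskal–Wallis
  multi-group tests.
- **Strain tracking** — for each pair and species, *determinant SNV
  positions* are defined at baseline (donor carries the alternative allele
  and the recipient does not, or vice versa) from per-position coverage and
  allele-frequency tables; post-FMT samples are scored by the retention
  fraction of each side and classified as donor takeover, recipient
  persistence, or donor–recipient coexistence; newly arising SNVs are
  quantified against baseline.
- **Per-taxon engraftment prediction** — one random-forest presence
  classifier and one abundance regressor per taxon, from donor profile +
  pre-FMT profile + baseline clinical indexes, with cross-validated `mtry`
  selection, out-of-bag AUC, pooled out-of-bag Spearman ρ for the
  regressors, and rank-normalized permutation-importance aggregation across
  well-performing models (AUC > 0.9).
- **Clinical correlation networks** — Spearman correlation of per-recipient
  *changes* (day 3 − baseline) in taxon abundance against changes in
  clinical indexes, Benjamini–Hochberg control, and a bipartite network of
  q < 0.05 edges exportable as GraphML or SIF.
- **Synthetic cohorts with known truth** — generators for donor/recipient
  abundance profiles with a controlled donor-engraftment fraction,
  determinant-SNV tables with controlled strain displacement and coverage
  noise, and clinical tables with planted taxon–index associations, so
  every stage is validated against ground truth without sequencing data.

Inputs are plain TSVs: an mOTU-style taxa × samples relative-abundance
table, a cohort manifest (sample ↔ subject ↔ donor links, CD/UC subtype,
allogenic/autologous arm, day offsets), a metaSNV-style per-position SNV
table, and a long-format clinical table. SNV positions are 0-based on the
species reference.

## Worked example

Simulate a 15-pair cohort (11 CD, 4 UC; follow-up at days 3 and 30) in
which 30% of each post-FMT community's mass comes from the donor, with
strain displacement f = 0.1 on the CD arm and f = 0.6 on the UC arm, then
quantify engraftment:

```r
library(fmtengraft)

cohort <- simulate_species_cohort(cohort_sim_spec(
  n_pairs = 15, n_taxa = 120, d = 0.3, g = 0.05,
  timepoints = c(3, 30), seed = 1))

parts <- partition_cohort(cohort$abundance, cohort$manifest)
donor_gain_summary(parts$table, kind = "count")
#>     group  n  mean     sd single_observation
#> 1      CD 22 0.251 0.0511              FALSE
#> 2      UC  8 0.242 0.0501              FALSE
#> 3 overall 30 0.249 0.0501              FALSE

snv <- simulate_snv_cohort(strain_sim_spec(
  n_species = 15, positions_per_species = 200,
  f = c(rep(0.1, 11), rep(0.6, 4)), seed = 2), cohort$manifest)
series <- track_strains(snv$snv, cohort$manifest)
cohort_retention_summary(series)
#>   subtype day n_recipients  mean     sd
#> 1      CD   3           11 0.107 0.0260
#> 2      CD  30           11 0.107 0.0267
#> 3      UC   3            4 0.545 0.0339
#> 4      UC  30            4 0.543 0.0395
```

Post-FMT recipients drew about 25% of their detected species from their
donors (the planted mixing fraction propagated through the detection gate),
and donor-specific strain alleles were retained at ~11% in the CD arm
versus ~54% in the UC arm, recovering the planted arm contrast. The whole
analysis can also be driven from one YAML config via `run_pipeline()` /
`write_report()`, or from the shell through the thin wrapper in
`inst/scripts/engraft-cli.R` (subcommands `simulate` and `run-all`).

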