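# dupdel

Analysis of duplication-then-deletion events in *Drosophila* gene pairs.

Each event starts with a gene duplication in the common ancestor of
*D. melanogaster* and *D. pseudoobscura*, followed by deletion of one copy
in one descendant lineage. The species where the deletion happened carries a
single **derived** copy (D); the other species preserves the ancestral state
with the orthologous **survived** copy (S) and the non-orthologous **lost**
copy (L). Events are classified as **redundant** (the two copies shared a
function) or **unique** (the lost copy had a distinct function). Two
questions drive the analysis:

1. Does deletion preferentially remove the **parent** (ancestral) or the
   **child** (newly created) copy of the duplicate pair?
2. How do deleted genes compare with single-copy genes in sequence
   evolutionary rate (Ka/Ks), expression (FPKM in six tissues),
   protein-interaction degree, and protein structure (TM-score, pLDDT)?

## What the package does

* **Six-stage assignment cascade** (`run_cascade()`): parent/child labels
  for each S/L pair from, in order: curated literature flags; conservation
  across 12 *Drosophila* species (the fully conserved copy is the parent);
  retrotransposition signature (the intronless copy of an
  intronless/intron-bearing pair is the child); ortholog counts across 37
  species (more orthologs = parent); orthogroup size (larger = parent); and
  the same conservation criteria applied to the D copy versus L. The first
  stage that discriminates wins; the rest never revisit the event.
* **Deletion-bias tests** (`run_bias_analysis()`): exact two-sided binomial
  tests by the point-probability method — `p = sum over k of Pr(X = k)` for
  all `k` with `Pr(X = k) <= Pr(X = x_obs) * (1 + 1e-7)` — comparing
  resolution rates between classes and child-versus-parent loss within each
  class against `p0 = 0.5`.
* **Feature comparisons** (`run_feature_comparisons()`): two-sided
  Mann-Whitney U tests (midranks; exact enumeration for small tie-free
  samples, otherwise normal approximation with tie and continuity
  correction) on log10-transformed features across the single-copy,
  deleted-redundant and deleted-unique groups.
* **Synthetic cohorts** (`generate_cohort()`): fully self-contained inputs
  with planted parent/child truth, per-stage resolvability, and configurable
  group effects, plus a deterministic bookkeeping fixture
  (`generate_reference_fixture()`) encoding the reference per-stage evidence
  structure.
* **I/O** for the formats involved: TSV event/evidence/feature tables,
  STRING-style physical-link + alias tables (`read_tables()`), GFF3 gene
  models for intron counts (`read_gene_models()`), and transcript FASTA
  (`read_sequences()`).

## Worked example

```r
library(dupdel)

fx <- generate_reference_fixture()
ba <- run_bias_analysis(fx$events, fx$evidence)
ba$stage_tally
#>         literature     conservation12 retrotransposition          orthodb37
#>                 10                 16                 22                 17
#>         orthogroup       derived_copy         unresolved
#>                 20                  5                 10
ba$tests
#>                            test  x  n    p0  p_value star
#>  resolution_redundant_vs_unique 37 45 0.964 1.97e-04  ***
#>         deletion_bias_redundant 23 37 0.500 1.88e-01   ns
#>            deletion_bias_unique 44 53 0.500 1.22e-06  ***
```

The cascade resolves 90 of the 100 events (10 stay unresolved). Unique
deletions are resolved significantly more often than redundant ones
(37/45 observed against the unique rate 53/55, p = 1.97e-4). Among resolved
redundant events, 23 of 37 child losses is compatible with unbiased loss
(p = 0.19); among resolved unique events, 44 of 53 child losses is a strong
bias toward losing the younger child copy (p = 1.22e-6).

Feature comparisons on a synthetic cohort with the default planted effects:

```r
co <- generate_cohort(cohort_config(seed = 1))
cmp <- run_feature_comparisons(co$features)$comparisons
subset(cmp, feature == "ka_ks")
#>  feature           group_a           group_b n_a n_b median_a median_b  p_value star
#>    ka_ks       single_copy deleted_redundant 500  45   -0.939   -0.627 7.41e-09  ***
#>    ka_ks       single_copy    deleted_unique 500  55   -0.939   -0.972 4.54e-01   ns
#>    ka_ks deleted_redundant    deleted_unique  45  55   -0.627   -0.972 1.42e-06  ***
```

Medians are on the log10(Ka/Ks) scale: deleted redundant genes evolve
faster than single-copy genes, while deleted unique genes do not — the
pattern the pipeline is designed to detect.

A thin command-line wrapper is installed under
`inst/scripts/dupdel.R` (`simulate`, `fixture`, `assign`, `compare`).

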