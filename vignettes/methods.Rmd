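---
title: "Methods: parent-child assignment and feature analysis of gene deletion events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parent-child assignment and feature analysis of gene deletion events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The setting

A duplication-then-deletion event pairs three genes across two *Drosophila*
species. The species in which the deletion occurred carries a single
*derived* copy (D). The other species preserves the ancestral, two-copy
state: the *survived* copy (S), which is D's ortholog, and the *lost* copy
(L), the paralog whose counterpart was deleted. Each event is classified
*redundant* or *unique* by whether the two copies shared a function before
the loss. The analysis asks which member of the original duplicate pair —
the ancestral *parent* or the newly created *child* — corresponds to the
deleted L copy, and how deleted genes differ from single-copy genes in
sequence, expression, interaction and structural features.

## The assignment cascade

Evidence about which copy is the parent is heterogeneous and partial, so
assignment proceeds through six stages applied in a fixed order; the first
stage that discriminates labels the event and later stages never revisit
it. The order follows the narrative in which the evidence layers were
collected, from most direct (experimental literature) to most indirect
(derived-copy conservation), and it encodes an authority ranking: a
literature assignment is never overturned by an ortholog count.

1. **Literature** — curated flags (`parent`, `child`, `none`) per gene.
   Resolves when exactly one copy is flagged or the two flags are
   complementary. Two identical flags are a curation conflict; the event
   passes on with a logged warning rather than an error, because a conflict
   is an input-quality fact worth surfacing, not a reason to halt a
   100-event analysis.
2. **12-species conservation** — a presence/absence profile over 12
   reference species per gene. The copy present in *all twelve* is the
   parent; the stage requires exactly one fully conserved copy. Partial
   conservation (11/12 versus 10/12) is deliberately not compared: the rule
   is full conservation, not "more conserved".
3. **Retrotransposition** — intron counts derived from gene models.
   Retrotransposed children arise from reverse-transcribed mRNA and are
   intronless; when exactly one copy has zero introns and its paralog at
   least one, the intronless copy is the child.
4. **37-species ortholog counts** — the copy with orthologs in strictly
   more of 37 surveyed species is the parent (greater evolutionary age).
   Strict inequality with no margin: a 5-versus-4 difference resolves. No
   threshold was stated for this evidence class, and inventing a margin
   would silently move events into later, weaker stages.
5. **Orthogroup size** — the copy in the strictly larger orthogroup is the
   parent; same strictness rationale.
6. **Derived copy** — for still-unresolved events, the same conservation
   criteria (full 12-species conservation, then ortholog counts, then
   orthogroup size) are applied between D and L. D is compared against L —
   not S — because D is S's ortholog: the informative contrast is whether
   the surviving lineage (D/S) or the lost lineage (L) is the conserved
   one. If D wins a criterion, S is the parent and L the child; if L wins,
   L is the parent. The internal criterion order repeats the cascade's own
   conservation ordering. Both the D-versus-L contrast and the internal
   order are design choices; the evidence description leaves them open.

The deleted role follows mechanically: the L copy is the one that was
deleted, so the event is a *parent deletion* exactly when L receives the
parent label.

Order sensitivity is confined to genuinely conflicting evidence: on any
cohort where at most one stage discriminates per event (which the synthetic
generator guarantees by construction), permuting the stage order leaves all
assignments unchanged — a property the test suite checks directly.

## Statistical machinery

**Exact binomial test.** Two-sided p-values use the point-probability
definition: with observed successes $x$ out of $n$ trials under null
probability $p_0$,
$$p = \sum_{k:\; \Pr(X=k) \le \Pr(X=x)\,(1+10^{-7})} \Pr(X = k), \qquad X \sim \mathrm{Bin}(n, p_0).$$
The $1+10^{-7}$ relative tolerance protects ties in point probabilities
from floating-point noise; for asymmetric nulls (the resolution-rate test
uses $p_0 = 53/55$) it decides which far-tail outcomes join the rejection
set and is required to reproduce the reference values. Point probabilities
are computed in log space and summed by log-sum-exp; the result is clamped
to $(0, 1]$. The implementation is verified against complete enumeration of
all $2^n$ success/failure sequences for $n \le 12$.

Three tests are parameterized from the cascade output: resolution-rate
(successes = resolved redundant events, trials = all redundant events,
$p_0$ = fraction of unique events resolved), and within-class deletion bias
(successes = deleted children among resolved events of the class, $p_0 =
0.5$). Raw p-values are reported; no multiple-testing adjustment is applied
by default (an optional Benjamini-Hochberg flag exists for the feature
comparisons), matching the convention of reporting each test against the
conventional star thresholds (* $p<0.05$, ** $p<0.01$, *** $p<0.001$,
strict inequalities).

**Mann-Whitney U.** $U$ is computed from midranks, so $U_A + U_B = n_A
n_B$ holds with ties. For tie-free samples with both $n \le 10$ (or on
request) the exact null distribution is enumerated by the standard
count recursion and the two-sided p-value is $\min(1,\, 2\min(\Pr(U \le
u), \Pr(U \ge u)))$; otherwise a normal approximation with tie correction
and continuity correction is used. The exact branch is verified against
complete enumeration of all $\binom{n_A+n_B}{n_A}$ labelings; both
branches agree with R's reference implementation to $10^{-12}$ on random
data. When all pooled values are identical the tie-corrected variance is
zero and the p-value is defined as 1.

**Transforms.** Ka/Ks uses $\log_{10}$ of the ratio (nonpositive and
missing values excluded); expression and interaction degree use
$\log_{10}(v+1)$ (only missing excluded); TM-score and pLDDT use raw
$\log_{10}$ on their native scales ($[0,1]$ and $[0,100]$). Exclusion is
per feature, never per gene: a gene missing Ka/Ks still contributes to the
expression comparison, and each comparison reports its own sample sizes.

**Expression aggregation.** The six per-tissue FPKM values collapse to one
expression value per gene as the mean of the six $\log_{10}(\mathrm{FPKM}+1)$
values (a max-over-tissues alternative is configurable). A single
distribution per group is what the comparison consumes; the mean is the
neutral choice when no aggregation rule is prescribed.

**Which copy represents a deleted event.** Per-gene features of deleted
events default to the L copy — the gene that was actually deleted in the
derived lineage, observable in the ancestral-state species. The choice is
configurable (`S` or `D`) because the pairing of per-gene features to
events is genuinely ambiguous in the data description; the package stores
features per gene and leaves pair construction (e.g. for Ka/Ks or
TM-score, which arise from S-L or cross-species alignments upstream) to
the columns supplied, rather than recomputing alignments it does not have.

## The synthetic cohort generator

The generator emulates the *statistical structure* the analysis assumes,
not *Drosophila* biology. Defaults mirror the reference cohort: 45
redundant and 55 unique events; a single-copy baseline (500 genes by
default — a simulation size chosen to keep replicate studies fast, not an
estimate of the real 9,177-gene baseline, and freely configurable);
child-deletion probabilities 23/37 (redundant) and 44/53 (unique), the
resolved-event fractions; and stage-resolution probabilities proportional
to the per-stage resolution counts (10/16/22/17/20/5 resolved, 10
unresolved, per 100 events).

Per event, the generator draws the true parent/child orientation and the
intended resolving stage, then emits evidence that discriminates at exactly
that stage: all other layers carry non-discriminating values (both copies
fully conserved, both with two introns, tied ortholog counts of 20, tied
orthogroup sizes of 5). Evidence is therefore noise-free by construction —
the cascade recovers the planted truth for every resolvable event — so
passing recovery tests demonstrate the bookkeeping and rule logic, *not*
robustness to conflicting or erroneous evidence, which real curation
exhibits and the generator deliberately does not model.

Feature distributions are standard positive-valued families with
group-specific location shifts: log-normal for Ka/Ks (baseline median
$\approx 0.12$, typical of purifying selection) and per-tissue FPKM
(baseline medians of roughly 7-19 FPKM across the six tissues),
negative-binomial for interaction degree (mean 8, dispersion 1.5),
logistic-normal for TM-score (median 0.55) and pLDDT/100 (median 78).
Default shifts plant the qualitative orderings the analysis is built to
detect: elevated Ka/Ks for deleted redundant genes only (+0.35 on the
log10 scale, one generating SD); expression single-copy > deleted unique >
deleted redundant (0 / −0.25 / −0.55); degree deleted unique > single-copy
> deleted redundant (+0.5 / 0 / −0.7 on the log-mean); higher pLDDT for
both deleted classes (+0.35 on the logit scale); and *no* planted TM-score
difference, so the TM-score comparisons double as a type-I calibration of
the whole comparison path. None of these distributional families or effect
sizes is an estimate from data; they are simulation choices fixed once.

A separate deterministic fixture encodes the evidence bookkeeping exactly:
100 events whose layers resolve 10/16/22/17/20/5 per stage with 10
unresolved, deleted-role counts of 14 parent / 23 child among resolved
redundant and 9 / 44 among resolved unique events, and literature flags
only for *D. pseudoobscura*-lineage deletions (curated evidence existed
only where both copies sit in the better-studied *D. melanogaster*). The
8/2 redundant/unique split of the unresolved events is forced by the
resolved-class totals (45−37 and 55−53). The functional-class composition
*within* each stage is not a reported quantity; the fixture fixes it
arbitrarily but deterministically.

Synthetic coding sequences are placeholder open reading frames (random
codons between start and stop) and synthetic gene models encode the
configured intron counts with decoy shorter transcripts; no
sequence-evolution model stands behind either. They exist to exercise the
FASTA/GFF3 readers' longest-transcript rule, defined as greatest summed
exon length with ties broken by lexicographically smallest transcript
identifier.

## Numerical and degenerate-input choices

* Binomial p-values are clamped to $(0,1]$; a zero-probability observed
  outcome under a degenerate null returns the smallest positive double
  rather than 0.
* GFF3 coordinates are 1-based inclusive; strand is ignored for exon
  counting (intron counts are strand-invariant). A transcript with no
  exons is a validation error; a gene with no transcript is simply absent.
* Interaction degree counts distinct physical-link partners in either link
  direction, ignoring duplicate records and self-links; a minimum-score
  filter exists and defaults to 0 because no score cutoff is prescribed
  for physical links.
* Missing values are the literal token `NA` in all TSVs; doubles are
  written with 17 significant digits so write-then-read round-trips are
  bit-exact.
* Referential integrity is always enforced: an event referencing a gene
  without evidence is an error, never a silent drop.

## Problem sizes in the test suite

Calibration tests run 200 replicate cohorts at the default configuration
(and 200 under null configurations) — enough for a 3-standard-error band
of ±4.6 percentage points around a 5% rejection rate; brute-force oracles
enumerate up to $2^{12}$ binomial outcomes and $\binom{16}{8}$ rank
labelings. These sizes were chosen so the full suite completes in about
two minutes while keeping Monte-Carlo bands tight enough to detect
miscalibration of a few percentage points. Because exact binomial tests
are conservative by discreteness (true size $\approx$ 0.027-0.036 at the
relevant sample sizes), calibration bands allow the rejection rate to sit
below the nominal 5%.

## Known limitations

* The cascade is strictly sequential with no weighting or probabilistic
  combination of evidence; an early-stage error propagates.
* The generator's noise-free evidence cannot measure assignment *accuracy*
  under realistic curation error, only bookkeeping correctness.
* Feature comparisons treat genes as independent observations, as the
  rank tests require; paralog relatedness within the deleted groups is not
  modeled.
* TM-score and Ka/Ks enter as precomputed per-gene columns; the package
  does not perform alignments or structure comparison, so the upstream
  pairing convention is whatever produced those columns.
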