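---
title: "Validation statistics for sequencing callsets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation statistics for sequencing callsets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordare)
```

`concordare` computes the statistics used to validate SNV/indel callsets
from clinical whole-exome and whole-genome sequencing: genotype
concordance against truth sets and between technical replicates,
callable-region and coverage summaries, precision–recall behaviour of
variant-quality filters, and site-level evaluation against validated
gene panels. This vignette describes the underlying models, the
parameters that matter, the synthetic-data generators the package is
validated with, and the design decisions taken where the methodology was
genuinely open.

## Variant representation and joining

All downstream statistics join callsets under *strict variant equality*:
two calls match only if chromosome, position, reference allele and
alternate allele are all identical. That rule is cheap and unambiguous,
but it only works if both callsets are normalized the same way, so the
`callset` model enforces:

* **bi-allelic records** — multi-allelic sites are decomposed, one
  record per alternate allele (`decompose_site()`). Each record's
  genotype class is derived from the copy count of *its own* alt allele
  (2 → hom-alt, 1 → het, 0 → hom-ref); copies of other alt alleles count
  as non-alt, so `GT=1/2` becomes two het records. This keeps every
  record self-contained under bi-allelic joins. Any missing allele
  (`./.`, `0/.`) yields a no-call; haploid genotypes map alt → hom-alt
  and ref → hom-ref, with no separate hemizygous class (the expected
  input pipelines emit diploid-style genotypes on gender-masked
  references). Symbolic alleles (`<DEL>`, `*`) are dropped with a
  logged count; MNPs are classed `OTHER` and excluded from SNV/indel
  metric tables.
* **parsimony and left alignment** — `left_align()` trims shared
  trailing bases (borrowing from the reference when an allele would
  empty, which is what shifts indels left through tandem repeats), then
  trims shared leading bases down to the single anchor base. The
  operation is haplotype-preserving and idempotent, and is verified in
  the test suite against an independent string-diff oracle (longest
  common suffix, then prefix, of the reference window and the variant
  haplotype) on randomized tandem-repeat contexts. A context window too
  small to prove the left-shift fixpoint is an error rather than a
  silent partial shift.

A deliberate consequence of strict equality, shared with the validation
practice this package supports: different representations of the same
*complex* variant are not recognized as concordant. Left-aligning both
sides reduces, but does not eliminate, that effect; haplotype-aware
matching is out of scope.

Intervals are 0-based half-open (BED convention) and canonicalized on
construction; the algebra (intersect, union, subtract, flank expansion)
is delegated to GenomicRanges/IRanges behind a tibble surface.
Flank-expanded targets that overlap are merged — the alternative
(keeping overlapping flanked targets distinct) would double-count bases
in coverage denominators.

## The concordance matrix and its metrics

`join_callsets()` produces a 5×5 truth × test count matrix over
{HOMREF, HET, HOMALT, NOCALL, ABSENT}. FILTERED calls are counted as
NOCALL — a filtered variant is a no-call from the caller's point of
view. `concordance_metrics()` then computes:

* concordance over the 3×3 genotyped-in-both block (diagonal / total);
* NRS: non-ref truth rows with a non-ref test call at the same variant;
* NRC: non-ref truth rows with the exactly matching genotype;
* precision: exact matches over evaluable test non-ref calls.

Three choices deserve justification:

* **Concordance excludes no-call and absent cells.** The metric is
  defined over the intersection of the two callsets; including easy
  hom-ref agreements would inflate it, and the callers this package
  targets do not emit hom-ref records at all.
* **Precision and exhaustive truth.** What should a test call at a key
  the truth set lacks mean? Against an *exhaustive* truth source
  (arrays, validated panels, high-confidence reference sets — and
  replicate-vs-replicate comparisons, where the other replicate is the
  only standard available), absence is evidence of a false positive and
  those calls count against precision. Against a non-exhaustive truth
  set they are unevaluable: they are excluded from the denominator and
  reported as `n_unevaluable`. Exhaustiveness is a declared attribute of
  the truth callset, defaulting from its assay type. The exhaustive
  convention also makes the duality `precision(A,B) == nrc(B,A)` exact,
  which the suite asserts on random fixtures.
* **Undefined ratios are `NA`.** A metric with an empty denominator
  carries no information; reporting 0 or 1 would silently bias
  averages over replicates.

`pairwise_replicates()` runs every unordered same-sample pair twice,
with each callset alternately as truth and test: concordance is
symmetric by construction, while NRS/NRC/precision differ between the
directions whenever one replicate has private calls.

## Panel site-level evaluation

`site_eval()` compares a test callset to a panel truth set whose
records are validated as either `nonref` or `ref-confirmed`. Every truth
site lands in exactly one category — exact-variant match (TP), same-site
different-allele call, missed (FN), or confirmed-reference with no call
(TN) — and every unmatched test call is a combined FP/"excess positive"
(the two cannot be distinguished computationally; Sanger-inconclusive
sites make some test-only calls unresolvable). Site-level sensitivity
counts different-allele sites as detected:

sensitivity = (TP + different-allele) / (TP + FN + different-allele),

the rule that reconciles the published per-replicate panel rows this
package reproduces in its acceptance suite; NRC uses genotype-exact
matches over the same denominator, so sensitivity ≥ NRC always. Unlike
the concordance metrics (where FILTERED = no-call is applied at join
time) and unlike uniformity (below), a FILTERED test call here counts as
*not called*: a clinically reportable variant suppressed by the filter
is a missed variant. Truth TN values depend on how many reference sites
a laboratory chose to confirm, so no attempt is made to model them
beyond the supplied `ref-confirmed` records.

`fn_report()` describes each missed or different-allele site with its
truth genotype, the fraction of supplied replicates that call it
(PASSing, exact key), and the longest single-base reference run
overlapping the variant. Runs of ≥ 10 bp are flagged: single-base
indels inside such homopolymer tracts are the dominant false-negative
class in panel comparisons, because sequencers under-observe the
deletion allele there.

## Callable loci and coverage

A base is *confidently callable* iff depth ≥ `min_depth` (default 20×)
and the MAPQ0 read fraction is ≤ `max_mapq0_frac` (default 0.10).
Boundaries are inclusive on both thresholds — "a minimum of 20" admits
20, "no more than 10%" admits exactly 10%. Zero-depth bases (including
positions absent from the track) fail the depth test, so the undefined
0/0 MAPQ0 fraction never needs evaluating. `coverage_summary()` follows
the two-interval convention of exome pipelines: depth statistics
(mean, % ≥ 1/10/20/30×) over the *un-flanked* capture targets, with
zero-depth target bases included in the mean; callable fraction of
coding exons over the targets *expanded by 100 bp flanks*, since reads
spilling over target edges support calls there.
`squared_off_callable()` intersects per-replicate callable sets — the
region where *every* replicate could call — which is the natural
restriction when comparing replicate call uniformity.

The coverage input is a plain per-base TSV (`chrom pos depth mapq0`)
rather than an alignment file: every statistic here is a pure function
of that table, and the table is what synthetic generators and tests can
construct exactly.

## Variant-quality threshold sweeps

`pr_sweep()` treats calls with score ≥ t as PASS and the rest as
no-calls, recomputing precision and NRC at each threshold (≥ rather
than >, fixing a convention the source material leaves open). The
callset's own FILTER column gives the *operating point* — where the
production filter, e.g. a VQSR tranche cut capturing 99.5% of known
true positives, actually sits on the curve. Auto-thresholds are the
sorted distinct scores, thinned deterministically by quantile sampling
to ≤ 200 points so output size is bounded without changing the curve's
shape. Calls lacking the score are excluded and counted (`n_unscored`)
rather than guessed: in real pipelines some variant types are filtered
by fixed rules instead of a trained score, and their placement on a
score sweep is undefined. Sweeps are per variant class (SNV and indel
scores are trained separately).

`marginal_ratio()` reports, between consecutive thresholds, the newly
admitted agreeing calls (ΔTP) and newly admitted disagreeing or
truth-absent calls (ΔFP). A well-placed filter sits near the inflection
where ΔTP:ΔFP ≈ 1 — relaxing further buys more errors than variants —
and the function flags the threshold interval bracketing that ratio.

## Replicate reproducibility

`uniformity()` partitions the union of variant keys across same-sample
replicates by the number of replicates containing each key. Presence
here deliberately *ignores* FILTER — called-but-filtered is still
called — because the question is caller emission stability, not filter
stability; this intentionally differs from the concordance rule.
Percentages are over the raw union of emitted sites. Restricting to
nested interval sets (squared-off callable, then its intersection with
high-confidence regions) concentrates the analysis on well-covered
sequence; because dropout concentrates in poorly covered regions, the
all-replicates fraction should only improve along that nesting, a
directional property the suite asserts on generated families whose miss
rate rises outside the callable tiers.

`build_design()` derives each same-sample pair's comparison kinds from
replicate provenance: same run and machine → intra-run; same machine,
different run → inter-run; different machine → inter-machine; different
mode (high-throughput vs rapid) → inter-mode; different library
preparation → inter-library. Kinds are non-exclusive; the
`primary_label` ("other" when several kinds apply) exists only for
plotting. The shipped WES/WGS design tables derive run, machine, slot
and mode exactly from the *sample/run-machine-slot* naming scheme; the
library column is a synthetic reconstruction consistent with the
experiment constraints (inter-machine pairs share a preparation;
intra-run and inter-run experiments include both same- and
different-preparation variants) and is documented as such in the TSV
headers — every published pair classification the acceptance suite
checks depends only on the name-derived fields.

`regress_concordance()` quantifies kind effects on the
direction-symmetric pairwise concordance. The three run/machine kinds
partition all pairs (every pair is exactly one of intra-run, inter-run,
inter-machine), so a joint model of all indicators is structurally rank
deficient; accordingly the *overall* question — do comparison kinds
matter at all? — is answered by a nested F-test of the joint fit
(rank-aware) against the sample-only null, while each kind's
*coefficient* is estimated from its own OLS fit of concordance on that
kind plus the sample control, mirroring the analyze-each-kind-
individually practice this design follows. Per-kind tests are
Bonferroni-corrected at 0.05 / (number of kinds tested); with the
default WGS family four kinds vary (inter-mode does not exist in WGS),
giving 0.0125. Kinds constant across all pairs are dropped with a
warning. Coefficients read as additive changes in concordance: an
inter-library estimate of −0.0006 means 99% → 98.94%.

## The synthetic-data generators

The generators exist so that every statistic above can be validated
against known ground truth. They are pure functions of their parameters
and seed.

* `gen_reference_context()` draws an i.i.d. A/C/G/T background but
  *caps* background single-base runs at 9 bp, one under the homopolymer
  flag threshold, then embeds exactly the requested tracts with pinned
  flanking bases. Without the cap, a 100 kb random sequence would
  contain spurious ≥ 10 bp runs (expected count ≈ 1.5), making
  homopolymer-specific assertions unreliable.
* `gen_truth_callset()` places sites at distinct positions (spaced 12 bp
  apart when indels are requested, so left-alignment can never collide
  two sites), draws genotypes from the requested het/hom-alt mix, builds
  alleles from the context, left-aligns at generation, and annotates
  each site's homopolymer run length.
* `corrupt()` applies the confusion model per site in a fixed order —
  miss (with an extra dropout for indels in ≥ 10 bp runs), then
  different-allele, then genotype error (het↔hom-alt), then filter —
  with independent draws, so the analytic expectations are exact:
  NRS = (1−p_miss)(1−p_filtered)(1−p_diffallele) and
  NRC = NRS·(1−p_gterr). False positives arrive as a Poisson count per
  interval kilobase at unoccupied positions. The latent per-site labels
  (kept / gterr / filtered / diffallele / missed / fp) ride along as a
  sidecar attribute for exact accounting in tests.
* `score_model()` attaches normal quality scores by latent status (true
  vs artifact distributions); `score_model_roc()` is its closed form,
  the oracle for threshold sweeps. Different-allele calls draw from the
  artifact distribution: they are caller errors, not true variants.
* `batch_effect_model()` / `gen_replicate_family()` generate pairwise
  concordances as base − Σ(active kind decrements) + Gaussian noise,
  clipped to [0, 1], over a replicate metadata table — the known
  generative model `regress_concordance()` must recover. Defaults echo
  the regime the package targets: base concordance 0.99, inter-library
  decrement 6×10⁻⁴, pair noise 2×10⁻⁴.

What the generators *do not* emulate — and what passing tests therefore
do not show about real data: linkage and allele-frequency structure,
sequence-context-dependent error beyond homopolymer dropout, structural
variants and the artifactual calls they induce, caller-specific
representation quirks, and correlated (batch-structured) errors within
a replicate. The generators validate the *statistics*, not the
sequencing.

## Numerical and testing choices

* Chromosomes sort in natural human order (chr1..chr22, X, Y, M),
  unknown contigs lexicographically after, so serialization is
  deterministic.
* Percentages are computed in full precision and rounded only for
  display (one decimal, matching the reporting convention).
* Problem sizes in the validation suite are chosen to make binomial
  error bars meaningfully tight while keeping the whole suite fast:
  1,000 randomized ~40–120-site pairs for the brute-force metric
  oracle, n = 100,000 sites for parameter-recovery checks (3 binomial
  SE ≈ 0.002 at p = 0.95), 100 kb coverage tracks for the callable
  oracle, 25,000 + 25,000 true/artifact calls for the ROC envelope, and
  a 1,000-replicate null simulation for the regression's type-I error.
* Seeds are fixed in tests; generator determinism is itself a tested
  property.

## Known limitations

Complex-variant representations are not reconciled (by design, see
above). Panel TN counts are not modeled. The confusion model applies
errors independently per site, so it cannot represent error clustering.
VQSR itself (training the score) is out of scope: scores and FILTER
status are consumed as annotations. The coverage module consumes
per-base tables, not alignments; deriving such tables from BAM files is
a pre-processing step outside the package.
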