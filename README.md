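# concordare

Analytical validation of clinical whole-exome and whole-genome sequencing
hinges on a small set of questions: how often does a callset agree with an
orthogonal truth set, how reproducible are technical replicates, which
bases were covered well enough to call at all, and where should a
variant-quality filter sit? `concordare` implements the statistics that
answer these questions for SNV/indel callsets, together with deterministic
synthetic-data generators so every computation can be exercised and
validated without any external download. It is aimed at clinical
laboratory bioinformaticians and pipeline developers validating an NGS
workflow.

## The metrics

Callsets are first normalized — multi-allelic sites decomposed into
bi-allelic records, indels made parsimonious and left-aligned — and then
joined under **strict variant equality** (chromosome, position, reference
and alternate allele). Each joined pair of callsets yields a truth × test
count matrix over the genotype classes {hom-ref, het, hom-alt, no-call,
absent}; a FILTERED call is treated as a no-call. From that matrix:

* **concordance** = Σ matching genotypes / Σ sites genotyped in *both*
  callsets (hom-ref/het/hom-alt block only);
* **NRS** (non-reference sensitivity) = truth non-ref sites called
  non-ref at the same variant / all truth non-ref sites;
* **NRC** (non-reference genotype concordance, i.e. genotype-aware
  recall) = truth non-ref sites with the *exact* genotype matched / all
  truth non-ref sites;
* **precision** = test non-ref calls exactly matching the truth genotype
  / evaluable test non-ref calls.

Concordance is symmetric in truth/test; precision(A,B) equals NRC(B,A)
on the same join. Undefined ratios are reported as `NA`, never 0 or 1.

Around this core the package provides: site-level evaluation against
validated gene-panel truth sets (TP / FP-EP / FN / TN / different-allele
tallies, with homopolymer annotation of missed indels); callable-region
computation from per-base depth and MAPQ0 fraction (depth ≥ 20 and ≤ 10%
ambiguously mapped reads, by default); coverage summaries over flanked
and un-flanked targets; precision–NRC curves over a variant-quality
(VQSLOD) threshold sweep with the PASS operating point; replicate
call-uniformity tables; and OLS regression of pairwise concordance on
replicate comparison kinds (intra-run, inter-run, inter-machine,
inter-mode, inter-library).

## Worked example

Generate a truth callset, corrupt it with a known error model, and
measure what the metrics recover:

```r
library(concordare)

targets <- interval_set("chr1", 0, 200000)
truth <- gen_truth_callset(5000, targets, snv_frac = 0.85, seed = 11)
test <- corrupt(truth,
                confusion_model(p_miss = 0.05, p_gterr = 0.02,
                                fp_per_kb = 0.3),
                scores = score_model(), intervals = targets, seed = 12)

compare_callsets(truth, test, targets)
#>   n_joint n_truth_nonref n_test_nonref concordance    nrs    nrc precision
#>      4764           5000          4810      0.9757 0.9528 0.9296    0.9663

join_callsets(truth, test, targets)
#> Genotype concordance matrix: truth = SYNTH1/truth | test = SYNTH1/test
#>         test
#> truth    HOMREF  HET HOMALT NOCALL ABSENT
#>   HOMREF      0    0      0      0      0
#>   HET         0 3092     81      0    163
#>   HOMALT      0   35   1556      0     73
#>   NOCALL      0    0      0      0      0
#>   ABSENT      0   46      0      0      0
```

The numbers behave as designed: NRS ≈ 1 − p_miss = 0.95; NRC ≈
(1 − p_miss)(1 − p_gterr) = 0.931; the 46 `(ABSENT, HET)` cells are the
injected false positives, and the 81 + 35 off-diagonal genotyped cells
are the injected het/hom swaps. Sweeping the attached quality scores
gives the filter operating characteristic:

```r
curve <- pr_sweep(test, truth, targets, vtype = "SNV")
attr(curve, "operating_point")
#>   n_pass precision   nrc
#> 1   4099     0.965 0.929
head(curve, 3)
#>    threshold n_pass precision       nrc
#> 1 -6.1620211   4099 0.9648695 0.9290580
#> 2 -2.1738762   4079 0.9693552 0.9288231
#> 3 -0.6592442   4058 0.9731395 0.9276486
autoplot(curve)
```

Replicate reproducibility works the same way end to end — see
`gen_replicate_family()`, `uniformity()`, `build_design()` and
`regress_concordance()`, and the methods vignette
(`vignettes/validation-methods.Rmd`) for the full model description.

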