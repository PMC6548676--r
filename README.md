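# cogsub

Cognitively defined subgroups of late-onset Alzheimer's disease:
co-calibration of multi-study neuropsychological item data, relative-
impairment subgroup classification, and subgroup genetic association.

## The problem

Late-onset Alzheimer's disease is clinically heterogeneous. One way to
carve it into biologically coherent subgroups is to look at each person's
*relative* cognitive profile at diagnosis: average their scores across
memory, executive functioning, language, and visuospatial functioning,
and flag domains that fall substantially below that personal average.
Before profiles from different studies can be compared, item-level test
data from each study must be placed on a common metric — different
batteries, same latent constructs.

`cogsub` implements that full chain for analysts working with multi-study
cognitive and genetic data:

1. **Co-calibration** — graded response models (GRM) fit by marginal ML
   with fixed quadrature; studies linked through *anchor items*
   (identically scored items shared across studies) whose parameters are
   frozen at reference estimates while each study's latent mean/variance
   is estimated freely. Cumulative model per item:
   `P(X ≥ k | θ) = logistic(a(θ − b_k))`. A bifactor variant (general
   factor + orthogonal subdomain factors) is included. Scores are EAP
   (posterior means), z-transformed to the reference study's case sample.
2. **Classification** — with person mean `s̄` and deviations
   `d_k = s_k − s̄`, domain `k` is substantially relatively impaired iff
   `d_k ≤ −0.80` SD (inclusive, one-sided). Labels: `no-domain`, one of
   the four domain names, or `multiple` — six potential subgroups.
3. **Subgroup genetics** — carrier contingency tables by subgroup
   (Pearson chi-square, df adjusted for empty subgroups); per-subgroup vs
   shared-control additive-dosage logistic scans with age/sex/PC
   adjustment (Wald tests); inverse-variance fixed-effect meta-analysis
   with Cochran's Q, I², and direction strings; suggestive-locus
   selection at `p < 1e-5` with pooled OR outside `(0.77, 1/0.77)`
   outside chromosome 19.
4. **Risk-score evaluation** — weighted allele scores; nested logistic
   models compared by a 5-df likelihood ratio test with McFadden
   pseudo-R²; paired DeLong comparison of ROC AUCs.

A synthetic multi-study generator with planted truth (subgroup mixture,
carrier enrichment, per-subgroup SNP odds ratios via exponentially tilted
Hardy–Weinberg sampling) makes every stage testable without access to
restricted participant-level data.

## Worked example

Classify three hand-made score profiles (reference-metric SD units):

```r
library(cogsub)
sc <- data.frame(person_id = c("p1","p2","p3"), study = "act",
                 memory = c(-1.2, 0.0, -1.6), executive = c(0.1, 0.0, -1.6),
                 language = c(0.1, 0.0, 0.0), visuospatial = c(0.2, 0.0, 0.0))
asg <- assign_subgroups(sc, delta = 0.80)
asg[, c("person_id","label","mean_score","d_memory","d_executive")]
#>   person_id     label mean_score d_memory d_executive
#> 1        p1    memory       -0.2     -1.0         0.3
#> 2        p2 no-domain        0.0      0.0         0.0
#> 3        p3  multiple       -0.8     -0.8        -0.8
```

`p1`'s memory score sits 1.0 SD below their own mean (≤ −0.80, no other
domain qualifies): isolated memory impairment. `p3` has two deviations at
exactly −0.80 — the threshold is inclusive, so they are `multiple`.

Run the bundled end-to-end configuration (2 studies × 600 persons, 200
SNPs with planted memory/visuospatial/language effects) from simulation
through calibration, classification, scans, meta-analysis, selection, and
risk-score evaluation:

```r
man <- run_pipeline(example_pipeline_config(seed = 1), "out/")
str(man$results)
#> List of 9
#>  $ distribution_chisq: num 6.79
#>  $ distribution_df   : int 5
#>  $ apoe_overall_chisq: num 19.5
#>  $ apoe_overall_p    : num 0.00155
#>  $ n_suggestive      : int 2
#>  $ lr_stat           : num 49.9
#>  $ lr_df             : int 5
#>  $ auc_reference     : num 0.575
#>  $ auc_subgroup      : num 0.64
```

The planted carrier enrichment in the memory subgroup shows up as the
carrier-by-subgroup chi-square (19.5 on 5 df); two of the planted
extreme-OR SNPs reach the suggestive thresholds at this sample size; and
the five subgroup risk scores add strongly to the reference score
(LR = 49.9 on 5 df), with the subgroup-score model's AUC (0.64) above the
reference-score model's (0.575). Every stage artifact (scores,
assignments, association and meta TSVs, weights, manifest with checksums)
is written under `out/`. A thin CLI wrapper lives at
`inst/cli/cogsub.R` (`simulate` and `run` subcommands).

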