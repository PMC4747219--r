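# sagprisk

Survival-based screening and risk stratification for sense-antisense gene
pairs (SAGPs) — pairs of protein-coding genes transcribed from opposite
strands of a shared locus.  The package is for computational biologists
studying whether co-expressed gene-pair architectures carry prognostic
information in tumor cohorts: it screens pairs by partner correlation,
fits survival-optimal two-dimensional expression partitions, selects a
cross-cohort reproducible pair signature, stratifies patients by majority
voting, and runs the downstream differential-expression, enrichment,
promoter-overlap and copy-number comparisons.

## The method in brief

For a pair with standardized expression $(x, y)$, two cutoffs
$(c_1, c_2)$ on (optionally rotated) axes split the plane into four
quadrants.  A **design** assigns a non-empty proper subset of quadrants to
the high-risk sector — there are 7 such bipartitions (14 sub-designs); the
unrotated variant uses the 5 designs needing both cutoffs (10
sub-designs).  The **rotated search (2-D RDDg)** scans 16 angles
(0°–84.375°, step 5.625°) × designs × a 17-point quantile grid per cutoff
and keeps the configuration minimizing the Wald p-value of the binary Cox
model (Breslow ties)

$$\lambda(t \mid g) = \lambda_0(t)\, e^{\beta g}, \qquad
  g \in \{0 (\text{LR}), 1 (\text{HR})\},$$

subject to a minimum group size per side.  A pair enters the **signature**
when a per-cohort trained optimal configuration, held fixed, is
significant (Wald p < 0.05) and synergistic (better than both partners'
1-D groupings) in every training cohort.  Patients are classified by the
**predominant vote** over the signature's pairs, most significant pair
breaking ties.  Between the voted subgroups the package computes Welch-t
differential expression with Storey q-values, hypergeometric gene-set
enrichment, Fisher tests of ChIP-peak overlap with strand-aware −450/+50 bp
proximal promoters (with the bidirectional-promoter doubling rule for
divergent pairs), and per-gene SNP copy-number means compared by the
Wilcoxon signed-rank test.

A fully seeded synthetic-cohort generator with exported ground truth
(`simulate_study()`) makes every stage testable without external data.

## Worked example

```r
library(sagprisk)

st  <- simulate_study(simulation_config(seed = 11))  # 2 cohorts, 24 pairs
run <- run_pipeline(st$cohorts, st$pairs, mode = "RDDG2D")
print(run)
#> <sagp_run> 2 cohorts (training: cohort1, cohort2)
#>   pairs: 24 input -> 24 screened -> 11 in signature
#>   cohort1: WVG Wald p = 4.55e-18, accuracy = 69.2%, HR/LR = 91/159
#>   cohort2: WVG Wald p = 2.15e-20, accuracy = 74.0%, HR/LR = 86/164
#>   DEGs common across cohorts: 24 (100% up in HR)
```

Of the 24 simulated pairs (12 carrying survival signal, 12 controls), 24
pass correlation screening, and 11 survive cross-cohort signature
selection — 10 true signal pairs plus one control.  The majority-vote
stratification separates the survival curves with Wald p around 1e-18
(the generator's high-risk sector has log hazard ratio 1.5), and 69–74%
of patients' voted classes match their observed event indicator.  The
signature table (`run$signature`) lists each selected pair's design,
rotation angle, quantile-scale cutoffs and per-cohort p-values — the
parameters that transfer to new cohorts via `apply_model()`.

A thin command-line front end wraps the same functions:

```sh
inst/cli/sagp-risk simulate --config cfg.yaml --out data/
inst/cli/sagp-risk run      --config run.yaml --out results/
```

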