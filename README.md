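# MutDomains

Recurrent somatic mutation analysis on protein domains.

Tumour cohorts accumulate somatic mutations across the exome, and most of
them are passengers. One way to find the functional units that drive a
cancer is to step below the gene level: map every coding, non-synonymous
mutation onto the protein **domains** it hits — both sequence-defined
(Pfam-style) and structure-defined (CATH-style) annotations — and ask which
domains collect more mutations than their length alone would explain.
MutDomains implements that analysis end to end for people working with
MAF-like mutation tables: genomic-to-residue mapping, the binomial
recurrence test, per-cancer and pan-cancer candidate calling, patient
coverage, cancer-type specificity, grouped gene-set tests, and Pfam/CATH
region-overlap summaries. A seeded synthetic-cohort generator stands in for
patient-level data, so every stage is testable offline.

## The model

Under the null, mutations are independent and uniform over the analysed
universe (all domain residues for domain tests, all coding residues for
gene tests). A region of length `l_i` inside a universe of total length `L`
then receives each of the `n` observed mutations with probability
`p_i = l_i / L`, so its count is binomial:

    Pr(X = k_i) = C(n, k_i) p_i^k_i (1 - p_i)^(n - k_i)

Everything is evaluated in log space — `log Pr(X = k)` via a
Stirling-series log-factorial with an exact small-argument fallback — so
cohorts with millions of mutations never overflow. A region is a
**candidate** when its upper-tail probability `P(X >= k_i)` falls below the
Bonferroni-corrected level `alpha / m`, where the family size `m` is
(number of regions) x (number of cohorts, the per-cancer cohorts plus one
pan-cancer union cohort) and `alpha = 0.05` by default.

Derived quantities follow the same conventions used in domain-level cancer
studies: a candidate domain *covers* a patient when the patient has at
least one mutation inside it; a candidate is *specific* to a cancer type
when no other individual type calls it; a protein is a *specific protein*
of a type when all of its candidate domains are specific to that type and
at least one of them is mutated there.

## Worked example

Simulate a two-cancer cohort with a 40-fold enrichment planted on domain
`PF00003`, run the domain test on the pan-cancer cohort, and look at the
top of the table:

```r
library(MutDomains)

cfg <- syntheticConfig(nGenes = 30, patientsPerCancer = 30,
                       plantedEnrichments = c(PF00003 = 40), seed = 11)
models  <- generateGeneModels(cfg)
domains <- generateDomainAnnotations(models, cfg)
cohortT <- generateCohort(models, domains, cfg)

recs    <- filterCodingNonsynonymous(cohortT, models)
cohorts <- buildCohorts(recs, models, domains)
m <- length(unique(domains$domain_id[domains$source == "PFAM"])) *
     length(cohorts)
res <- testDomains(cohorts[["pan-cancer"]], domains, "PFAM", m = m)
head(res[order(res$p_upper), ], 3)
#>    region_id  l    L   n   k      p p_upper  m alpha candidate
#> 3    PF00003 57 1562 733 439 0.0365   0.000 60  0.05      TRUE
#> 11   PF00011 39 1562 733  11 0.0250   0.975 60  0.05     FALSE
#> 4    PF00004 67 1562 733  20 0.0429   0.989 60  0.05     FALSE

patientCoverage("PF00003", cohorts[["pan-cancer"]])
#> [1] 100
```

The planted domain spans 57 of the 1562 domain residues (`p = 0.0365`) yet
collects 439 of the 733 in-domain mutations, so its upper-tail probability
is far below `0.05 / 60` and it is the only candidate; it covers 100% of
patients. The `pipelineSimulate()` / `pipelineRun()` / `pipelineOverlap()`
/ `pipelineReport()` functions run the same steps from TSV files to TSV
results (candidate tables, bipartite cancer-to-region edges, coverage and
specificity summaries, a run-log of every family's `n`, `L`, `m` and
`alpha/m`); `inst/scripts/mutdomains.R` wraps them as shell subcommands.

Region overlap uses union-then-intersect interval arithmetic. For a
protein with nested CATH-style occurrences at residues 102-176 and 1-176
and a Pfam-style domain at 10-145:

```r
proteinOverlap("VPS25", ann)[, c("gene", "overlap_len",
                                 "pct_of_cath_rounded",
                                 "pct_of_pfam_rounded")]
#>    gene overlap_len pct_of_cath_rounded pct_of_pfam_rounded
#> 1 VPS25         136                  77                 100
```

The overlap (residues 10-145, 136 residues) covers 77% of the 176-residue
CATH region and 100% of the Pfam region.

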