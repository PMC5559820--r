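---
title: "Detecting recurrently mutated protein domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrently mutated protein domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MutDomains)
```

## The problem

A tumour cohort's somatic mutations are dominated by passengers. Gene-level
recurrence tests dilute the signal of a small functional unit inside a long
gene; domain-level analysis asks instead which protein domains — Pfam-style
sequence families or CATH-style structural superfamilies — collect more
non-synonymous mutations than their residue length would predict, per
cancer type and in a pan-cancer union cohort. MutDomains implements that
analysis as composable pieces: tabular IO, genomic-to-residue mapping, the
binomial recurrence test, cohort orchestration, region-overlap arithmetic,
and a synthetic-cohort generator used throughout the test suite.

## The statistical model

Under the null hypothesis, mutations are mutually independent and uniform
over the analysed universe. For domain tests the universe is the set of
all domain residues of one source, so a domain with summed occurrence
length $l_i$ out of a total $L$ receives each of the $n$ in-universe
mutations with probability $p_i = l_i / L$, and its count $k_i$ is
binomial:

$$\Pr(X = k_i) = \binom{n}{k_i} p_i^{k_i} (1-p_i)^{n-k_i}.$$

For gene tests, $l_i$ is the gene's coding length in residues and $L$ the
total coding length of all modelled genes; $n$ counts all filtered coding
mutations. Lengths are in amino-acid residues throughout, so $p_i$ is
scale-free — nucleotide units would give identical ratios.

A region is a candidate when its upper-tail probability $P(X \ge k_i)$
falls below the Bonferroni-corrected level $\alpha/m$ with $\alpha = 0.05$
(configurable). This upper-tail form is the corrected version of the
equivalent rejection rule "lower tail $P(X < k) > 1 - \alpha$": dividing
the rejection criterion by $m$ only acts on the tail probability, so the
corrected test compares $P(X \ge k)$ with $\alpha/m$. The lower tail is
defined with the strict inequality $P(X<k)=\sum_{j=0}^{k-1}\Pr(X=j)$; the
boundary case ($P(X \ge k)$ exactly equal to $\alpha/m$) is treated as not
significant, a convention the strictly-less form leaves open.

The family size $m$ is (number of regions tested) $\times$ (number of
cohorts). The pan-cancer union is deliberately counted as one additional
cohort — with 29 cancer types that yields the characteristic $\times 30$
family factors (e.g. $37 \times 30$ mitochondrial genes, $6 \times 30$
complexes, $182 \times 30$ stem-cell genes, $174 \times 30$ DNA-repair
genes, $30 \times 759$ CATH and $30 \times 6009$ Pfam domains at full
scale). `pipelineRun(familySize = "auto")` reproduces this pattern for
synthetic universes of any size; the run-log records every family's $n$,
$L$, $m$ and $\alpha/m$.

### Numerical evaluation

All probability mass is computed in log space,
$\log\Pr(X=k) = \log\binom{n}{k} + k\log p + (n-k)\log(1-p)$, so cohorts
with millions of mutations cannot overflow. The log-factorial is exact
(cumulative sums of logs) for arguments below 64 and a Stirling series
$n\log n - n + \tfrac12\log(2\pi n) + \frac{1}{12n} - \frac{1}{360n^3} +
\frac{1}{1260n^5}$ above, whose truncation error at $n \ge 64$ is below
$10^{-12}$; the test suite verifies $10^{-10}$ relative agreement with
exact values across $n \in [1, 10^7]$. One refinement matters for the
binomial coefficient: at $n \sim 10^6$ the difference
$\log n! - \log(n-k)!$ cancels two values of order $10^7$ and double
precision would leave only $\sim 10^{-9}$ absolute accuracy, so the
falling-factorial ratio is instead accumulated directly as
$\sum_{j=n-k+1}^{n}\log j$ (with $\log k!$ still from the Stirling
log-factorial), and contiguous runs of $k$ — the tail sums — telescope
through the pmf ratio $\frac{n-j}{j+1}\cdot\frac{p}{1-p}$ from one
accurately computed base term.

Tail sums are log-sum-exp accumulations. The upper tail is summed
*directly* over $j = k, \dots, j_{\max}$ rather than as
$1 - P(X<k)$: in the deep tail — exactly where candidates live — the
complement would cancel to zero at double precision. The summation stops
at $j_{\max} = \max(k, np) + 60\,\mathrm{sd} + 60$, beyond which terms are
below $e^{-40}$ of the largest retained term, far under the $10^{-9}$
relative accuracy the suite enforces against independent oracles
(`dbinom`/`pbinom`, which use different algorithms — Loader's saddle-point
pmf and the regularised incomplete beta function). When $k \le np$ the
result is dominated by bulk mass and $1 - P(X<k)$ is both accurate and
cheaper, so it is used there.

Degenerate inputs are defined, not errors: $k=0$ gives an upper tail of 1
(never a candidate); a single-region universe has $p=1$, forcing $k=n$ and
an upper tail of 1; $p \in \{0,1\}$ are handled as point masses.

## Mapping and counting conventions

* Coordinates are 1-based inclusive everywhere (MAF/UniProt convention),
  and one canonical transcript per gene is assumed; multi-transcript genes
  must be reduced upstream.
* A genomic position maps to residue $\lceil o/3 \rceil$, where $o$ is its
  1-based offset in the spliced, strand-oriented CDS; positions outside
  the CDS map to nothing (that is a valid result, not an error). The stop
  codon is excluded from protein length so residue coordinates align with
  domain annotations.
* Indels are assigned to the residue containing their start position; a
  multi-nucleotide event spanning a domain boundary therefore counts where
  it begins. This keeps counts well defined at the cost of ignoring the
  event's extent.
* A mutation inside occurrences of two different domain ids produces one
  hit per id; overlapping occurrences of the *same* id count once, so a
  domain's $k_i$ is never inflated by self-overlap. Correspondingly,
  $l_i$ is the *sum* of occurrence lengths (a domain present twice offers
  twice the target), and the domain-level $n$ counts only in-universe hits
  — mutations outside all domains of the source do not enter the
  domain-test sample space, which keeps $p_i$ a probability over the
  stated universe. The alternative reading (all coding mutations as $n$)
  would make $\sum_i p_i < 1$ with no compensating outcome class.
* `variant_class` is trusted from the input rather than recomputed from
  alleles; consequence calling is out of scope and MAF-like inputs carry
  the class already.

## Derived quantities

A candidate domain *covers* a patient if the patient has at least one
mutation in it; coverage is reported as a percent of all cohort patients
(including patients whose mutations were filtered out, when a patient
table is supplied). Cumulative coverage over a set of domains is a union,
not a sum. A candidate is *specific* to a cancer type when no other
individual type calls it — the pan-cancer cohort is excluded from the
exclusivity count because it is a union of the others, not a distinct
disease; with it included, almost no region could ever be specific. A
protein is a *specific protein* when every candidate domain it carries is
specific to the type and at least one of them is mutated there. Candidate
genes can be restricted to those containing at least one candidate domain;
the comparison against an external causal-gene list reports, per type, how
many causal genes carry domains, mutated domains, and candidate domains.

Pfam/CATH region overlap uses union-then-intersect semantics: each
source's occurrence intervals on a protein are coalesced, the two unions
intersected, and the intersection reported as a percent of each union.
This reading is what reproduces the canonical worked example (nested
structural occurrences at residues 102–176 and 1–176 against a sequence
domain at 10–145 give an overlap of 136 residues: 77% of the structural
region, 100% of the sequence region). Reported percentages are rounded
half-up to integers; full precision is kept for computation. The
per-dataset averages are unweighted means over proteins annotated by both
sources — length-weighted averaging is a defensible alternative, but the
per-protein mean matches the "average protein" framing of the summary
statistic.

## The synthetic-data generator

The generator emulates the statistical structure of a multi-cancer
whole-exome cohort without any patient data. Design choices, fixed once:

* One synthetic chromosome; genes laid end-to-end with 1000 nt intergenic
  gaps and 100 nt introns. Mapping correctness needs exon/strand/splice
  structure, not genome realism.
* Exons are whole numbers of codons, so CDS divisibility by 3 holds by
  construction; strand is random per gene.
* Per-patient mutation counts are Poisson; positions are uniform over
  coding positions. Planted enrichment multiplies the per-position
  sampling weight inside a domain's occurrences by the fold factor —
  mixture sampling with exact fold control, no rejection step.
* 25% of mutations are labelled synonymous (Bernoulli), giving the coding
  filter material to remove; non-synonymous classes split 9:1
  missense:nonsense.
* All randomness flows from the config seed; each generator stage seeds
  its own stream at a fixed offset, so models, annotations and cohorts are
  independently reproducible.

What the generator does *not* emulate — trinucleotide mutational
signatures, chromatin- or replication-timing covariates of mutation rate,
copy-number change, germline variation, isoform diversity — bounds what
green tests mean: they demonstrate correctness of the pipeline and
calibration of the test *under its own null*, not robustness of the
uniformity assumption on real exomes, where locally elevated background
rates can mimic enrichment.

## Problem sizes in the test suite

The suite checks calibration and power with simulations sized to keep the
whole run in a few minutes while leaving no interesting regime untested:
family-wise error control uses 200 replicate null families of 30 domains
across three cohorts ($m = 90$, roughly 600 mutations each), asserting the
observed family-wise rejection fraction stays below
$0.05 + 3\,\mathrm{SE}$; recovery uses 100 replicates of a 100-fold
enriched 100-residue domain inside a $10^5$-residue domain universe with
about 5000 in-universe mutations (recovered in at least 99 of 100, with
fold-1 domains flagged no faster than $\alpha/m$ allows); mapping is
verified exhaustively against an explicit spliced-CDS oracle on every
position of 50 randomized multi-exon genes on both strands.

## Limitations

The binomial null ignores regional mutation-rate heterogeneity, so on real
data the test is anti-conservative wherever the local background exceeds
the genome average; Bonferroni across regions x cohorts is conservative in
the other direction, and the pan-cancer cohort is not independent of the
per-type cohorts (the family treats it as one more member, as the x30
design does). Domain annotations are taken as given — no statement is made
about annotation completeness, and proteins lacking one source simply drop
out of overlap summaries. Hypermutated patients are not down-weighted; a
single ultra-mutated exome can dominate a small cohort's $n$.
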