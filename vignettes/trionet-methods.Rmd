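---
title: "Models and methods behind trionet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trionet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trionet)
```

trionet implements the computational core of a family-trio sequencing
study: calling de novo mutations from parent–offspring read counts,
filtering them with an empirically calibrated Bayes factor, summarising
the validated calls per cohort, testing gene lists for functional
enrichment, and searching a weighted gene–gene likelihood network for a
cohesive cluster among variant-hit genes. This vignette explains each
model, its assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## The de novo genotype model

A site in a trio is described by six numbers: total read depth and
alternate-supporting read count for father, mother, and proband.
Conditional on a genotype (coded by alternate-allele dosage: RR, RA,
AA), reads are independent draws carrying the alternate allele with
probability $\varepsilon$, $\tfrac12$, or $1-\varepsilon$, where
$\varepsilon$ is the per-read error rate (default 0.005). So the
genotype likelihood is binomial, and a site with no reads has
likelihood 1: no information.

`detect_candidates()` enumerates all 27 trio dosage configurations.
The two de novo configurations (both parents RR, proband RA or AA)
share a prior mass of `denovo_prior` (default $10^{-4}$ per site; real
per-base de novo rates are far smaller, but candidate sites are already
pre-selected by a caller, so the prior acts as a tunable stringency
knob, not a genome-wide rate). The Mendelian-consistent configurations
share the complementary mass uniformly; other violations — dropout-like
patterns where the proband's alleles all exist in the parents but no
transmission explains them — get no prior mass, since they are evidence
of artifact rather than mutation. A site is a candidate when the
posterior odds of de novo versus Mendelian exceed 1. The implementation
is checked against an independent brute-force enumeration of the same
27 cells in the test suite.

Assumptions worth stating: reads are independent given genotype (no
mapping correlation, no strand artifacts — those are meant to be
captured by the downstream QC-feature filter); error symmetric between
reference and alternate; diploid genotypes everywhere, so sex
chromosomes in males are approximated. `classify_trio_genotypes()`
applies the same transmission logic to called allele-pair genotypes and
distinguishes de novo heterozygous, de novo homozygous, and dropout-like
Mendelian violations.

## Empirical calibration and the log Bayes factor

Candidate lists at this stage are dominated by artifacts. The filter is
a naive-Bayes classifier trained on calibration sites where an
orthogonal genotyping array provides truth: *concordant* sites (array
and exome agree) stand in for true calls, *discordant* sites for false
ones. For each QC feature the two classes get binned empirical
densities — by default 20 equal-width bins with a Laplace pseudocount of
0.5 per bin, which keeps every bin mass positive and therefore every
log ratio finite. Densities are estimated separately per coverage
stratum (quartiles of mean site depth by default, since most QC metrics
drift with depth) and per heterozygous/homozygous call (allele-balance
features behave completely differently in the two classes). Cells with
no data in either class fall back to pooled, unstratified densities
rather than failing. Calibration classes are pooled across cohorts; the
package takes whatever labeled table it is given, so a per-cohort
calibration is a matter of subsetting the input.

The score of a site is the naive-Bayes log Bayes factor
$$\log \mathrm{BF} = \sum_{f}
\log \frac{\hat p(x_f \mid \text{concordant})}
          {\hat p(x_f \mid \text{discordant})},$$
in natural log (the log base is a presentation choice; thresholds
quoted in this package are natural-log values). Feature independence is
the usual naive-Bayes idealization — correlated features double-count
evidence, which is acceptable for a ranking score but means the
absolute value of the score should not be read as a calibrated
probability.

`calibrate_threshold()` converts the score into a decision rule: the
smallest threshold $t$ such that among sites scoring at least $t$, the
proportion of discordant sites is at most the target (default 5%). Note
one subtlety of this rule: when the true class is large, the loosest
acceptable cut may legitimately admit a handful of false sites while
staying under the target; the realized false-positive proportion
converges to the target from below as the calibration set grows, which
is exactly the property verified out-of-sample in the test suite. The
default hard filters retain candidates with $\log \mathrm{BF} \ge 3$
and minimum trio depth $\ge 20$, both boundaries inclusive for
retention.

## Cohort summary tables

`read_variant_table()` parses a validated-variant TSV — the package
ships an 88-record table of Sanger-validated de novo mutations from
three schizophrenia trio cohorts (75 Algerian, 45 French, and 61
Japanese families) — normalising chromosome labels (`chr10` equals
`10`), locus-style positions, and damage-class spellings. Summaries
follow the conventions of the printed tables they reproduce:

* percentages are rounded half away from zero (every printed cell
  matches this rule, while round-half-to-even does not);
* chromosome percentages use a denominator of 23 (22 autosomes plus X;
  no Y-linked calls occur), and the "any mutation" percentage is
  computed from the unrounded count, so rounded components can differ
  from the rounded total by one point;
* the PolyPhen-2 triage thresholds default to 0.94 and 0.446. These are
  reverse-engineered from the shipped table's score/label boundaries
  (0.947 is labeled probably damaging and 0.929 possibly; 0.478
  possibly and 0.414 benign). Neither the predictor's HumDiv nor HumVar
  cut-offs reproduce the labels, so the package documents its own cuts
  and leaves both configurable;
* the patient-level table cannot be derived from the variant table,
  which carries no patient identifiers; `patient_distribution()`
  therefore accepts per-cohort patient counts (defaulting to the
  study's printed ones, see `sz_cohort_families()`) and derives counts
  from records only when a `patient_id` column exists.

## Network cluster search

The likelihood network is an input: a weighted undirected gene graph
whose edge weight scores the evidence that two genes share a phenotype.
Building such a network from functional-genomics features is out of
scope here; the package consumes a three-column edge list.

Search units are *events*: an SNV event carries one gene, a CNV or GWAS
locus carries a gene set of which at most one member may enter a
cluster (otherwise a single multi-gene locus could masquerade as a
cluster by itself). The cluster score is the weighted sum of
within-cluster edges. `greedy_search()` starts from every event gene as
a seed and repeatedly adds the gene, from events not yet represented,
with the largest connection to the current set, recording the best set
of each size up to `k_max`. Ties are broken by lexicographically
smallest gene symbol so the search is fully deterministic. Greedy
growth is a heuristic: its score never exceeds the exhaustive optimum,
and on small planted-structure instances (checked exhaustively up to 12
nodes in the tests) it attains it.

Significance is by permutation: each permutation replaces every event's
genes with a random same-sized set of network genes — preserving the
number of events and the genes-per-event structure — and reruns the
identical search. Uniform sampling is the default; a weighted-degree
decile-matched sampler is available for networks whose hubs would
otherwise dominate the null. The empirical p-value uses the add-one
rule $p = (1 + \#\{S_{\text{null}} \ge S\})/(1 + B)$, so $p$ is never
zero and is exactly uniform under exchangeability; the z-score
standardises the observed score by the null mean and standard
deviation. `best_network()` tests every size $2 \le k \le k_{\max}$
from one common set of permutations, Bonferroni-adjusts across the
tested sizes, and selects the size with minimal adjusted p, breaking
ties by maximal z and then by smaller size. Bonferroni was chosen over
FDR because the per-size hypotheses are strongly dependent (nested
clusters) and only one size is ultimately reported. For reporting,
`report_interactor_expansion()` augments the selected cluster with its
direct interactors from a physical-interaction edge list, optionally
restricted to genes in given annotation classes.

## Enrichment statistics

`hypergeometric_tail()` computes the one-sided upper tail
$P(X \ge k)$ by log-space summation of `lchoose` terms, exact to
machine precision even for tails far below double underflow of the
individual factors; the test suite requires agreement with direct pmf
summation to $10^{-12}$ relative error. `ease_score()` is the
conservative DAVID-style variant with the overlap jackknifed by one,
and is the default statistic of `annotation_chart()` because the
study-style chart it mirrors uses it; plain Fisher is one argument
away. Adjustment defaults to Benjamini–Hochberg across reported terms.
The background universe is always user-supplied — enrichment p-values
are only meaningful relative to an explicit universe. Annotation sets
come from GMT files; no ontology-graph propagation is performed, so
parent terms are only tested if present in the collection.
`composition_test()` is a one-sided Fisher exact test for 2×2
variant-type composition questions, and `venn_overlap()` reports all
Venn-partition cardinalities plus per-list hypergeometric overlap
p-values against a reference set.

## Synthetic data: what it emulates and what it does not

The generators in `sim_config()` exist so that every stage has inputs
with known ground truth:

* `simulate_trio_reads()` — Poisson(40) depths, binomial alt counts,
  de novo events planted at rate 0.01 among sites segregating an
  inherited variant at allele frequency 0.2. Defaults mirror a
  desk-scale version of a trio study (deep exome coverage, a
  candidate-site de novo fraction of about 1%), not a whole exome.
* `simulate_calibration_features()` — Gaussian QC features with
  class-dependent location/scale (default: a two-standard-deviation
  separation), Poisson coverage, random het/hom flags.
* `simulate_labeled_scores()` — the two-Gaussian score mixture (true
  scores Normal(4, 1), false Normal(0, 1), equal proportions) used to
  exercise threshold calibration end to end.
* `simulate_likelihood_network()` — an Erdős–Rényi background (150
  genes, edge probability 0.05, exponential weights) with a fully
  connected 12-gene module whose weights are tripled; the module is the
  recoverable signal at the default signal-to-noise ratio.
* `simulate_events()` and `simulate_annotation_sets()` — events over
  the network genes, and a 50-term annotation collection over a
  2000-gene universe with one term's genes over-sampled five-fold in a
  companion list.

A single root seed is split deterministically per generator, so one
seed reproduces an entire input tree bit for bit. What the generators
do *not* emulate: real exome coordinates and mutational spectra,
linkage and haplotype structure, batch effects between cohorts,
scale-free topology of real interaction networks, or the correlated,
heavy-tailed QC features of real sequencing. Passing tests on synthetic
data therefore demonstrate the correctness and calibration of the
algorithms under their stated models, not their performance on any
particular real dataset.

## Numerical choices and problem sizes

All probability arithmetic is in log space with a shared
log-sum-exp helper. Degenerate inputs are defined rather than left to
chance: zero-depth sites have likelihood 1; a degenerate permutation
null (zero standard deviation) yields z = 0 while the counting p-value
remains valid; a constant feature gets an artificial unit-width bin
range; empty and singleton clusters score 0. The test and verification
workloads are sized for a single CPU: 10,000 sites for calibration
checks, 200 replicates for the p-value uniformity test, permutation
counts of 99–200, and exhaustive-search oracles up to 12 nodes; all
statistical assertions use fixed seeds and tolerance bands derived from
binomial or Kolmogorov–Smirnov sampling theory at those sizes.

## Known limitations

The caller assumes a clean diploid binomial model and makes no attempt
to model systematic artifacts itself — that burden is on the calibrated
QC filter, which in turn is only as good as the labeled calibration
set. The greedy search can miss adversarial optima that exhaustive
search would find at larger sizes. Published cluster results from real
studies depend on their specific background network and gene universe;
with a different network the search will find different clusters, which
is why the package treats the network strictly as data.
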