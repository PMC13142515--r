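---
title: "From GWAS credible sets to drug-target genetic support: the pleiomap methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS credible sets to drug-target genetic support: the pleiomap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiomap)
```

# Overview

`pleiomap` is a desk-scale implementation of the analysis chain that turns
GWAS summary statistics into drug-target evidence: harmonised 95% credible
sets, colocalisation between disease and molecular-QTL signals,
locus-to-gene (L2G) prioritisation, variant- and gene-level pleiotropy
scores, and enrichment of genetic support among clinically successful
target–indication pairs. Consortium-scale inputs are replaced by a seeded
synthetic-cohort generator that plants known causal variants, pleiotropic
genes and clinical outcomes, so every stage can be tested against a truth
table. This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic cohort does and
does not emulate.

# Effect rescaling and detection power

Marginal effects arrive on heterogeneous scales across studies, so the
pipeline re-estimates them from p-values. With $Z$ the square root of the
complementary $\chi^2_1$ quantile of the association p-value, the standard
error is approximated from the study design,

$$\widehat{SE}_{logit} = \frac{1}{\sqrt{2\,n\,f(1-f)\,K(1-K)}}, \qquad
  \widehat{SE}_{lm} = \frac{1}{\sqrt{2\,n\,f(1-f)}},$$

where $n$ is the sample size, $f$ the major-ancestry MAF of the lead
variant and $K$ the case proportion; the rescaled effect is
$\hat\beta_{resc} = \widehat{SE}\cdot Z$. P-values at genome-wide
significance routinely underflow double precision, so `rescale_effect()`
also accepts $\log_{10}p$ and evaluates the quantile in log space; a
p-value of $10^{-400}$ still yields a finite $Z$.

Detection power for a variant uses the non-central $\chi^2_1$ tail beyond
the central $1-10^{-8}$ quantile with

$$NCP = \beta_{max}^2 \cdot N_{eff,max} \cdot 2\,f_{max}(1-f_{max}) / 11.$$

The divisor 11 scales the maximal observed effect down by roughly an order
of magnitude: the quantity models the chance of detecting this variant's
*other* trait associations, assumed much weaker than its strongest one. The
divisor is an argument (`divisor = 11` by default; `divisor = 1` gives the
variant's own detection power, which is what the synthetic generator uses
when calibrating planted effects). Effective sample size is not defined by
the upstream method description, so the package uses the standard GWAS
convention $4/(1/n_{cases}+1/n_{controls})$ for binary traits and $n$ for
quantitative traits.

# Locus definition and PICS fine-mapping

Three clumping strategies are implemented. Distance clumping absorbs all
variants within ±500 kb of the most significant remaining genome-wide
significant variant. LD clumping absorbs variants with $r^2 \ge 0.5$ to the
current top, greedily by significance (deliberately *not* a transitive
closure). The locus-breaker first distance-clumps to obtain lead SNPs, then
chains sub-threshold variants ($p < 10^{-5}$) within 250 kb, keeps chains
containing a genome-wide significant variant, and splits chains longer than
1.5 Mb around the lead SNPs into ±750 kb sub-loci, so every emitted locus
spans at most 1.5 Mb. Ties in "most significant" are broken by larger
$|\hat\beta|$ and then variant id, making all three strategies
deterministic.

PICS assigns causal probabilities to the lead's LD proxies
($r^2 \ge 0.5$) from the lead's significance $S = -\log_{10} p$ alone. A
proxy's expected significance is $r^2 S$ with spread
$\sqrt{1-r^{6.4}}\,\sqrt{S}/2$. The cited approximation leaves the exact
probability rule open; evaluating a normal *density* at $S$ is unbounded as
$r^2 \to 1$, so the package uses the bounded two-sided tail probability

$$w_i = 2\,\Phi\!\left(-\frac{|S - r_i^2 S|}{\sigma_i}\right),$$

which gives the lead exactly weight 1, makes perfect proxies tie with the
lead, and is monotone in $r^2$. Weights are normalised over the proxy set
(configurable; the alternative of normalising over the full ±500 kb locus
is equivalent up to the proxy restriction), and the 95% credible set is the
smallest prefix in descending probability reaching 0.95. The LD-decay
exponent (6.4 on $r$) is configurable; a dual, independently coded
transcription of the weighting pins whatever is configured in the tests.

# Colocalisation

Credible-set pairs sharing at least one variant are candidate
colocalisations. Two statistics are computed. CLPP is the sum over shared
variants of the product of the two sets' PIPs; it needs no summary
statistics beyond the sets themselves and is significant at
$\ge 0.01$. The five-hypothesis posterior combines per-variant Wakefield
approximate Bayes factors over the shared region, enumerating
single-causal-variant configurations; $H_4 \ge 0.8$ is significant. Priors
default to $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ with prior effect
standard deviation 0.15 (quantitative) or 0.2 (binary) — the canonical
defaults of the method family — and are configurable. Fewer than two shared
region variants yields an "unknown" record rather than a number. Effect
directions are compared after aligning both signals to one effect allele
(flipping the second beta when the alleles are swapped); strand-ambiguous
A/T and C/G pairs at MAF > 0.4 and magnitude-only records are excluded as
"unknown".

# Qualification, replication and therapeutic areas

Noise control mirrors the production rules: disease studies qualify when
binary with $n > 1000$ and in-study prevalence above 0.1% (prevalence is
$n_{cases}/n$ since no external prevalence source exists at desk scale);
measurement studies when quantitative and not protein/microbiome traits.
Credible sets additionally need minor allele count $2\,n\,\mathrm{MAF} \ge
20$ and $|\hat\beta_{resc}| < 3$; rare leads (MAF < 1%) must also show a
significant molQTL colocalisation, a protein-altering variant in the set,
or replication. Replication requires the lead–trait pair to recur in a
different cohort, publication or ancestry group (GWAS), or the lead–gene
pair to recur anywhere (molQTL). Multiple impact predictions per variant
collapse to the most severe of PAV > promoter > enhancer > intragenic >
intergenic. Therapeutic areas are assigned by ancestor traversal of the
trait ontology against a shipped, totally ordered 23-area hierarchy
(oncology first, `other` as the fallback); the production mapping table is
not reproduced, so the ordering is a documented package default.

# Locus-to-gene model

Each credible set is paired with the genes within ±500 kb of its region and
described by 28 features: 12 individual features (sentinel and PIP-weighted
mean distance scores to TSS and gene footprint with score
$1 - \min(d, 500\mathrm{kb})/500\mathrm{kb}$; maximal CLPP and $H_4$
against eQTL, pQTL and sQTL sets of the gene; PIP-weighted mean and maximal
pathogenicity), their 12 neighbourhood counterparts (individual value
divided by the per-set maximum, zero when the maximum is zero), candidate
gene counts (all and protein-coding, deliberately unscaled), a
credible-set-confidence tier, and a nearest-protein-coding-gene indicator.
The exact production roster lives in supplementary material not reproduced
here, so this roster is an interpretation and is config-driven; the tests
pin its behaviour, not a claim about the original feature list.

Training positives are credible-set × gene rows matching a gold-standard
(gene, trait) pair; negatives are the other protein-coding genes on the
same set. The 80/20 train/test split is by unique positive genes so no
positive gene spans partitions. The classifier is a gradient-boosted tree
ensemble (xgboost) with a small depth/learning-rate/rounds grid selected by
cross-validated average precision under a fixed seed. Selection takes all
genes scoring ≥ 0.5 per credible set, falling back to the top gene if it
scores ≥ 0.1.

# Pleiotropy scores

Disease credible sets are clustered by an iterative rule seeded at the
smallest lead p-value: pull in sets significantly colocalised with any
member, take the union of member lead variants, pull in sets sharing one,
and repeat to a fixed point. Re-testing colocalisation against newly added
members (full fixed point) was an open choice; the package does so, which
makes the partition equal to the connected components of the union relation
— a property the tests verify against an independent graph-reachability
oracle. The variant-cluster pleiotropy score (vPS) is the number of unique
diseases in the cluster; the gene score (gPS) is the union of diseases over
all credible sets prioritised to the gene; therapeutic-area counts are the
analogous unions. Direction concordance is the largest fraction of
same-sign effects (0.5–1, and 1 for single associations).

Count models for vPS/gPS covariates use negative-binomial GLMs
(log link) on min–max scaled covariates, with a Poisson fallback when the
dispersion estimate diverges (small synthetic cohorts make this common),
reporting Pearson $R^2$ of predicted versus observed and per-covariate
$R^2$ deltas. Gene-set enrichment is a logistic regression of set
membership on $\log_2(\mathrm{gPS})$ over the disease-associated-gene
background, Wald-tested and BH-corrected. Tissue specificity follows the
HPA-style rules (enriched ≥ 4-fold over every other tissue → 1; group of
2–5 enriched → 0.75; enhanced over the mean → 0.5; else −1; binary = score
> 0.75).

# Clinical translation

Genetic evidence attaches to a target–indication pair when the evidence
trait exactly matches the indication or is one of its ontology descendants.
Propagation direction was an open choice: evidence on *descendants* of the
indication counts (capturing more specific diagnoses), ancestors do not,
to avoid over-propagation; the direction is configurable through the edge
table supplied. Oncology indications are excluded before modelling.

Enrichment uses the 2×2 table of support against approval: the sample odds
ratio $ad/bc$, the relative success
$P(\mathrm{approved}\mid\mathrm{support}) /
P(\mathrm{approved}\mid\mathrm{no\ support})$, and the two-sided Fisher
exact p-value. With a zero cell the conditional-MLE estimate (0 or $\infty$
in the limits) replaces the sample OR, avoiding ad-hoc 0.5 corrections in
headline numbers; confidence intervals use the log-scale normal
approximation. Strata are compared with a logistic model on two binary
predictors and a t-test on the coefficient difference (identical strata
are reported as difference 0, p 1, since the model cannot separate
perfectly collinear predictors); non-linear pleiotropy effects use nested
logistic models in $\log(\mathrm{count}+1)$ and its square, compared by
likelihood-ratio tests, with percentile-bootstrap bands over 200 seeded
resamples and a LOWESS curve (span 0.6, fixed). Phase-transition
probabilities per pleiotropy group (Low = 1 TA, Medium = 2–5, High = ≥ 6)
carry Wilson 95% intervals and BH-corrected pairwise two-proportion tests.
The strict-support flag is PAV support with a therapeutic-area count
between 2 and 5.

# The synthetic cohort

The generator is the package's study design, not a tuning dial. Defaults:
30 LD blocks of 1 Mb with 60 variants and 3 genes each; AR(1)-style signed
LD ($r_{ij} = s_i s_j \rho^{|i-j|}$, $\rho = 0.9$), which is positive
definite by construction with a nearest-PSD projection guarding numerical
degeneracy; MAF from $0.5 \times \mathrm{Beta}(0.8, 2.5)$ floored at
$5\times10^{-4}$ (no quantitative spectrum is published for the real
cohorts, so this is a documented free parameter, not a calibration); 12
disease, 6 measurement and 10 molQTL studies with 50–200k participants;
per-population allele frequencies drifted on the logit scale
($\sigma = 0.1$) so rare frequencies survive annotation.

Planted effects follow $|\beta| \propto (2f(1-f))^{-\alpha}$ with
$\alpha = 0.5$ by default, calibrated so the median-MAF signal reaches 95%
detection power. At $\alpha = 0.5$ the non-centrality is MAF-independent,
so every planted signal has the same detection power while the inverse
MAF–effect relation still holds — the one exponent that decouples the two
properties. Marginal z-scores follow the standard summary-statistic model
$z = R\lambda + \varepsilon$, $\varepsilon \sim N(0, R)$ per block, so the
planted variant reaches genome-wide significance exactly with the
non-central $\chi^2$ power at its own non-centrality, and LD proxies behave
realistically for PICS and CLPP without genotype simulation.

The pleiotropy plan plants one gene with 5 diseases, one with 3, one with
2, and unique genes for the rest, all diseases of a gene sharing its causal
variant so colocalisation can recover the sharing; 30% of planted genes are
"distal" (the causal variant sits near another gene, with pathogenicity and
molQTL evidence carrying the true assignment — this is what gives the L2G
model something to learn beyond proximity). The clinical generator draws
approval directly from the planted log-odds model
$\mathrm{base} + b_1\,\mathrm{support} + b_2 \log(uD+1) + b_3
\log(uD+1)^2$ and assigns non-approved records a maximal phase of 1–3 by
sequential Bernoulli transitions ($p_{I\to II} = 0.7$,
$p_{II\to III} = 0.55$). Drawing approval from the logistic model directly
(rather than as a bonus on the last transition only) makes the marginal
odds ratio recoverable as $e^{b_1}$, which is the property the recovery
tests measure.

What the cohort does *not* emulate: individual genotypes, recombination
maps, multi-ancestry LD admixture, linkage between blocks, realistic trait
ontologies (each synthetic disease maps directly to one therapeutic area),
or the scale of the real corpora. Passing tests therefore demonstrate that
the algorithms are implemented correctly and recover planted structure
under a faithful noise model — not that the package reproduces
consortium-scale empirical values, which depend on data this cohort cannot
stand in for.

# Problem sizes and determinism

All randomness flows from one root seed through named child streams
(`child_seed()`), so each stage is reproducible in isolation and the full
pipeline is byte-deterministic: re-running with the same configuration
reproduces identical output digests. The default demo cohort (~1,800
variants, 18 GWAS studies, 10 molQTL sets, 4,000 clinical records) runs end
to end in well under a minute on one CPU; recovery simulations in the test
suite use 30,000-record clinical pipelines over 100 seeds and 500-instance
oracle comparisons, sizes chosen to make the Monte-Carlo acceptance bands
tight while keeping the whole suite a few minutes long.

# Known limitations

- PICS here is a single-signal approximation; multi-signal loci are
  represented by whichever signal leads the clump (no SuSiE-style
  multi-credible-set decomposition).
- The five-hypothesis posterior enumerates single-causal configurations
  from summary-statistic Bayes factors; it does not consume SuSiE Bayes
  factors.
- Stage resumption is coarse: stages are cheap and deterministic, so
  `run_all()` recomputes rather than caching intermediate state beyond the
  written text outputs.
- The 23-area hierarchy and the 28-feature roster are documented package
  defaults standing in for production tables that are not public at desk
  scale; both are config-driven.
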