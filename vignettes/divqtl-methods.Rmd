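---
title: "Models and methods in divqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in divqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

divqtl is a toolkit for *cis*-QTL analysis in multi-ancestry cohorts:
populations nested in continental groups, expression and splicing
phenotypes, and the chain of analyses that follows — variance
partitioning, association scanning, fine-mapping, effect sizes,
frequency differentiation, effect-size heterogeneity, enrichment and
colocalization. This vignette explains the models, the tunable
parameters, the synthetic-data generator that every property test runs
against, and the numerical choices the package makes where the design
was genuinely open.

## The synthetic cohort

`sim_config()` describes a study; `simulate_study()` draws one. The
default cohort emulates a 1KGP-like design: 5 continental groups
holding 26 populations (7 + 4 + 5 + 5 + 5) of 28 samples each, with
sex assigned at random and sequencing batches stratified round-robin
within populations so that batch never confounds population.

**Genotypes.** Allele frequencies follow a nested Balding–Nichols
model: an ancestral frequency $p \sim U(0.05, 0.95)$ per variant, a
group frequency drawn from
$\mathrm{Beta}\!\big(p\tfrac{1-F_g}{F_g},\,(1-p)\tfrac{1-F_g}{F_g}\big)$
with $F_g = 0.10$ by default, and population frequencies nested the
same way with $F_p = 0.01$. Setting either $F$ to 0 collapses the Beta
draw to its parent frequency exactly. Haplotypes are Bernoulli draws
from the population frequency; each gene owns a disjoint 2-Mb cis
window of 200 variants (800 genes per chromosome, keeping positions
within integer range). The closed-form differentiation control is why
Balding–Nichols was chosen over a coalescent simulator: the expected
Hudson $F_{ST}$ between two groups is the configured $F_g$, which the
acceptance checks verify within ±0.02 at 2,000 variants.

Linkage disequilibrium is off by default (every variant independent)
and switched on with `ld = TRUE`: haplotypes are then copied in blocks
of 20 adjacent variants from a small panel of per-population template
haplotypes (6 templates, 2% per-allele copy error). Because each
population draws its own template panel, LD patterns — which variants
tag which — differ between populations and groups. This is a
deliberate caricature of real LD (no recombination maps, no decay with
distance), but it supplies the two features downstream stages need:
correlated candidates for the fine-mapper, and group-varying tagging
for the heterogeneity analyses.

**Expression.** Effect sizes are allelic fold changes. A causal
variant with effect $\beta = \log_2(\mathrm{aFC})$ multiplies its
haplotype's contribution by $2^{\beta}$; a haplotype carrying alleles
$a_k$ at causal variants $k$ contributes $\prod_k 2^{\beta_k a_k}$,
and the diploid mean is the average of the two haplotype
contributions. Around that genetic mean the generator applies a
per-gene baseline (log-uniform in 32–512 counts), per-gene batch and
sex factors ($\mathcal{N}(0, 0.2)$ on the log2 scale), optional
genotype-by-group interaction terms, log-normal noise (SD 0.5 in log2
units, optionally group-scaled for heteroskedastic cohorts), a
per-sample library size (log-uniform in 0.5–2×), and Poisson counting
noise (negative binomial with dispersion 0.1 behind a switch). Genes
carry 0–3 causal variants with probabilities (0.30, 0.40, 0.20, 0.10),
|β| uniform in [0.25, 2], and causal variants are drawn among variants
with pooled MAF ≥ 0.05 so the truth is identifiable at all.

One subtlety matters for the interaction analyses. The
haplotype-average model is *not* linear in dosage on the log scale:
heterozygotes sit at $\log_2\frac{1+2^\beta}{2}$, not $\beta/2$. A
linear genotype-by-group model applied to data from this mode reads
that dominance-like curvature — loaded differently in groups with
different allele frequencies — as weak effect-size heterogeneity
(about 6–8% rejection at a nominal 5% for |β| up to 2). That is model
misspecification in the test, not miscalibration of the F statistic,
so the generator also offers `expression_model = "log_additive"`, in
which the log2 mean is exactly additive in dosage. Calibration checks
and the "additive causal variants" heterogeneity experiments use the
additive mode; the aFC mode remains the default everywhere else.

**Splicing.** Every gene carries one cluster of 2–4 introns with
Dirichlet-distributed usage (concentrations uniform in 2–10). An sQTL
multiplies the target intron's concentration by $2^{\beta g}$; ratios
sum to one within cluster by construction.

**What the generator does not emulate:** realistic LD decay,
recombination, selection, admixture, trans effects, GC or length
biases, and any dependence between genes beyond shared library sizes.
Passing tests demonstrate that the estimators recover the truth under
this generative model — they bound implementation error, not
real-data behaviour.

## Phenotype preparation

Counts are normalized by median-of-ratios size factors against the
geometric-mean pseudo-reference (features containing any zero are
excluded from factor estimation) and stored as
$\log_2(x/s_j + 1)$. Before scanning, each feature is inverse-normal
transformed, $\Phi^{-1}\!\big(\tfrac{r - 0.5}{n}\big)$ with average
ranks on ties, and residualized by OLS on batch indicators, a sex
indicator and expression PCs (10 by default; hidden-factor correction
is configurable because the right count is cohort-dependent).
Residualization is idempotent and leaves residuals orthogonal to every
covariate; the covariate count is carried along to correct residual
degrees of freedom in the scan. Note that median-of-ratios factors
assume a mostly-null transcriptome: in simulations where a third of
genes shift two-fold in one group, the factors absorb part of the
shift and differential-expression calibration visibly degrades — the
package makes no attempt to repair that, it is a property of the
normalization itself.

## Variance partitioning

For each residualized feature the package fits two separate one-way
models — continental-group labels, then population labels — and
reports eta-squared (SSB/SST, in percent) for each. Because population
labels refine group labels, the population fraction is at least the
group fraction for every feature; the package asserts this instead of
decomposing a nested ANOVA, matching the two-separate-averages
reporting convention. Raw eta-squared of a null feature has
expectation about $(k-1)/(n-1)$ (0.8% for 5 groups at $n = 500$), so
the omega-squared-style adjusted fraction
$\big(SSB - (k-1)\,MSW\big)/\big(SST + MSW\big)$ is reported
alongside; recovery against simulator truth is checked on the
adjusted scale, where the target is met within ±2 points.

The permutation null permutes sample indices — population and group
labels move together, preserving nesting — and uses the across-feature
mean eta-squared as a single global statistic per label level, with
$p = (1 + \#\{null \ge obs\})/(1 + B)$. The heteroskedasticity test
models per-feature per-group sample variances ($N$ = features ×
groups observations) with a Gamma GLM, log link, group as the only
term, and an analysis-of-deviance LRT against the intercept-only model
($\chi^2$, df = groups − 1, one-tailed). The Gamma family is the
natural fit here because sample variances of Gaussian residuals are
scaled chi-squared, i.e. Gamma; this realization of "analysis of
deviance on variances" is an interpretive choice.

## Scanning and eGene calling

Candidates are variants within 1 Mb of the TSS (inclusive on both
ends) at sample MAF ≥ 0.01. The nominal scan is simple linear
regression of the prepared phenotype on dosage;
$t = r\sqrt{df/(1-r^2)}$ with $df = n - 2 - k$ for $k$ residualized
covariates. Gene-level inference uses the adaptive-permutation +
Beta-approximation scheme: permute the phenotype, record the best
nominal p per permutation, fit $\mathrm{Beta}(a, b)$ to the permuted
minima by maximum likelihood (Nelder–Mead on log parameters,
method-of-moments start), and evaluate the observed best p under the
Beta CDF. The direct empirical p is always computed, serves as the
fallback if the Beta fit fails, and bounds below at $1/(B+1)$.
Adaptive mode runs permutations in blocks of 100 and stops once 100
permutations beat the observed best p — clearly null genes stop
early, promising genes run the full budget. eGenes are called by
Benjamini–Hochberg at 5% FDR (BH rather than Storey for
dependency-free reproducibility), and the per-gene nominal threshold
is the Beta quantile at the empirical-p cutoff halfway between the
last accepted and first rejected gene.

## Fine-mapping

The fine-mapper is a sum-of-single-effects model fitted by iterative
Bayesian stepwise selection. Each of $L$ effects (default 10) is a
mixture over variants: given the residual of all other effects, the
single-effect regression computes per-variant Bayes factors under a
Gaussian effect prior, posterior inclusion weights proportional to
them (uniform prior over variants), and posterior moments; the
effect's prior variance is re-estimated each sweep by maximizing its
single-effect marginal likelihood (1-D search on the log scale, with
the previous value kept as a fallback candidate so the update can
never descend), and the residual variance by the expected residual
sum of squares. Iteration stops when the evidence lower bound moves
by less than 1e-4; the ELBO trace is exposed and tested to be
monotone within 1e-8 — that invariant caught a sign error in the KL
term during development, which is exactly what it is for.

95% credible sets take, per surviving effect, the smallest
inclusion-weight prefix reaching 0.95; sets with purity (minimum
absolute genotype correlation among members) ≤ 0.5 are dropped, as
are effects whose estimated prior variance collapses to zero.
Defaults (L = 10, coverage 0.95, purity 0.5) are the conventional
fine-mapping settings. For splicing, intron-level sets are merged to
gene level by connected components over shared variants (an
LD-threshold merge was considered; shared-variant closure is simpler
and testable, and the merged PIP is the per-variant maximum across
source sets). Leads are highest-PIP variants, ties broken by smaller
|TSS distance|, then lexicographic id.

## Effect sizes (conditional aFC)

For lead QTLs the package fits the multiplicative dosage model
$E[y \mid g_1..g_K] = C \prod_k \big((2-g_k) + g_k k_k\big)/2$ by
least squares on the log2 scale, profiling out $C$, box-constrained to
100-fold ($|\log_2 k| \le \log_2 100$, the reference implementation's
convention — a `capped` flag marks when the bound binds), initialized
from marginal one-lead fits, with optional bootstrap standard errors
(200 resamples). The dosage model is exact for one causal variant and
an approximation for several (phase is unobserved in dosages); when
phased haplotypes are available, `afc_conditional(haplotypes = ...)`
fits the exact haplotype-average model instead. On simulator truth the
dosage model recovers single effects with median absolute error ~0.05
and regression slope ~0.99, and both effects of two-causal genes
within ±0.1 median. Perfectly collinear leads are dropped (the later
one), flagged in the output.

## Population differentiation

Per-group allele frequencies classify variants as unobserved
(MAF = 0), rare (MAF < 0.05) or common (MAF ≥ 0.05), with derived
flags (globally common; unobserved in one group but present
elsewhere). $F_{ST}$ uses the Hudson estimator,
$$F_{ST} = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}}{p_1(1-p_2) + p_2(1-p_1)},$$
focal group against the pooled complement (the ratio-of-averages
aggregate over variants for summaries; pooling the complement rather
than averaging pairwise values is an interpretive choice, and the
pairwise matrix is available). Negative estimates are reported, not
clipped; both samples fixed for the same allele yield a missing
value.

Differential expression contrasts each group against all other
samples with a per-gene negative-binomial GLM (log link, log
size-factor offset, ML dispersion with a method-of-moments fallback,
LRT). Dispersion is per-gene without shrinkage across genes — a
deliberate divergence from shrinkage-based DE tools to stay
self-contained; at desk-scale sample sizes the LRT is calibrated
without it. Genes are binned into p-rank deciles (10th = most
significant), lead-eQTL $F_{ST}$ is averaged per decile, and a
two-tailed Mann–Whitney U compares DE against non-DE genes.

## Effect-size heterogeneity

A lead is eligible if its MAF is ≥ 0.05 in at least two groups. The
single-causal model fits
`y ~ g + group + g:group + covariates` and F-tests the interaction
block (one-tailed, upper tail), building interaction columns only for
groups where the variant is polymorphic and contributes ≥ 5 samples
(parameters are unestimable otherwise). The multi-causal model adds
every fine-mapped lead of the gene as an additive predictor and tests
one lead's interaction at a time; with one lead it reduces exactly to
the single model. The PC variant replaces the categorical block with
`g × PC` terms. Under the additive generative null the single-model
test rejects at the nominal rate (the acceptance suite checks the
binomial CI at 2,000 replicates); under two additive
AF-differentiated causal variants with template-block LD, the
single-model test — pointed at the top nominal variant, typically a
tag whose group-specific LD to the causal pair differs — produces
spurious Bonferroni-significant interactions that conditioning on the
fine-mapped leads removes, reproducing the qualitative
single-versus-multi contrast as a mechanism rather than a printed
percentage.

## Enrichment

Backgrounds are matched on MAF and |TSS distance| by 10 × 10 pool
deciles; each draw samples one pool variant per lead from the lead's
joint bin without replacement within the draw, widening empty bins to
the nearest non-empty ring (logged). Fold enrichment is the lead
proportion over the mean background proportion, reported as log2 fold
with a 95% percentile CI across per-draw ratios; zero proportions use
a 0.5/n pseudo-count rather than dropping draws, so depletion is
representable. Categories with fewer than 5 annotated leads are
refused. The bin counts and percentile CI are package choices — the
matching covariates are given, the mechanics are not.

## Colocalization

Per-variant evidence enters either as Wakefield approximate Bayes
factors from marginal summary statistics,
$\log ABF = \tfrac12\big(\log(1-r) + r z^2\big)$ with
$r = s_0^2/(s_0^2 + se^2)$, or as per-effect Bayes factors from two
sum-of-single-effects fits, paired one surviving credible set at a
time. The five-hypothesis posterior uses per-variant priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 5 \times 10^{-6}$ (the conventional
defaults; the source analysis does not print its priors), log-sum-exp
stabilized, with PP4 ≥ 0.5 labelled moderate and ≥ 0.8 strong.

## Numerical choices and degenerate inputs

Missing genotypes are imputed to the rounded per-variant mean and
counted; variants above 5% missingness are dropped. Multiallelic VCF
records are skipped with a count. Constant phenotype features cannot
be rank-transformed and are dropped with a warning. Zero variance
cells in the heteroskedasticity test are floored at 1e-12 and
flagged. Monomorphic candidates are refused by the scan (they should
never pass the MAF floor). Beta-fit failures fall back to the direct
empirical p. The aFC optimizer runs at tolerance 1e-9 so exact-model
fixtures recover parameters to ~1e-6.

## Problem sizes used by the checks

The acceptance suite runs cohorts of n = 500 (5 groups × 2
populations × 50 samples — the reduced-population emulation the
configuration supports), 10–200 cis variants per gene, 200-gene
recovery panels, 2,000 calibration replicates, 20 FDR replicates of
200 genes, and 100–10,000 permutations depending on the check; the
full 26-population default is exercised in the generator tests. These
sizes were chosen as the smallest at which the targeted properties
have stable sampling distributions.
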