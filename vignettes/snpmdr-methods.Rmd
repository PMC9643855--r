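---
title: "Detecting epistatic SNP effects in case-control cohorts with snpmdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epistatic SNP effects in case-control cohorts with snpmdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmdr)
```

# Scope and model

`snpmdr` implements the analytic chain used in candidate-gene case-control
studies of complex disease: per-SNP association under inheritance models,
multifactor dimensionality reduction (MDR) for gene-gene interaction, and
entropy-based interaction scoring, together with a cohort simulator that
makes every stage testable against data of known architecture. The packaged
worked example is a panel of five cytokine-gene SNPs (IL1A rs1800587, IL6
rs1800796, TNFA rs361525 and rs1800629, IFNG rs2069705) genotyped in a
dementia case-control cohort of 221 cases and 710 controls, for which the
per-SNP class-by-genotype marginal counts are shipped as a plain-text
fixture.

Genotypes are coded throughout as minor-allele dosage: 0 = homozygous
common allele, 1 = heterozygous, 2 = homozygous variant. PED input is
recoded against the panel's declared common allele, never against
file-observed frequency, so coding is deterministic across files. Missing
genotypes are handled complete-case per analysis: each operation drops only
the subjects missing the SNPs it actually uses.

# Single-SNP association

For one SNP the unit of analysis is the 2x3 class-by-genotype count table.
Five inheritance models collapse it to 2x2 exposure tables:

* codominant: heterozygote vs common homozygote, and variant homozygote vs
  common homozygote (two tables);
* dominant: common homozygote vs carriers of the variant;
* recessive: variant homozygote vs the rest;
* over-dominant: heterozygote vs both homozygotes;
* additive: allele-count table with alleles as units.

Odds ratios are $OR = ad/bc$ with the Wald interval
$\exp(\ln OR \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})$ and a two-sided
Fisher exact p-value on the uncorrected table. The Haldane-Anscombe
correction (add 0.5 to every cell) is applied only when a zero cell occurs.
Published tables in this field are not always consistent about which group
is the "exposure"; the package fixes one orientation per model (listed
above) so every result is reproducible, and a printed value using the
opposite orientation corresponds to $1/OR$. For the additive model the
allele-count table is the default in crude scans, with a per-dose logistic
coding available through `adjusted_model_or()`; crude and covariate-adjusted
estimates are kept strictly separate because they answer different
questions, and the adjusted fit reports its AIC for inheritance-model
selection (`select_best_model_aic()`, ties broken in the fixed order
codominant, dominant, recessive, over-dominant, additive).

Hardy-Weinberg equilibrium is tested either asymptotically (Pearson 1-df
statistic against the HWE-expected counts) or by a conditional exact test
that enumerates all heterozygote counts compatible with the observed allele
counts and sums the probabilities of configurations no more probable than
the observed one, without mid-p adjustment. Monomorphic samples return
p = 1 by convention. QC filtering (`qc_filter()`) applies MAF >= 1%, exact
HWE in controls at p < 0.05, and composite-LD pruning at r^2 > 0.1,
dropping the later SNP of a high-LD pair in panel order so pruning is
deterministic. On the packaged marginals this computation retains four of
the five SNPs: the rs361525 control counts (642, 63, 5) carry an excess of
variant homozygotes (exact HWE p = 0.032), so at the default threshold that
SNP is flagged — a fact of the printed counts themselves.

# The MDR engine

A k-SNP combination partitions subjects into $3^k$ genotype cells. Each
cell's normalised case:control ratio
$R = (n_{ca}/N_{ca})/(n_{co}/N_{co})$ labels it high-risk when $R > T$
(default $T = 1.05$, strict inequality; the classic MDR threshold $T = 1$
is available through the `threshold` argument). Cells with cases but no
controls are high; cells empty in training classify unseen subjects as
low — the conservative choice. The pooled high/low attribute is scored by
balanced accuracy, $(sensitivity + specificity)/2$, which is insensitive
to the 710:221 class imbalance.

Cross-validation uses stratified folds built by seeded shuffling within
each class followed by cyclic allocation, so stratification is exact and
runs are bit-reproducible given the seed. Within each fold the winning
combination is the one minimising training classification error
(1 - training balanced accuracy), ties resolved by combination order; the
reported model per k is the modal fold winner refit on all data, its
testing metrics averaged over folds, and its cross-validation consistency
(CVC) the number of folds that chose it. The overall best model maximises
testing balanced accuracy, with ties resolved towards higher CVC and then
smaller k (parsimony). Significance comes from a label-permutation test,
$p = (r+1)/(n_{perm}+1)$, which can never return zero. Covariates are
deliberately ignored by the MDR engine: the attribute space is genotypes
only, and covariate-adjusted MDR variants are out of scope.

A note on the threshold: with $T > 1$ the per-cell labelling rule is not
guaranteed monotone under cell refinement (a parent cell with ratio just
above $T$ can split into children that all fall below it), so the
"training accuracy never decreases with k" property of classic MDR is
exact only at $T = 1$; the test suite checks it there.

# Entropy-based interaction scores

Main effects are measured as mutual information $I(A;C)$ between an
attribute and the class, pairwise effects as interaction information
$IG(A;B;C) = I(AB;C) - I(A;C) - I(B;C)$, both reported as percentages of
the class entropy $H(C)$ — the base-2 logarithm cancels in the ratio.
Positive $IG$ means synergy (the pair carries information beyond its
parts), negative means redundancy; a duplicated SNP gives exactly
$IG = -I(A;C)$. Entropies are empirical plug-in estimates with no bias
correction, matching the MDR software lineage; all three terms of $IG$ are
computed on the subjects complete for both SNPs so the decomposition is
internally consistent. The dendrogram clusters SNPs by average linkage on
$d(A,B) = S_{max} - S(A,B)$, where $S$ is the edge score — a monotone
transform under which the strongest synergy merges first. The distance
transform and linkage are this package's choice (the originating software
lineage does not document its own) and are exported in Newick format so
the tree, not a drawing, is the artifact.

# The cohort simulator

`simulate_cohort()` draws independent SNPs under Hardy-Weinberg at
specified allele frequencies and assigns disease through a penetrance
table — a map from each k-locus genotype to a disease probability.
Case-control ascertainment is by rejection sampling until both quotas
fill, capped at $10^7$ draws so degenerate specifications fail loudly
rather than hang. The XOR model (`xor_penetrance()`, high risk iff exactly
one locus is heterozygous) is the canonical pure-epistasis generator: at
allele frequencies 0.5 each locus has identical marginal penetrance across
its genotypes, so single-SNP scans see nothing while a 2-locus MDR search
should. Its expected prevalence has the closed form
$p_{low} + (p_{high}-p_{low})/2$, which the tests use as an oracle.

Covariates emulate an elderly dementia case-control population
(`table2_covariate_params()`): age, education, BMI, total cholesterol and
HDL as per-class normals; sex as a per-class Bernoulli; glucose, LDL and
triglycerides as right-skewed median/quartile specifications. Skewed
variables are drawn from a three-parameter (shifted) log-normal solved to
match the median and both quartiles exactly
($\gamma = (q_1 q_3 - m^2)/(q_1 + q_3 - 2m)$); a plain two-parameter
log-normal cannot match all three, and the sampler falls back to a normal
when the quartiles are symmetric about the median. LDL can also be derived
from the Friedewald equation ($TC - HDL - TG/5$) or its DeLong
modification ($TC - HDL - 0.16\,TG$); BMI classes use the half-open bins
$[0,25)$, $[25,30)$, $[30,\infty)$ so the boundary 30.0 is obese and the
classes partition the range.

`resample_from_marginals()` turns the packaged count tables into
subject-level data by permuting, per class and SNP, the exact genotype
multiset the counts describe. Marginals are therefore reproduced
integer-for-integer under any seed, but the joint distribution across SNPs
is independent conditional on class — the study's true joint genotype
distribution is unpublished. Consequently single-SNP (marginal) statistics
computed on resampled data are exact reproductions, while multi-locus
quantities (MDR accuracies, consistency, interaction percentages) are
properties of the emulation, not of the original cohort, and the package
makes no claim to reproduce the latter. This is also what passing tests do
and do not show about real data: the simulator has no linkage
disequilibrium, no population structure and no genotyping error, so it
validates the machinery, not the biology.

# Numerical choices and problem sizes

Fold and permutation randomness always flow through explicit seeds and
the caller's RNG state is restored afterwards. Degenerate inputs are
signalled with classed conditions (`snpmdr_undefined_error`,
`snpmdr_validation_error`) rather than silent NA coercion: undefined odds
ratios (both diagonal products zero), monomorphic SNPs in LD computation,
single-class entropy, quasi-complete separation in logistic fits.

The validation experiments use these sizes, chosen to give the binomial
checks comfortable power while keeping a full run in minutes on one CPU:
XOR recovery uses 400 cases + 400 controls with three effect-free
background SNPs over 50 seeds, where the causal pair should be the modal
2-locus winner with CVC >= 8/10 in at least 90% of seeds; null
calibration uses 500 replicate cohorts of 251 cases / 263 controls with a
3-SNP joint attribute and 99-permutation tests — the unequal classes and
27-cell attribute make the balanced-accuracy statistic effectively
tie-free, which matters because permutation p-values are exactly uniform
only for tie-free statistics; and the best 1-locus null model at
n = 1000 should stay within testing balanced accuracy [0.45, 0.55] in at
least 90% of 50 seeds. The brute-force cross-checks (exact HWE
enumeration, 2x3 Fisher enumeration, triple-loop entropy, naive MDR
search, naive average-linkage clustering) live in the test suite and are
implemented independently of the package internals they verify.

# Known limitations

Adjusted odds ratios use Wald inference, which degrades near separation
(flagged, not patched). The MDR engine is exhaustive — $C(m,k)$
combinations per k — and intended for candidate panels, not genome-wide
data. The simulator's conditional-independence assumption bounds what any
resampled analysis can say about the original cohort's joint genotype
structure, and entropy percentages on resampled data inherit that caveat.
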