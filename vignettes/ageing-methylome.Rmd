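---
title: "Modelling the ageing methylome: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the ageing methylome: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methager)
```

# The problem

Insects with functional DNA methylation systems offer compact model systems
for epigenetic ageing: short lives, discrete timepoints, and sparse
methylomes in which only a small fraction of CpGs is methylated at all.
`methager` implements the complete analysis path from per-CpG bisulfite
counts to four ageing read-outs:

1. **Differentially methylated positions (DMPs)** — CpGs whose mean
   methylation shifts between ages within a sex;
2. **Variably methylated positions (VMPs)** — CpGs whose methylation
   *variance* grows with age, the positional signature of epigenetic drift;
3. **Methylome Shannon entropy** — a per-library summary of how
   "undecided" the methylome is, modelled against age and sex;
4. **An elastic-net epigenetic clock** — a penalized linear predictor of
   chronological age from CpG methylation fractions.

The pipeline starts at Bismark-style per-CpG counts (coverage files or
cytosine reports); alignment, deduplication and methylation extraction are
upstream of its scope.

# Preprocessing model

**Strand merging.** The two cytosines of a CpG carry one methylation state;
`merge_strands()` pools a plus-strand C at position $p$ with the
minus-strand C at $p+1$ and reports the merged site at $p$. Totals are
conserved exactly; stranded singletons are re-homed to their plus-strand
coordinate.

**Conversion error.** Every library carries an unmethylated lambda phage
spike. Apparent methylation there can only be bisulfite non-conversion, so
the pooled rate $\hat e = \sum m / \sum n$ over spike CpGs estimates the
error. A zero estimate is floored at half a pseudo-count so the binomial
null below stays non-degenerate.

**Coverage filter.** Sites with coverage below 10 carry too little
information for per-CpG models; sites above the per-sample 99th percentile
are likely collapsed repeats or PCR stacks. The percentile is the
linear-interpolation (type 7) empirical quantile of the sample's pre-filter
coverage distribution; the choice of definition is fixed here because it
changes which boundary sites survive. The filter is per sample, and the
united matrix keeps only sites observed in every library, because each
per-CpG regression uses all libraries.

**Methylation calling.** For each site $\times$ library cell an upper-tail
exact binomial test asks whether the methylated count exceeds what
non-conversion alone would produce: $p = P(X \ge m),\ X \sim
\mathrm{Bin}(n, \hat e)$. One-sided is the only meaningful direction — the
null *is* the error process. BH correction runs jointly across all cells
(the conservative single reading; a per-sample variant would be easy to add
but changes little at genome scale), and a CpG enters the analysis set when
any library's cell is significant at $q < 0.05$. In a sparse methylome this
removes the overwhelming majority of CpGs.

# Differential methylation

For a two-group comparison the binomial logistic regression of methylated
counts on the group indicator has closed-form maximum-likelihood estimates:
the pooled within-group proportions. `dmp_test()` therefore computes the
likelihood-ratio deviance directly,

$$D = 2\left[\ell(\hat p_A, \hat p_B) - \ell(\hat p_{pooled})\right] \sim \chi^2_1,$$

which is algebraically identical to the glm route but vectorizes across
tens of thousands of CpGs. Replicates are treated as independent binomial
observations (no overdispersion correction), matching the standard logistic
test in this setting; with beta-binomial data this is mildly
anti-conservative, which is why calls additionally require an effect size:
$q < 0.05$ *and* a methylation difference strictly greater than 15
percentage points. Comparisons run within sex for all three age pairs by
default; "consistent" hyper/hypo sets are those significant with the same
sign in *both* successive comparisons (day 0→8 and day 8→16) — the only
reading that makes "consistently" operative. Gene-level calls need at least
two significant CpGs in the feature and a weighted methylation difference
(total methylated over total coverage across the feature) of at least 15%.
CpGs overlapping two genes count in both, as no exclusion rule is stated
anywhere; a fixed-effects weighted-methylation summary by sex × age is
produced for inspection in place of a mixed model.

# Drift: VMPs and entropy

**Beta regression.** Methylation proportions and entropies live on (0,1),
so mean models use the beta likelihood with logit link and constant
precision $\phi$ (`shape1` $= \mu\phi$, `shape2` $= (1-\mu)\phi$), fitted
by BFGS with analytic gradients and Wald errors from the observed
information. Proportions touching 0 or 1 are first compressed with the
standard transform $y' = (y(n-1) + 0.5)/n$, which is affine and therefore
order-preserving — and, usefully, leaves the Breusch-Pagan $R^2$ unchanged.
Starting values come from least squares on the logit scale; fits that do
not converge are flagged and excluded from downstream screening, never
silently zeroed.

**VMP screen.** Drift is heteroscedasticity: variance that depends on age.
Per CpG, the screen fits the beta regression on age + sex (recorded as the
mean-trend model) and runs the studentized (Koenker) Breusch-Pagan test on
the ordinary least-squares fit of the fractions on (age, sex): regress the
squared residuals on the same design and refer $LM = n R^2_{aux}$ to
$\chi^2_2$. The linear-fit reading is used because the test is defined for
linear models; a beta-residual variant would be a straightforward
extension. Holm correction across all tested sites gives family-wise
control.

A structural caveat that any user of this screen at small $n$ should know:
$LM = nR^2 \le n$. With 18 libraries the smallest achievable p-value is
$1-F_{\chi^2_2}(18) \approx 1.2\times10^{-4}$, so *no* site can survive
Holm correction across more than a few hundred tests, whatever the effect
size. At this design scale the unadjusted p-values remain informative as a
ranking (drifting sites are stochastically smaller; the package's tests
verify this), but family-wise significant VMP calls require either far more
libraries or a much smaller test family. The `vmp.tsv` output therefore
carries both `p` and `p_holm`.

**Entropy.** Per library, over a fixed CpG set (by default the
age-significant DMP union, mirroring the read-out's use as an ageing
summary),

$$\mathrm{Entropy} = \frac{1}{N \ln \tfrac12}\sum_i \left[ MF_i \ln MF_i + (1-MF_i)\ln(1-MF_i) \right],$$

the normalized mean binary entropy of the methylation fractions, with
$0\ln 0 = 0$: 0 for a fully determined methylome, 1 for coin-flip noise.
The normalization makes the logarithm base irrelevant. A variant sometimes
seen in print replaces the second term by $(1-MF_i)(1-\ln MF_i)$; that
expression is not bounded by [0,1] and cannot be the intended statistic —
it is available behind `variant = "printed"` for comparison, while the
binary-entropy form is the default. The entropy ageing model is a beta
regression of entropy on age × sex; the interaction is tested by a
likelihood-ratio $\chi^2_1$ and per-sex slopes by Wald tests on stratified
refits — the same inference target as marginal-means machinery, with a
simpler contract.

# The clock

`fit_elastic_net()` minimizes
$\frac{1}{2n}\sum (y - \beta_0 - x^\top\beta)^2 + \lambda(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2)$
over a descending $\lambda$ path (glmnet), with features standardized
internally and coefficients returned on the original scale. Choices that
were genuinely open and are fixed here:

* **mixing $\alpha = 0.5$** — "elastic net" implies $0 < \alpha < 1$; the
  midpoint is the conventional default and is exposed as an argument;
* **$\lambda$ = CV-MSE minimizer**, not the 1-SE rule — the clock's job
  here is in-sample age recovery; the sparser 1-SE model is a one-line
  change;
* **seeded age-stratified folds** — with 18 samples and 3 ages, random
  3-folds can easily concentrate an age in one fold; stratification deals
  each age group across folds, and the seed makes the assignment (hence
  the fitted clock) reproducible bit for bit.

Epigenetic age is the affine prediction; accuracy is summarized by Spearman
correlation (average ranks; p from the t approximation, adequate at these
n and documented as such) and RMSE in days. With tied chronological ages
(6 libraries per day), the maximum attainable Spearman correlation is about
0.944, not 1 — worth remembering when reading the evaluation. Age
acceleration is the residual of chronological on epigenetic age (summing to
zero by construction) and is compared between sexes by a Wilcoxon rank-sum
test, exact by enumeration for tie-free samples up to 12, normal
approximation with tie and continuity correction otherwise. In-sample
accuracy is optimistic by construction, because the clock's candidate CpGs
were pre-selected for age association on the same libraries; the
cross-validated predictions kept in the model object give the honest
counterpart.

# GO enrichment

Hypergeometric upper-tail tests per term, BH across terms. The universe is
the background intersected with GO-annotated genes — unannotated genes
carry no information under the model. Two backgrounds mirror the two kinds
of question: methylated genes (mean weighted methylation strictly above
0.05 — the spike-scale cutoff — in at least one sex × age group) for VMP
and clock gene lists, and differentially methylated genes for the
consistent hyper/hypo lists. No GO-graph propagation is performed;
enrichment is on the annotations as given.

# The synthetic study

`simulate_experiment()` generates the study the analyses assume: 2 sexes ×
3 timepoints (day 0, 8, 16) × 3 replicates of pooled-individual WGBS
counts. Coverage is negative binomial (mean 30, size 15, truncated at 1);
counts are beta-binomial with mean $\mu$ and precision $\phi$ per site
class:

| class | count (default) | mean model | precision |
|---|---|---|---|
| `null_unmeth` | 20000 | $\mu = 0.005$ (the conversion error) | binomial |
| `stable` | 2700 | constant, $U(0.2, 0.8)$ | 100 |
| `dmp_hyper` | 300 | logit-linear, base $U(0.10, 0.20)$, +0.30 by day 16 | 100 |
| `dmp_hypo` | 300 | logit-linear, base $U(0.80, 0.90)$, −0.30 by day 16 | 100 |
| `vmp` | 300 | constant, $U(0.35, 0.65)$ | 80 → 10 with age |
| `clock` | 40 | linear, +0.02/day, clipped to [0.02, 0.98] | 200 |
| `lambda_spike` | 200 | binomial at the conversion error | — |

Reasoning behind the values that were free:

* the genome is **null-dominated** (20000 of ~23600 CpGs), as real insect
  methylomes are; this is also what makes the joint BH methylation call
  behave — in a methylation-rich genome the BH threshold is lenient and
  the site-level "methylated in any library" false-call rate inflates;
* DMP slopes are calibrated so the day-0 → day-16 difference is 0.30 on
  the proportion scale, comfortably above the 15% call threshold but far
  from trivial at 3 replicates; hyper sites start low and hypo sites start
  high, so ageing moves both toward 0.5 — the regression-to-the-middle
  geometry real ageing methylomes show, and the reason entropy rises with
  age over the DMP set (a mean-preserving *spread* alone, as at VMP sites,
  can only lower mean binary entropy, by concavity);
* $\phi = 100$ for stable/DMP sites reflects pooled libraries of ten
  individuals, which average out much individual variation; the VMP
  schedule 80 → 10 makes drift a pure precision loss;
* the spike is emitted as a separate chromosome (`lambda`) inside the same
  files, exercising conversion-error estimation end to end.

Reproducibility is per-site: each site's draws come from a substream seeded
by (master seed, site index), so changing one class's count never
reshuffles another site's data, and identical configurations give
byte-identical files.

**What the simulator does not emulate** — and hence what passing tests do
not demonstrate about real data: read-level artefacts (M-bias, chimeras),
non-CpG contexts, genomic autocorrelation of methylation state, covariance
between neighbouring CpGs, batch effects, and genuine biological pathway
structure in the GO map (one designed term is planted for recovery tests;
the rest are random).

# Numerical choices and degenerate inputs

* Deviances are clamped at 0 against floating-point negatives; $0\log 0$
  terms are evaluated as 0 throughout.
* Perfect separation in `dmp_test` is benign: the closed-form group
  proportions hit 0 or 1 and the $0\log 0$ convention keeps the deviance
  finite.
* `normalize_coverage` rounds half-up after scaling both count components
  by the same factor, so `meth <= cov` survives rounding.
* Beta-regression fits whose Hessian is not positive definite are flagged
  non-converged; the VMP screen drops them from the Holm family.
* The Breusch-Pagan chi-square reference is asymptotic: at $n = 18$ its
  null p-values are visibly non-uniform (Kolmogorov distance ≈ 0.11 even
  for ideal normal errors — identical for the reference `lmtest`
  implementation), while at $n \ge 50$ the approximation is good. The
  package's calibration tests therefore check uniformity at $n = 200$ and
  treat the small-$n$ distortion as a documented property of the design,
  not of the implementation.
* Problem sizes in the shipped tests and workflow: a ~23,600-site genome
  with 18 libraries (the full study design) for end-to-end checks, and a
  ~1,300-site genome for unit-level fixtures.

# Known limitations

* The VMP stage's family-wise correction is honest but, at 18 libraries,
  structurally powerless (see above); treat `p_holm` as a guarantee, the
  raw ranking as the practical signal.
* The logistic DMP test ignores beta-binomial overdispersion; the effect
  size threshold absorbs most of the resulting anti-conservatism, but an
  overdispersion-corrected variant would be the next improvement.
* Entropy inference at 18 points rests on a parametric beta model;
  residual diagnostics are advisable on real data.
* GO enrichment does not propagate annotations up the ontology graph.
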