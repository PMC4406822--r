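---
title: "Bayes factors with uncertainty in the effect-size prior variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayes factors with uncertainty in the effect-size prior variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorbf)
```

## The model

Fine-mapping a disease-associated region means ranking hundreds or
thousands of densely genotyped SNPs by their evidence of causal
association and retaining the top of the list for functional follow-up.
For SNP $i$ with per-allele log odds ratio MLE $\hat\beta_{1i}$ and
asymptotic variance $V_i$ (the squared standard error from univariate
logistic regression), the Wakefield approximation compares
$H_0:\beta_{1i}=0$ against $H_1:\beta_{1i}\sim N(0,W)$ and gives the
closed-form Bayes factor

$$\mathrm{WBF}_i(W) \;=\; \sqrt{\frac{V_i}{V_i+W}}\;
  \exp\!\left\{\frac{\hat\beta_{1i}^2\,W}{2V_i(V_i+W)}\right\},$$

oriented here so that values above 1 favour association. Its weakness is
the fixed prior variance $W$: rankings are sensitive to it, and experts
rarely commit to a single value.

This package treats $W$ itself as uncertain. With a density $f(W)$
supported on $0<a\le W\le b$, the Bayes factor becomes the prior-weighted
average

$$\mathrm{BF}_i \;=\; \int_a^b \mathrm{WBF}_i(W)\, f(W)\, dW .$$

Four families are available for $f$, each specified up to a normalizing
constant computed at construction:

| family      | kernel on $[a,b]$                       | hyperparameters |
|-------------|------------------------------------------|-----------------|
| power       | $(V+W)^k$                                | $k<-1/2$        |
| exponential | $e^{-cW/2}$                              | $c>0$           |
| hybrid      | $(V+W)^k e^{-d/(2(V+W))}$                | $k<-1$, $d\ge 0$|
| reciprocal  | $(V+W)^{-1} e^{-(V+W)/2}$                | none            |

The corresponding averaged BFs are the PPBF, EPBF, HPBF and RPBF. Three
of the families involve $V$; that dependence is a device to make the
integrals tractable, not a statement of belief, and at Bayes-factor time
each SNP's own $V_i$ is used inside the kernel and its normalizer. For
prior construction and elicitation a single anchor $V$ is needed; the
median per-SNP $V$ is the recommended choice. In large studies the
density of $W$ changes little over the realistic range of $V$, which is
what justifies the convenience.

Properties worth knowing when choosing a family: the power, exponential
and reciprocal densities are monotone decreasing on the support (most
mass at small effects); the exponential family is the only one
independent of the data and approaches the uniform on $[a,b]$ as
$c\to 0$; the hybrid family is the only one with an interior mode, at
$W=-(V+d/(2k))$ clipped to $[a,b]$, so it can place mass anywhere. For
the power and reciprocal families $E(W)$ is nondecreasing in $V$, which
matches the hypothesis that rarer alleles (larger $V$) have larger
effects; the hybrid family can violate that monotonicity when $d$ is
large, so analysts holding that hypothesis should keep $d$ near zero.

## Numerical strategy

Adaptive quadrature (relative tolerance `1e-9`, up to 200 subdivisions)
on $\int_a^b \mathrm{WBF}(W)f(W)\,dW$ is the definitional implementation
for every family. Substituting $u=V+W$ and splitting
$\exp\{\hat\beta^2W/(2V(V+W))\} =
e^{\hat\beta^2/(2V)}e^{-\hat\beta^2/(2u)}$ turns the power and hybrid
integrands into $u^{k-1/2}e^{-q/u}$ with $q=(\hat\beta^2+d)/2$, an upper
incomplete-gamma difference; this closed form is the fast default for
those two families and must agree with quadrature to `1e-6` relative (it
is tested on a grid of specs and SNP summaries, along with a
Monte-Carlo estimate as a third, stochastic path). No closed form is
attempted for the exponential and reciprocal families. All Bayes factors
are computed and stored in log space: the large factor
$e^{\hat\beta^2/(2V)}$ stays outside the integral, so a zero or tiny
$\hat\beta$ never produces NaN.

Distribution functions are closed-form: the power family has a
polynomial form with a dedicated logarithmic branch at $k=-1$ (taken
whenever $|k+1|<10^{-10}$, never by the generic formula); the
exponential CDF is written with `expm1` so the $c\to 0$ uniform limit is
exact; the hybrid CDF is a ratio of incomplete gamma functions evaluated
on the log scale of whichever tail is better conditioned; the reciprocal
CDF uses $\ln u$ plus the alternating series
$\sum_n (-1)^n (u/2)^n/(n\cdot n!)$, truncated when terms fall below
$10^{-12}$ (after at least 5 terms) with a quadrature fallback if 500
terms fail to converge. Quantiles come from 80 bisection steps on the
CDF; sampling is inverse-CDF. `prior_mean()` uses closed
polynomial/logarithmic antiderivatives for the power family (including
the $k=-1$ and $k=-2$ branches) and adaptive quadrature elsewhere —
the closed exponential-family mean was deliberately not used because it
cancels catastrophically as $c\to 0$, where quadrature is exact.

Degenerate inputs: $W$ outside $[a,b]$ has density 0 (not an error);
support bounds must satisfy $0<a<b$, so a degenerate interval is
rejected at construction; a narrow support $b-a\to 0$ reduces every
averaged BF to $\mathrm{WBF}(a)$, which is verified at width $10^{-8}$.

## Eliciting the hyperparameters

Experts think in odds ratios, not variances. If the upper limit of the
central $z$% probability interval of the OR is $\mathrm{PI}_u$, then
with $p = 1-(1-0.01z)/2$ the implied quantile of $W$ is
$w = (\ln \mathrm{PI}_u / \Phi^{-1}(p))^2$. The support comes from the
smallest and largest plausible OR limits at a reference percentile
(default the 80th, used directly as $p=0.8$). Given $h$ elicited pairs
$(w_i, p_i)$, each family's hyperparameters minimize
$\sum_{i=1}^h (F(w_i)-p_i)^2$:

* power: exhaustive grid $k \in [-10, -0.5)$ at step 0.01;
* exponential: 1-D bounded minimization of $c$ refined from a log-spaced
  grid on $(0, 10^4]$;
* hybrid: the same $k$ grid crossed with
  $d\in\{0,10^{-4},\dots,10\}$, then continuous refinement of $d$
  between its grid neighbours. Keeping $k$ on the grid was a deliberate
  design choice: the hybrid family contains the power family at $d=0$,
  and refining $k$ continuously for one nested family but not the other
  would let the hybrid "win" by search resolution rather than by fit.
  With equal resolution the nested fits tie exactly and the tie is
  reported;
* reciprocal: no parameters, the objective is simply evaluated.

`select_prior_family()` fits all four and returns the smallest achieved
sum of squares; ties within $10^{-9}$ are broken by the fixed precedence
power > exponential > hybrid > reciprocal and flagged. Support bounds
are kept at full precision internally and rounded (a to 3 decimals, b to
1) only for display. After fitting, `feedback_quantiles()` inverts the
CDF at unelicited probabilities and maps them back to OR upper limits,
the standard feedback step of a structured elicitation.

The package ships the worked elicitation from a breast-cancer
fine-mapping study of the CASP8 region (`icogs_elicitation()`): an 80th
OR percentile between 1.05 and 1.3 gives $a=0.003$, $b=0.1$; interval
limits 1.43, 1.21, 1.14 at the 95%, 75% and 50% levels give
$w=(0.0333, 0.0275, 0.0377)$; with $V=0.00017$ the power-family grid
minimum sits at $k=-1.66$ and the exponential fit at $c=145$, the power
family fitting best. The test suite and `scripts/acceptance.R` recompute
all of these from scratch.

## What the simulator emulates — and what it does not

`sim_scenario()`/`simulate_case_control()` generate an LD-structured
region with a single causal SNP for method evaluation without any
external download. Haplotypes follow a first-order Markov chain along
SNPs: stationary allele frequencies are uniform on `maf_range` (default
0.05–0.5, the causal SNP forced to its own MAF), and adjacent SNPs have
correlation `ld_decay` (default 0.9), capped per-pair at the feasibility
bound for binary variables with unequal frequencies so that marginal
frequencies stay exact; $r^2$ therefore decays geometrically with
distance. Diploid genotypes are sums of two haplotypes drawn with
replacement from a pool (default 10,000 haplotypes, an artifact choice
playing the role of a reference panel). Case status follows the logistic
model at the causal SNP with intercept set for a 10% baseline disease
probability — a typical complex-disease figure; the intercept is not
identified by case-control data, so it is exposed in the scenario rather
than estimated — and subjects are rejection-sampled to exact case and
control quotas.

Scenario defaults mirror the published simulation design: 2,871 SNPs,
causal MAF 0.08, OR 1.14 (of the studied 1.10/1.14/1.18), 2,000 cases
and 2,000 controls (of the studied totals 2,000/4,000/20,000). What the
parametric chain does **not** reproduce is the block structure,
haplotype diversity and allele-frequency spectrum of real CASP8-region
reference haplotypes. Absolute true-positive rates are therefore not
comparable with analyses that used real LD, and the package's simulation
checks are deliberately property-based: null calibration of the per-SNP
test, Hardy–Weinberg marginals, $V\propto 1/n$, recovery of the
generating log odds ratio, and — the pattern that motivates the whole
construction — a power prior concentrating mass near $W=a$ produces a
threshold-averaged ROC curve close to the fixed-$W$ Wakefield filter at
$a$, while a hybrid prior with mass near $b$ tracks the filter at $b$.
Passing these says the machinery behaves as the theory predicts under a
known truth; it does not certify performance on real haplotype
structure.

The test suite runs these checks at desk scale: 60-SNP regions, 200
replicate datasets for the ROC comparisons (with one shared haplotype
pool), 100 replicates for null calibration, and 1,000 pure-ranking
replicates for the TPR = FPR null — sizes chosen so the full property
battery stays inexpensive while Monte-Carlo error remains well below the
asserted margins.

## Filtering evaluation conventions

`tpr_at_fpr()` uses a conservative threshold: at FPR level $f$ a
replicate admits exactly $\lfloor f \cdot n_{\text{null}}\rfloor$ null
SNPs, and the causal SNP counts as detected only if it scores strictly
above the first rejected null. Requested levels below $1/n_{\text{null}}$
are unreachable; the achieved level (0) is used and flagged.
`threshold_averaged_roc()` pools score thresholds across replicates
(all distinct scores up to 512, subsampled evenly by rank) and averages
per-replicate (FPR, TPR) at each threshold — threshold averaging in
Fawcett's taxonomy — so the summary curve is monotone by construction;
endpoints (0,0) and (1,1) are always included. Ranks use average ties,
descending for Bayes factors and ascending for P-values.

## Known limitations

* Univariate only: covariate adjustment, imputation uncertainty and
  multivariate (haplotype or conditional) Bayes factors are out of
  scope; the multivariate analogues of these integrals do not appear
  tractable.
* The hybrid family's closed form assumes $d \ge 0$ (enforced at
  construction); the looser classical validity condition ties $d$ to a
  per-SNP estimate and is not usable as a family-level constraint.
* The EPBF must be computed by quadrature; this is the slowest path,
  and for studies where power or hybrid priors can approximate the
  desired exponential shape those families are preferable.
* Elicitation fits with a single quantile pair are underdetermined;
  every family with a free hyperparameter fits almost exactly and the
  reported selection rests on the tie-breaking precedence.
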