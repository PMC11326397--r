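---
title: "Genome-wide fine-mapping with low-rank Bayesian mixture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide fine-mapping with low-rank Bayesian mixture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwfm)
```

## The problem

Genome-wide association studies test SNPs one at a time, so linkage
disequilibrium (LD) smears every causal signal across its neighbours.
Statistical fine-mapping inverts that smearing: it asks, for each SNP, what
the posterior probability is that the SNP has a nonzero *joint* effect on
the trait — the posterior inclusion probability (PIP). `gwfm` performs that
inference genome-wide rather than locus-by-locus, fitting all SNPs
simultaneously so the genetic architecture (how many causal variants there
are, how large their effects tend to be, and how they distribute over
functional annotations) is learned from the whole genome and feeds back into
every local posterior.

## The model

### Low-rank likelihood from summary statistics

The package never needs individual-level data. Starting from the multiple
regression of phenotypes on mean-centred genotypes, each quasi-independent
LD block is rotated into the eigenbasis of its LD correlation matrix
\(R = U \Lambda U'\). Writing \(b\) for the marginal GWAS effects on the
standardized-genotype, standardized-phenotype scale, the projected data

\[ w = \sqrt{n}\,\Lambda^{-1/2} U' b, \qquad
   Q = \sqrt{n}\,\Lambda^{1/2} U' \]

satisfy the linear model \(w = Q\beta + \epsilon\) with
\(\mathrm{var}(\epsilon) = I\sigma_e^2\), and \(Q'Q\) reconstructs \(nR\) on
the retained basis. Only the leading eigenvectors holding a fraction
`variance_fraction` (default 0.995) of the LD variation are kept, so the
model has rank \(q \ll m\) per block. The printed algebra for this rotation
admits more than one normalization; the one above is the unique choice for
which \(KK' = I\) when \(K = \Lambda^{-1/2}U'X'/\sqrt{n}\), and it is
verified in the test suite against an individual-level computation of
\(\Lambda^{-1/2}U'X'y/\sqrt{n}\) on simulated genotypes.

Two practical notes:

* `b` is obtained from each SNP's z-statistic through the exact
  t-to-correlation identity \(b_{std} = z/\sqrt{z^2 + n - 2}\), after allele
  alignment against the LD reference (swapped alleles negate the sign;
  strand-ambiguous A/T and C/G SNPs are excluded and counted).
* the SNP conditional uses \(C_k = Q_j'Q_j + \lambda_k\) with the *actual*
  retained-basis diagonal \(Q_j'Q_j\) rather than the full-rank value \(n\);
  the two coincide when nothing is truncated, and the former is the exact
  conjugate algebra of the truncated model.

### Mixture priors

Two priors are provided through one interface, `gbmm()`:

* **SBayesC** (point-normal): \(\beta_j \sim \pi N(0, \sigma_\beta^2) +
  (1-\pi)\,\delta_0\), with \(\sigma_\beta^2\) free under a scaled inverse
  chi-squared prior and \(\pi \sim U(0,1)\) via Beta–binomial conjugacy.
* **SBayesRC** (multi-component): \(\beta_j \sim \sum_k \pi_k
  N(0, \gamma_k\sigma_g^2)\) with \(\gamma = (0, 10^{-5}, 10^{-4}, 10^{-3},
  10^{-2})\) by default. With annotations, the mixture proportions become
  SNP-specific through a sequential (stick-breaking) probit model:
  \(P(\delta_j > k \mid \delta_j \ge k) = \Phi(\mu_k + A_j\alpha_k)\),
  updated by truncated-normal data augmentation. The orientation is chosen
  so that a positive annotation effect on the first stick *increases* a
  SNP's non-null prior mass; a flat per-class probit link would not yield a
  proper simplex over components, which is why the sequential construction
  is used.

Unstated hyperprior constants are fixed as: scaled inverse chi-squared
degrees of freedom \(\nu = 4\) with the scale taken from the parameter's
initialization; \(\sigma_e^2\) floored at \(10^{-6}\). Initialization is
\(\beta = 0\), all SNPs null, \(\sigma_e^2 = 1\), and a genetic-variance
scale from the mean-\(\chi^2\) inflation of the input z-statistics; chains
of the default length are insensitive to these choices, which burn-in
absorbs.

### MCMC

The Gibbs sampler sweeps SNPs in genomic order (a random-order scan is
available via `random_order = TRUE`), sampling each SNP's component label
from its conditional posterior and, if non-null, its effect from
\(N(r/C_k, \sigma_e^2/C_k)\), maintaining the block residuals
incrementally. Defaults are 10,000 iterations, 2,000 burn-in, and stored
effect draws thinned by 10 (PIPs and posterior means use every retained
iteration via running counts). PIP is the post-burn-in frequency of
non-null labels.

For SBayesRC, mixture components are pruned automatically: every 500
iterations, the smallest non-null component is removed if the genetic
variance it explains (averaged since the previous checkpoint) is less than
half of that of the second-smallest component — strictly less, so exact
ties are retained. After a removal the burn-in restarts and the total chain
is extended so the number of retained draws is unchanged; checking stops at
the first checkpoint with no removal. The motivation is that a superfluous
small-effect component collects null SNPs by chance and would otherwise
bias the estimated number of causal variants.

### Heritability

On the standardized scale the per-draw SNP-heritability is the genetic
variance itself, \(h^2 = \sum_b \beta_b' R_b \beta_b\) (computed as
\(\|Q\beta\|^2/n\) per block). The residual-variance parameter
\(\sigma_e^2\) is deliberately *not* used in this quotient: because blocks
are modelled independently, each block's projected noise contains the
genetic signal of all other blocks, so \(\sigma_e^2\) converges to roughly
one minus the per-block (not genome-wide) heritability and acts as the
nuisance parameter absorbing heterogeneity between the summary statistics
and the LD reference. Dividing by \(h^2 + \sigma_e^2\) would underestimate
\(h^2\) progressively as the genome is split into more blocks.

## Credible sets

**Local credible sets (LCS).** SNPs are visited in decreasing PIP order
(ties broken by position). Each still-"free" SNP seeds a candidate set of
free SNPs with \(r^2 > 0.5\) to it within its block; members are added in
decreasing PIP until the summed PIP reaches \(\alpha\) (default 0.9).
A candidate that reaches \(\alpha\) consumes its members; it is *reported*
only if its posterior heritability-enrichment probability (PEP) exceeds
0.7. PEP is the fraction of posterior draws in which the set's summed
squared effects strictly exceed those of a freshly drawn random SNP set of
equal size. Strictness matters: a set tied with its comparator (both zero,
or the whole genome against itself) counts as not enriched, which makes PEP
conservative on null data rather than centred at one half. Candidate sets
that never reach \(\alpha\) release their members for later sets.

**Global credible set (GCS).** With \(\hat m_c = \mathrm{round}(M(1 -
\hat\pi_1))\) the estimated number of causal variants, the \(\alpha\)-GCS is
the shortest prefix of PIP-ranked SNPs whose cumulative PIP reaches
\(\alpha \hat m_c\); it is expected to contain a fraction \(\alpha\) of all
causal variants.

**Power and variance explained given the data.** The expected discovered
fraction of causal variants at PIP threshold \(\alpha\) is
\(\sum_{PIP_j \ge \alpha} PIP_j / (M\hat\pi_{nonnull})\), and the
proportion of SNP-based heritability explained by any SNP set is the
posterior mean of \(\sum_{j \in set}\beta_j^2 / \sum_m \beta_m^2\) over
stored draws.

## Predicting power at prospective sample sizes

For a causal variant explaining variance \(v\), its association statistic
\(Z = r^2/(n\sigma_e^2)\) follows a noncentral \(\chi^2_1\) with
noncentrality \(nv/\sigma_e^2\), and the fitted mixture maps \(Z\) to a PIP
through

\[ PIP = 1 - \frac{1}{1 + \sum_{k\ge2} A_k e^{B_k Z}}, \qquad
   A_k = \frac{\pi_k}{\pi_1}\sqrt{\frac{\lambda_k}{C_k}}, \quad
   B_k = \frac{n}{2C_k}. \]

The printed form of the \(B_k\) constant is typographically ambiguous; the
form above is forced by the conjugate-normal algebra and is validated
against empirical Gibbs PIPs by a Kolmogorov–Smirnov test in the suite.
Power at threshold \(\alpha\) integrates \(\Pr(PIP > \alpha \mid v)\) over
the fitted effect-size distribution, done by Monte Carlo: draw a component,
draw \(\beta\), set \(v = \beta^2\) (exactly equivalent to the
change-of-variables density for the symmetric \(\beta\) distribution), draw
\(Z\), and threshold. Expected discoveries are \(M(1-\pi_1)\) times power;
the expected proportion of genetic variance explained divides
\(M(1-\pi_1)\,E[\mathbb{1}\{PIP>\alpha\}\,v]\) by the architecture's total
genetic variance \(M\sum_k\pi_k\gamma_k\sigma_g^2\) (which *is*
\(\sigma_g^2\) in the multi-component parametrization, but differs for the
free-slab point-normal model, where \(\sigma_g^2\) is the per-SNP slab
variance). `required_sample_size()` inverts either metric by bisection on
\(\log n\) under common random numbers.

The power theory treats causal variants independently — it does not model
LD between them — so its PHE projections are compared against the realized
PHE of discovered credible sets in the acceptance checks at a \(\pm 0.1\)
tolerance.

## Case-control traits

Case-control summary statistics are converted to the liability scale before
fitting. The equivalent quantitative-trait sample size is
\(N_{eq} = i^2 v(1-v)N_{01}/(1-K)^2\) with \(i = \phi(\Phi^{-1}(1-K))/K\)
the mean liability of cases; per-SNP effects become
\(SE = 1/\sqrt{2p(1-p)(N_{eq}+z^2)}\), \(b = z\,SE\), preserving z-scores
and p-values exactly. For the schizophrenia sample sizes often used as a
reference (53,386 cases, 77,258 controls, prevalence 0.01) this gives
\(N_{eq} \approx 228{,}810\). `cases_required()` is the exact algebraic
inverse at a chosen case proportion.

## The synthetic cohort generator

All tests and the acceptance script run on data from `simulate_gwas()`,
which emulates the features of real cohort data that the model relies on,
at desk scale:

* **Genotypes**: independent LD blocks (default 50 blocks of 100 SNPs);
  within a block, two latent AR(1) Gaussian haplotypes per individual are
  thresholded at \(\Phi^{-1}(MAF_j)\) and summed to 0/1/2 counts. Each
  block's AR(1) level is drawn from \([0.5, 0.95]\) and each SNP's MAF from
  \(U(0.01, 0.5)\), giving a spread of LD and allele-frequency regimes.
  Thresholding attenuates the latent correlation (tetrachoric attenuation),
  which is deliberate: realized genotype LD is measured from the realized
  genotypes wherever it is needed.
* **Phenotypes**, three architectures: *sparse* — 1% of SNPs causal with
  \(N(0, h^2/m_c)\) standardized effects and \(h^2 = 0.5\); *large-effects*
  — 10 designated SNPs carrying 20% of \(h^2\) (i.e. 10% of phenotypic
  variance) on top of the remaining causal SNPs; *LDMS* — causal variants
  drawn only from the high-LD, high-MAF quartile defined by median splits
  of within-block LD score and MAF. Residual variance is set to
  \(\mathrm{var}(X\beta)(1/h^2 - 1)\), so the realized genetic share
  matches \(h^2\) in expectation.
* **Summary statistics**: standard per-SNP marginal regression, emitted in
  the ".ma" layout (`SNP A1 A2 freq b se p N`).

Defaults (m = 5,000, n = 10,000) are small enough for routine testing yet
large enough for parameter recovery; the same defaults are what the
acceptance script uses. What the generator does *not* emulate: realistic
demography and haplotype structure, imputation error, long-range LD across
blocks, and genome-wide LD-score structure (LD scores are within-block
sums). Passing tests therefore certify the inference machinery under the
model's own assumptions plus moderate misspecification (thresholded
genotypes are not Gaussian), not performance on real cohorts.

## Numerical choices and degenerate inputs

* Component probabilities are computed in log space with max-subtraction;
  they cannot overflow.
* Negative LD eigenvalues are clamped to zero before rank selection; a
  retained zero eigenvalue (possible only at `variance_fraction = 1` on a
  singular block) is refused with an error rather than inverted.
* Monomorphic SNPs get a variance floor in the marginal regression and are
  flagged; they carry no information and are effectively ignored by the
  model.
* `sigma_e2` is floored at \(10^{-6}\); the annotation probit solve adds a
  \(10^{-6}\) ridge against rank-deficient designs.
* LCS ties in PIP are broken by ascending position, making set construction
  deterministic; PEP uses one fresh random comparator per stored draw and
  is seeded.
* Under exact collinearity (r = 1 duplicates) the single-site sampler mixes
  between the equivalent labelings only through rare both-in states; the
  sequential scan would further favour whichever duplicate is updated
  first. Analyses that average PIPs over replicate datasets (as in the
  perfect-LD acceptance check) therefore use the random-order scan, which
  restores exchangeability; PIP *sums* over such sets are insensitive to
  the scan order.

## Problem sizes used in the checks

The acceptance script fits five sparse-architecture replicates at the
generator defaults (m = 5,000, n = 10,000, 10,000 MCMC iterations each),
runs 150 perfect-LD pair replicates (two duplicated SNPs plus 100
background null SNPs at n = 10,000), and measures the large-effects
variance share on 100 generator replicates at m = 2,000, n = 2,000 (the
share is scale-free; its replicate noise comes from the \(\chi^2_{10}\) law
of the ten large effects, so the replicate count, not the cohort size,
controls the Monte Carlo error).

## Known limitations

* Cross-block LD is zero by construction; causal variants in strong LD
  across a block boundary will split their PIP mass without a credible set
  linking them.
* The annotation model is one faithful reading of a sequential probit
  construction; other orderings of the sticks are defensible and would give
  slightly different per-SNP priors.
* PEP's strict tie rule makes it conservative when the posterior is very
  sparse; an LCS whose members are all near-certain nulls is suppressed
  rather than scored 0.5.
* The power predictor inherits the fitted architecture; if the mixture is
  misspecified for a trait, projections at large n extrapolate that
  misspecification.
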