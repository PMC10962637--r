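---
title: "Methods: scanning for selection on predicted expression over time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for selection on predicted expression over time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the statistics it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and the limits of what the synthetic-data tests can show.

## The expression scan

The object of inference is directional change in *cis*-regulated gene
expression over a dated sample of genotypes. Expression is never measured;
it is predicted from sparse linear eQTL weight models,

$$\hat E_{gj} = \sum_{i \in \text{model}(g)} \beta_i \, d_{ij},$$

where $d_{ij}$ is individual $j$'s dosage of the effect allele of SNP $i$
(oriented against the genotype data; see below) and $\beta_i$ is the
model's effect on normalized expression, in expression-SD per allele copy.
Each gene uses the model from the tissue with the highest training
$R^2$ — not because that tissue is the relevant one, but because models
are correlated across tissues and a single deterministic choice avoids a
per-tissue multiple-testing burden. Ties in training $R^2$ are broken by
the lexicographically smallest tissue name, making the choice reproducible.

The scan itself is ordinary least squares of $\hat E_{gj}$ on forward time
$t_j = -\mathrm{date}_j$ (years before present, negated), with an
intercept. The slope $\beta_g$ is the average change in predicted
expression per year; a positive value means expression rising toward the
present, which keeps reported signs aligned with the intuitive reading
of "selection for increased expression". The Wald statistic
$(\beta_g/\mathrm{se})^2$ is referred to a 1-df chi-square.

**Assumptions.** A closed, roughly homogeneous population sampled at
known point dates; weight models whose effects are stable over the time
horizon; independent errors across individuals. No ancestry covariates
are fitted; residual structure and, above all, genetic drift are absorbed
by genomic control instead.

**Genomic control.** Drift makes allele frequencies — and therefore
predicted expression — trend over time even without selection, inflating
every test statistic. The correction divides all chi-squares by
$\lambda = \mathrm{median}(\chi^2)/0.45494$. $\lambda$ is clamped at 1:
deflating apparently well-behaved statistics would anti-conservatively
sharpen the tail. $\lambda$ is computed on whichever set of genes is
handed to the scan; when the quality filter is used, that is the filtered
set. An important and easily overlooked limitation: median rescaling
corrects the *center* of the null distribution, not its *shape*. Under
strong drift the corrected tail remains heavier than chi-square, so the
realized false-discovery proportion of BH calls can exceed the nominal
level even though the per-gene false-positive rate stays far below it.
The date-randomization null (`randomized_date_null()`) is the honest way
to visualize this: dates are permuted across individuals, one shared
permutation per replicate so the gene-gene correlation structure is kept,
and the full regression + genomic-control pipeline is re-run.

**FDR.** Benjamini–Hochberg at $q = 0.05$ via `stats::p.adjust`. The
largest p-value called significant is reported as the scan's implied
threshold, the analogue of a fixed genome-wide line.

## Gene-level imputation quality

Ancient dosages are imputed, and badly imputed SNPs dilute the predicted
expression signal. The gene-level quality is the weight-magnitude-weighted
mean of its SNPs' imputation $R^2$:

$$R^2_{\text{gene}} = \frac{\sum_i |\beta_i| R^2_i}{\sum_i |\beta_i|},$$

computed over resolvable variants. The filter drops genes strictly below
the empirical 20% quantile — implemented as the order statistic at rank
$\lfloor 0.2 n \rfloor + 1$, with ties at the threshold retained, so with
all-distinct qualities exactly $n - \lfloor 0.2 n \rfloor$ genes survive.
The quantile definition matters for reproducibility and is therefore
spelled out rather than delegated to one of R's nine quantile types.

## Allele orientation

Weight models name an effect allele; genotype files carry ref/alt
dosages. A variant whose effect allele equals alt contributes its dosage
as-is; one whose effect allele equals ref contributes $2 - d$; one
matching neither is unresolvable and contributes nothing, shrinking the
gene's *coverage* (the fraction of $\sum|\beta_i|$ on resolvable SNPs).
Strand-ambiguous A/T and C/G sites are resolved by allele match alone and
flagged — a frequency heuristic would import exactly the kind of silent
data-dependence this package avoids. Orientation is an involution
(flipping twice restores the input), which the tests assert. Genes with
zero coverage are excluded and logged rather than silently predicted as
zero; a model whose weights are all exactly zero is the one exception
(its prediction is legitimately zero everywhere).

## The genome scan

The SNP-level scan asks a complementary question — where did allele
frequencies move too fast for drift? Sites are filtered to MAF
$\ge 0.1$, missingness $\le 90\%$, and a nonzero minor-allele frequency
among ancient samples (a site fixed in the past but polymorphic today is
more plausibly an artifact of the modern reference panel than a
resurrection). Allele counts are binned in 100-year intervals (dosages
rounded to hard calls, because the counts feed a binomial likelihood; a
flag switches to expected-dose counts), and a selection coefficient per
generation is estimated per SNP by maximizing the binomial likelihood
under a logistic mean trajectory $\mathrm{logit}\,p(g) = a + s g$ — i.e.
a binomial GLM on the generation axis. Under genic selection the
per-generation logit increment is $\log(1+s) \approx s$, so the slope is
the selection coefficient up to $O(s^2)$, negligible across the studied
range ($|s| \le 0.02$, relative bias $\sim 1\%$).

A piecewise-constant variant ("blocks" mode) splits the horizon into $B$
equal spans with a smoothness penalty
$\lambda_s \sum_b (s_{b+1} - s_b)^2$ added to the negative
log-likelihood, optimized by BFGS from $s = 0$; as
$\lambda_s \to \infty$ it collapses to the scalar fit, which the tests
verify. The default penalty weight $10^{4.5}$ mirrors the smoothing
scale customary for spline-based time-varying selection estimators.
Neither mode attempts to reproduce a full forward-backward
allele-frequency HMM; externally computed per-SNP estimates can be
plugged into `run_gwss()` unchanged, which is the intended path when such
a model is available.

Window statistics are the mean RMS selection coefficient of 20 consecutive
retained SNPs, advancing by 10; windows never cross a chromosome
boundary. When the 20/10 grid leaves trailing SNPs uncovered, one final
partial window is emitted (flagged) if it holds at least 10 SNPs;
chromosomes with fewer than 10 estimable SNPs are skipped with a warning.
A gamma distribution is fitted to *all* window statistics by maximum
likelihood (`fitdistrplus`), with a method-of-moments fallback on
non-convergence, and each window's p-value is the fitted upper tail. Exact
zeros — possible only in degenerate inputs — are replaced by half the
smallest positive statistic and logged. Fitting all windows (rather than
excluding the top of the distribution) is the simpler, more conservative
choice; with a handful of truly selected loci among thousands of windows
the fit is dominated by the null bulk, and the tests confirm parameter
recovery to within 2.5% at $10^4$ windows.

Significant windows (BH-implied threshold by default, or a fixed
`p_threshold`) are merged when separated by less than 5 Mb, and each
merged peak is extended by 0.1 Mb on both sides before gene-overlap
counting (all genes / modeled genes / expression-scan-significant genes).
Peaks are 1-based inclusive internally and exported as 0-based half-open
BED.

## Gene-level classic statistics

Normalized haplotype statistics (SDS, iHS) are standard normal per SNP
under neutrality, so the weighted gene aggregate

$$z_g = \frac{\sum_i \beta_i s_i}{\sqrt{\sum_i \beta_i^2}}$$

is standard normal too, provided the summed SNPs are independent. Scores
are first polarized to the model's effect allele: a score reported for
the non-effect allele is negated, a score whose allele matches neither
model allele is treated as unavailable, and an untagged score is assumed
to already refer to the effect allele. Genes with fewer than half their
model SNPs scored are removed (exactly half is retained). The denominator
sums $\beta_i^2$ over *scored* SNPs only: restricting both numerator and
denominator to the same set is what preserves the unit null variance
after masking, which the tests verify at 40% masking; a flag restores
the all-SNPs denominator for comparison. Two-sided normal p-values are
corrected by the same genomic-control machinery as the expression scan
(residual correlation between model SNPs inflates $z^2$ the same way
drift inflates the regression chi-squares).

The concordance report against the expression scan gives the count of
jointly significant genes, the direction agreement among
expression-significant genes with scores, and the Spearman correlation of
slope versus $z$ over all shared genes.

## Observed-expression comparison

For genes of interest, predicted and observed expression medians per
population are compared by per-gene Spearman correlation across
populations (average ranks for ties; constant vectors are skipped with a
warning). The test statistic is $T = \sum_g \rho_g$. The null permutes
the assignment of observed gene rows to predicted gene rows while leaving
population columns intact, exactly preserving every between-population
relationship; permuting populations instead would destroy the structure
the statistic conditions on, so it is not the default (the row-rank
formulation also makes each permutation a simple indexed sum over a
precomputed rank-correlation matrix). The p-value is one-sided
(agreement, not disagreement, is the claim) with an add-one correction:
$p = (1 + \#\{T^\ast \ge T\})/(1 + n_{\mathrm{perm}})$.

## The synthetic-data generator

The generator exists so that every stage above can be tested against
known truth. Its defaults describe the study design the scans target:

| parameter | default | meaning |
|---|---|---|
| `effective_population_size` | $10^4$ | diploid Wright–Fisher $N_e$ |
| `generation_time` | 28 y | years per generation; no canonical value exists, so it is configurable |
| `n_generations` | $\lceil 4500/28 \rceil = 161$ | horizon covering a 4,500-year transect |
| `sample_schedule` | 77 × {4500, 4000, …, 1000 BP} + 91 × present | 616 ancient + 91 modern individuals |
| `imputation_quality_range` | [0.5, 1] | per-SNP $R^2$, uniform |
| `weight_scale` | 0.15 SD/allele | eQTL effect-size scale |
| `snps_per_gene` | lognormal, median 12 | sparse model sizes |
| `shift_per_unit_s` | 100 | score shift per unit $s$ for synthetic SDS/iHS |

Trajectories use genic (multiplicative) selection,
$p' = p(1+s)/(p(1+s)+(1-p))$, then binomial resampling of $2N_e$ alleles;
0 and 1 are absorbing. Genotypes are Binomial(2, $p$) draws at the
sampled generation. Imputation noise is modeled as linear shrinkage of
the genotype toward the population mean dosage $2p$ with weight $1 - q$,
$q$ the SNP's quality: this reproduces the characteristic property of
imputation — per-sample variance loss that biases sample frequencies
toward the panel — through a single interpretable parameter recorded as
the SNP's $R^2$. The joint distribution of imputation quality across real
SNPs is unknown; the uniform default is a modeling choice, and nothing
downstream depends on its shape beyond mixing high- and low-quality
SNPs. Genes tile contiguous SNP blocks (a cis-window caricature that also
makes genes statistically independent, which the calibration tests rely
on); selected genes receive per-SNP coefficients with sign
$\mathrm{sign}(\beta_i) \times \text{direction}$ on the effect-allele
scale, so frequency shifts push expression the intended way. Synthetic
selection scores are $N(\text{shift} \cdot s_i, 1)$ with configurable
masking and allele-tag flipping.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (SNPs are independent, so there are no hitchhiking
genes and no LD-induced peak widths), radiocarbon date uncertainty
(dates are points), sequencing error, reference bias, and ancestry
structure. Passing calibration and power tests on this generator
therefore demonstrates the statistics are implemented correctly and
behave as designed under their own assumptions — not that those
assumptions hold in any particular real dataset. In real data, LD between
model SNPs inflates gene-level statistics beyond what independent-SNP
calibration shows; that is precisely why genomic control remains in the
pipeline even though the synthetic null barely needs it.

## Numerical choices and degenerate inputs

- Row-wise closed-form OLS across genes (cross-checked against `lm` in
  the tests); constant expression yields slope 0 and p 1, constant dates
  are an error.
- p-values are floored at the smallest positive double rather than
  returned as exact zeros.
- Full-precision (`%.17g`) numeric formatting in the VCF/TSV writers, so
  write→read round-trips are bit-exact; the TSV reader parses numerics
  via `strtod` for the same reason.
- Monomorphic SNPs (all bins fixed) are flagged and excluded from
  windows rather than assigned an arbitrary estimate.
- BH significance uses `q_value <= q`; the largest significant p is
  reported as the implied threshold.
- Chromosomes sort numerically where possible ("chr" prefixes stripped),
  lexicographically otherwise.

## Test and verification scale

The suite verifies oracle equivalence on hundreds of random small
instances (brute-force loops, independent BH step-up, closed-form
expectations), null calibration at $10^4$ simulated genes (genomic
control within $1 \pm 0.05$, KS-uniform p-values, unit gene-score
variance within $\pm 0.03$ including 40% masking), selection-coefficient
recovery at $s \in \{0, 0.005, 0.01, 0.02\}$ over 40 replicate
trajectories with $10^4$-allele bins, and scan power over 50 replicate
cohorts of 301 genes with one planted $s = 0.02$ gene. The power and
end-to-end checks run the scan without the 20% quality drop: that filter
removes a random fifth of genes irrespective of signal, so including it
would turn a sharp statement about scan power into a statement about the
filter; the filter's own behavior is pinned by exact fixtures instead.
These sizes keep the whole suite within a few minutes on one CPU while
leaving Monte-Carlo error well inside every asserted tolerance.

## Known limitations

- Genomic control guarantees a calibrated median, not a calibrated tail;
  under strong drift the realized false-discovery proportion of the
  expression scan exceeds the nominal BH level even though per-gene
  false-positive rates stay tiny. Treat FDR-significant genes as a
  ranked candidate set, not a set with a certified error rate.
- The scalar selection estimator assumes a deterministic logistic mean
  path; it is a likelihood approximation, not a diffusion model, and its
  uncertainty is not propagated into the window statistics.
- The best-tissue rule is tissue-agnostic by design; a gene regulated
  context-specifically can be missed entirely.
- Predicted expression is in normalized units, so effect sizes are not
  comparable across genes, and slopes cannot be converted to absolute
  expression changes.
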