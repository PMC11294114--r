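---
title: "Models and methods behind l1rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind l1rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1rescue)
```

# The scientific setting

`l1rescue` analyses bulk RNA-seq count data from a 2×2 study design used in
mouse models of segmental trisomy: trisomic (TS) and wild-type (WT) animals,
each either treated (t) with a candidate drug or not (nt), in two brain
tissues (cerebral cortex, CX; hippocampus, HC). RNA from several mice of the
same group is pooled before sequencing, so the sample — the column of the
count matrix — is a *pool*, not a mouse. Counts are quantified both for genes
and for individual LINE-1 (L1) retrotransposon loci, and each animal carries
a behavioural readout from a novel-object-recognition test.

Three questions structure the analysis:

1. **Dosage and trans deregulation.** Which features differ between
   untreated trisomic and wild-type animals (TS-nt vs WT-nt)? Genes on the
   triplicated segment (the mouse regions on MMU10/16/17 orthologous to
   human chromosome 21) are expected around a 3:2 = 1.5-fold increase.
2. **Rescue.** Which of those features are no longer differentially
   expressed when *treated* trisomic animals are compared with untreated
   wild types (TS-t vs WT-nt)? This set difference is the operational
   definition of a treatment-rescued feature, applied identically to genes
   and L1 loci.
3. **Behaviour.** Does the expression of rescued features track recognition
   memory, summarised per animal by the discrimination index?

# The differential-expression engine

The engine is a deliberately transparent negative-binomial (NB) Wald
pipeline. It does **not** reproduce DESeq2's dispersion-trend shrinkage,
Cook's-distance outlier handling or independent filtering; its correctness is
established by simulation recovery and by exact limits (see below), not by
matching another implementation's output.

**Size factors.** `estimate_size_factors()` uses the median-of-ratios
estimator: for sample $s$, $\hat f_s = \mathrm{median}_{g \in R}\,
(c_{gs} / \tilde c_g)$ where $\tilde c_g$ is the geometric mean of feature
$g$ across samples and $R$ is the set of reference features (positive in
every sample). The median is taken on the ratio scale, exactly as defined;
no further global rescaling is applied, so factors are meaningful only
relative to one another. If no reference feature exists the function stops
and offers a documented fallback (`pseudo_reference = TRUE`, which adds 0.5
to every count for the reference computation only).

**Dispersion.** The NB variance is parameterised as
$\mathrm{Var}(Y) = \mu + \alpha \mu^2$. `estimate_dispersions()` uses the
method-of-moments estimator on size-factor-normalised counts, centred within
groups: $\hat\alpha_g = \max\{10^{-8},\ (s^2_g - \bar\mu_g)/\bar\mu_g^2\}$,
with the pooled within-group variance on $n - G$ degrees of freedom. The
floor keeps the Poisson limit well-defined; all-zero features get the floor
and a `filtered` flag.

**The Wald test.** `wald_test()` fits, per feature, the log-link NB
regression $\log \mu_{is} = \beta_0 + \beta_1 x_s + \log f_s$ with $x_s$ the
group indicator and dispersion fixed at $\hat\alpha$. Because the two-group
design is saturated, the MLE reduces to one score equation per group,
$\sum_i (y_i - f_i m)/(1 + \alpha f_i m) = 0$, solved by a vectorised,
safeguarded Newton iteration (tolerance $10^{-12}$ relative, 100 iterations
cap). The reported quantities are $\log_2\!fc = \hat\beta_1/\ln 2$, its
standard error from the Fisher information
($\mathrm{Var}(\hat\beta_1) = 1/w_a + 1/w_b$ with
$w = \sum_i \mu_i/(1+\alpha\mu_i)$), and the Wald statistic
$z = \hat\beta_1 / \mathrm{SE}(\hat\beta_1)$.

**Why a t reference distribution.** The p-value is
$2\,P(T_{n_a+n_b-2} \le -|z|)$ rather than the standard-normal tail. This is
a measured decision: with the per-feature moment dispersion plugged in, the
Wald statistic behaves like a t statistic, not a normal one, at study-sized
groups. On a null simulation (5,000 features, 6 vs 6 samples, $\alpha = 0.1$)
the normal tail rejects at rate 0.078 at nominal 0.05 while the
$t_{10}$ tail rejects at 0.047 — the package's own type-I-error test would
fail under the normal tail. With `df = Inf`, or as $\alpha \to 0$, the test
coincides with the Poisson GLM Wald test, which is verified against an
independently coded Poisson oracle in the test suite.

**Degenerate features.** A group whose counts are all zero has its group
mean replaced by $(0.5 + \sum y)/(\sum f)$ — a pseudo-count policy that
bounds the reported fold change; the case is rare at realistic depth and is
flagged by the low-count filter in most instances. Features with fewer than
`min_total` (default 10) summed raw counts across the contrast's samples are
excluded before testing *and before BH adjustment*, so the multiple-testing
family contains only testable features.

**Calling DE.** Two regimes mirror common practice: `padj_le` (BH-adjusted
p ≤ 0.1, inclusive) for the main contrasts, and `rawp_and_lfc`
(raw p < 0.05 and $|\log_2 fc| \ge 1.5$) as a candidate-generating rule for
contrasts with little signal after adjustment. Benjamini–Hochberg is
implemented directly (step-up with monotonicity enforcement, missing values
excluded from the family size) and is tested against a brute-force
evaluation of the definition.

# Rescue logic

`rescued_features()` computes the set difference
$\mathrm{DE}(\text{TS-nt vs WT-nt}) \setminus \mathrm{DE}(\text{TS-t vs
WT-nt})$ over the *intersection* of the two contrasts' tested universes, so
a feature that was low-count-filtered in one contrast can never appear
"rescued" merely because it was untestable. Up/down labels come from the
genotype contrast's fold-change sign.

Whether "rescued" should additionally require the treated-contrast fold
change to have *moved toward* the wild-type level is genuinely ambiguous:
the operational definition is pure set difference, while the narrative
phrase "restored to WT levels" suggests a direction condition. Both modes
are provided; `direction_check = FALSE` is the default, and the stricter
mode additionally requires $|\log_2 fc_{treated}| < |\log_2 fc_{genotype}|$.
Neither mode is asserted as "the" definition; the choice is recorded in the
report's attributes.

Two summaries accompany the set: `ortholog_fraction()` (the share of rescued
features flagged as HSA21-orthologous, i.e. on the triplicated regions of
MMU10/16/17) and `rescue_ratio_index()` — per sample, the mean normalised
expression of up-rescued features divided by that of down-rescued features.
The index is undefined when either set is empty (the functions stop or
return NA with a warning rather than fabricating a value).

# LINE-1 summaries

L1 loci ride through the same DE/rescue machinery as genes; the dedicated
operations are bookkeeping around them. `l1_fraction()` is the per-sample
share of transcriptome counts on L1 loci; group differences are assessed by
the package's Mann–Whitney test. `nearest_gene()` classifies each L1 locus
as `intragenic` (≥ 1 bp overlap with a gene), `proximal` (nearest gene by
interval gap within a window), or `distal_none`. Conventions, chosen once
and exposed as arguments:

* coordinates are 0-based half-open (BED convention) everywhere;
* distance is the interval gap, so touching intervals have distance 0 but
  remain `proximal` (no shared base);
* the proximity window defaults to 100 kb — the field's informal notion of
  "close to a gene" is not standardised, so the window is an argument, not
  an assertion;
* strand is ignored: proximity, not orientation, is reported;
* ties go to the smaller gene start, then lexicographic gene id.

# Behaviour

The discrimination index is
$DI = 100\,(t_{novel} - t_{familiar})/(t_{novel} + t_{familiar})$, bounded
in $[-100, 100]$ with the endpoints attained exactly when only one object is
explored. $\Delta DI = DI_{4M} - DI_{baseline}$. Learner classes use the
group mean ± 3 SEM rule (good / poor / intermediate); SEM uses the $n-1$
sample standard deviation (the convention is not universal, so it is stated
here), and a degenerate group (SEM = 0) is entirely intermediate.

Group comparisons use the Mann–Whitney rank-sum test. For untied data with
$n_x + n_y \le 12$ the exact two-sided p-value is computed from the full
null distribution of $U$, built by a dynamic program over rank partitions;
otherwise a normal approximation with tie and continuity corrections is
used. The exact path is tested against complete enumeration of all
$\binom{n+m}{n}$ partitions. Spearman correlation is the Pearson correlation
of mid-ranks with a $t_{n-2}$ p-value; a permutation p-value is available
behind a flag for very small samples.

`correlate_expression_with_di()` bridges the pool/mouse mismatch: expression
lives on pools, DI on mice. Each pooled sample is assigned the aggregate
(default: mean) of its member mice's $DI_{4M}$, and features (or a supplied
per-sample index) are correlated across samples, BH-adjusted across
features. The pooling of the study is an irreversible design feature; the
aggregation is a configuration choice, not a claim about the original
study's procedure.

# Over-representation

`enrich_sets()` tests a query set against user-supplied collections (GMT)
with the upper-tail hypergeometric probability, computed in log space from
binomial coefficients. The background universe is a required argument; the
recommended choice — used by the pipeline — is the set of unfiltered
(testable) features of the tissue, not the whole annotation, so the null
reflects the population that could have been called. Only over-representation
is computed. No catalogue ships with the package, and GO/KEGG term lists from
any particular catalogue version are out of scope.

# The synthetic-data generator

`simulate_counts()` emulates the study design as stated: group sizes
13/17/9/9 (TS-t/WT-t/TS-nt/WT-nt), two tissues, pools of three formed in
mouse-id order within each (tissue, genotype, treatment) cell (a remainder
forms a final smaller pool), and NB per-mouse counts
$y \sim \mathrm{NB}(f_m\, q_g\, 2^{x_m^\top \beta_g},\ \alpha_g)$ summed
within pools. Default parameter choices and their reasons:

* `dosage_fold = 1.5`: the naive three-copies-vs-two expectation for genes
  on the triplicated segment;
* `mean_expression_log_range = log(c(50, 5000))` per-mouse counts: the
  emulated study sequenced ~110 M reads per pooled sample, which puts
  typical per-gene counts in the thousands; this is the single most
  power-relevant choice and is set from that stated depth;
* `dispersion_range = c(0.05, 0.2)`: gene-wise biological variation typical
  of inbred-mouse bulk tissue; pooling three animals reduces the effective
  pool-level dispersion roughly threefold;
* `frac_rescued = 0.3` of affected features have their genotype effect
  cancelled in TS-t mice (`rescue_scale = 1`, complete restoration; partial
  rescue available);
* a **strong-trans tier** (`frac_strong_trans`, default 2% of non-dosage
  genes) carries genotype effects of dosage magnitude with random sign and
  is rescuable. This is a deliberate extension of the minimal dosage model:
  real trisomic transcriptomes show genome-wide deregulation with many
  *down*-regulated differential genes, and the behavioural ratio index
  (up-rescued over down-rescued expression) is undefined without
  down-regulated rescued features. The truth table records the tier
  separately (`is_strong_trans`);
* per-library depth variation is log-normal (`size_factor_sd = 0.1`),
  within the range normalisation handles comfortably;
* L1 loci are placed intragenic / within 100 kb / uniformly at configurable
  fractions, and a small fraction carries genotype effects of dosage
  magnitude and random sign.

`simulate_behavior()` couples behaviour to expression:
$DI_{4M} = \text{intercept} + \text{coupling} \times \text{ratio index of
the mouse's pool} + \varepsilon$, truncated to $[-100, 100]$, with the
coupling negative by default (animals with higher rescued-gene expression
ratio perform worse). Exploration times are back-solved from each DI at a
fixed 40 s total, so `discrimination_index()` reproduces the DI exactly.
Baseline DI is independent noise near zero.

What the generator does **not** emulate — and hence what a green test does
not establish: batch effects, GC or length bias, alignment and multi-mapping
artefacts (L1 quantification in real data depends on an EM reassignment step
entirely out of scope here), tissue-specific effect sizes, outlier samples,
and any mouse-to-mouse correlation beyond pool membership.

# Numerical and edge-case policy

* Seeds: one seeded generator per simulation call; the seed is recorded in
  the truth table. Pipeline re-runs with the same configuration are
  byte-identical.
* Newton/IRLS: 100-iteration cap, relative tolerance $10^{-12}$, positivity
  safeguard by step halving.
* BH: step-up with `cummin` monotonicity; NA p-values excluded from the
  family.
* Ties: mid-ranks everywhere; the exact rank-sum path refuses tied data and
  falls back to the corrected normal approximation with a warning.
* Zero denominators (ratio index, L1 fraction on empty samples, zero-variance
  correlations) produce errors or flagged NA values, never silent zeros.

# Known limitations

The engine's moment dispersion is noisier than shrinkage estimators; at very
small counts its power is accordingly lower than DESeq2's, and exact DE
counts from any real study are not a reproduction target. The rescue
criterion inherits the thresholding of both contrasts: with imperfect power,
features can enter the rescued set because the treated contrast narrowly
missed significance. The estimated rescued fraction is therefore an upward-
biased estimator when power is moderate — visible and quantified in the
package's recovery tests. PCA overview is a QC view only; no batch
correction is offered.
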