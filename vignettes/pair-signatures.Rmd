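---
title: "Immune-related lncRNA pair signatures: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-related lncRNA pair signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpair)
```

## The problem

Prognostic gene signatures built on absolute expression values inherit every
normalization and batch artifact of the platform they were trained on. A
*pair* signature sidesteps this: for two genes A and B measured in the same
sample, the indicator

$$ S_{AB}(s) \;=\; \mathbf{1}\{x_A(s) > x_B(s)\} $$

depends only on the within-sample ranking, so it is invariant to any
strictly increasing transform of that sample's measurements — FPKM versus
TPM, log versus linear, quantile normalization, all leave it untouched.
`lncpair` implements this idea for immune-related long noncoding RNAs
(lncRNAs) in tumor cohorts with survival follow-up, the setting where it has
been used for hepatocellular carcinoma: candidate lncRNAs are first tied to
immune biology by coexpression with a curated immune-gene list, restricted to
those differentially expressed between tumor and normal tissue, exhaustively
paired, and the pairs fed to a penalized Cox survival model with stability
filtering. The fitted risk score $\sum_i \beta_i S_i$ is dichotomized at a
model-based cutpoint and the resulting groups examined against survival,
clinicopathological factors, immune infiltration, checkpoint genes and
predicted drug sensitivity.

## Pipeline stages and the parameters that matter

**Coexpression screen** (`coexpression_screen`). A lncRNA is immune-related
when some immune gene satisfies $|r| > 0.4$ with correlation-test
$p < 0.001$ on $\log_2(x+1)$ values across all samples. Pearson correlation
is the default (the established template for this screen); Spearman is a
switch. The magnitude $|r|$ is thresholded rather than $r$ itself because
immune regulation is bidirectional; `signed = TRUE` restores the one-sided
reading.

**Differential expression** (`moderated_de_test`). A two-group
empirical-Bayes moderated t-statistic: the per-gene pooled variance
$s^2_g$ (d residual df) is shrunk toward a prior $s_0^2$ with prior df
$d_0$, both estimated by moment matching of $\log s^2_g$ against the
scaled-F sampling theory, and the statistic uses $d + d_0$ df. This is
authored in the package rather than delegated so the pipeline's inferential
core is self-contained and directly testable; the test suite cross-checks
it against limma on heteroscedastic data ($d_0$, $s_0^2$ and every
t-statistic agree to $10^{-6}$). One numerical convention is ours: when the
observed log-variances show no excess spread over the $\chi^2$ sampling
expectation, the prior df is infinite and we use the *geometric mean*
variance as the common value, so the equal-variance limit reduces exactly
to the pooled two-sample t. Genes are flagged at $|\log_2 FC| > 1$ and
Benjamini–Hochberg FDR $< 0.05$, with the FDR taken within the tested
(immune-related lncRNA) set, matching the screen-then-test ordering. Whether
the fold change should be a difference of $\log_2(x+1)$ means (our choice)
or the log of a ratio of raw means is not settled by the template; the
$\log_2(x+1)$ reading is the limma-conventional one.

**Pairing and validity** (`build_pair_matrix`, `validity_filter`). All
$\binom{k}{2}$ ordered pairs (lexicographic $A < B$); ties score 0 by the
literal rule. The validity rule — both indicator outcomes in more than 30%
of samples — is read as `one_frequency` strictly inside $(0.3, 0.7)$: a
near-constant indicator carries no prognostic contrast, which is the rule's
stated motivation, and only the two-sided reading enforces it. The 0.3 is a
knob (`min_frac`); related work uses anywhere from 0.2 to 0.5. Pairs are
generated in deterministic chunks so large gene sets stream instead of
allocating one giant Boolean intermediate.

**Selection cascade** (`fit_pair_signature`). Four stages:

1. *Univariate screen*: single-covariate Cox per pair (Efron ties — the
   data are day-resolution, ties are routine), Wald $p < 0.05$.
   Non-converging pairs (monotone likelihood) are dropped with a warning.
2. *Stability selection*: `n_reps` repetitions of 10-fold cross-validated
   LASSO-Cox, each on a bootstrap resample of the cohort; a pair scores a
   selection each time its coefficient is nonzero at the CV-chosen
   $\lambda$; pairs selected in more than `freq_threshold` repetitions
   (default 100 of 1000, i.e. 10%) become candidates. Each repetition runs
   on a deterministic substream of the master seed, so results do not
   depend on execution order. The "repetition = bootstrap resample"
   reading is the standard stability-selection construction and the one
   that makes a frequency threshold meaningful; `resample = "cv-only"`
   gives the alternative reading (only fold assignments refreshed).
3. *Stepwise Cox*: bidirectional AIC-minimizing search from the null model
   over the candidates (duplicate indicator columns deduplicated first).
   The entire visited sequence is kept.
4. *AUC sweep*: the 5-year time-dependent AUC of every visited model's
   risk score; the arg-max model is the signature. Running the sweep over
   the stepwise sequence (rather than stepwise after the sweep) is our
   resolution of an ordering the template leaves ambiguous.

Two $\lambda$ conventions are exposed. The default, the CV-deviance
minimum, maximizes sensitivity to real signal, and is what the template
literature reports. Its known cost is null behaviour: on data with *no*
signal the CV curve is flat, its empirical minimum falls at interior
$\lambda$, and noise features are selected far more often than the 10%
frequency threshold — so the threshold does not, by itself, control false
selections in a signal-free world. `lambda_rule = "1se"` restores
conservative null behaviour (observed null selection frequencies near
zero) at some cost in sensitivity. The package documents this rather than
hiding it: on cohorts with planted signal the default rule recovers
essentially all planted pairs while the downstream stepwise/AIC stages
prune chance survivors.

**Time-dependent ROC** (`td_roc`). Cumulative/dynamic ROC at horizon $t$
with Kaplan–Meier weighting (the Heagerty–Lumley–Pepe estimator): cases
are events by $t$, controls survivors past $t$,
$TP(c) = [1-S_c(t)]\,P(X>c)/[1-S(t)]$ and
$FP(c) = S_c(t)\,P(X>c)/S(t)$ with $S_c$ the KM estimate within
$\{X > c\}$. This estimator is implemented in the package because no
pre-installed package provides it. It can be locally non-monotone under
censoring (a known property); we isotonize the curve with a running
maximum along the threshold sweep, which has no effect in the uncensored
limit, where the curve provably equals the classical empirical ROC and its
area the Mann–Whitney statistic (asserted to $10^{-9}$ in the tests).

**Cutpoint** (`aic_cutpoint`). Candidate cutpoints are midpoints between
consecutive sorted unique scores, restricted so each side keeps at least
10% of samples — the "maximum inflection point" phrasing of the template
is not operational, and without the side constraint the AIC minimum can
land on degenerate 2-versus-rest splits. Each candidate dichotomizes the
score into one binary Cox covariate; minimum AIC wins, ties toward the
smaller cutpoint. In a signal-free score the chosen cutpoint is unstable
by construction; the returned attribute `delta_aic_vs_null` flags how
little the best split improves on the null model.

**Evaluation and immune modules.** Kaplan–Meier curves with the two-group
log-rank test; chi-square tests of risk group against clinical factors
(sparse categories with expected count < 1 merged, unknowns excluded
per-test, not per-sample — different factors are legitimately observed on
different case counts); rank-based score comparisons across factor levels.
Note one deliberate divergence: the template names a "Wilcoxon signed-rank
test" for comparisons between independent groups; the signed-rank test is
for paired data, so the package uses the Mann–Whitney rank-sum test
throughout. Clinical factors enter Cox models as ordinal scores via a
declared level dictionary; multivariate entry requires univariate
$p < 0.05$. Immune-infiltration and IC50 analyses consume *precomputed*
tables (seven deconvolution methods' outputs; ridge-predicted IC50s) —
re-deriving those estimators is out of scope by design — and use Spearman
correlation and rank-sum tests, so all three immune analyses are invariant
to monotone transforms of the non-score variable.

## The synthetic cohort generator

`simulate_cohort()` produces the ground-truth worlds every claim above is
tested in. Expression is log-normal (the pipeline consumes FPKM-scale
abundances, not counts, so a negative-binomial read model would add
realism the method never sees): gene baselines $\mu_g \sim U(2,7)$ on the
$\log_2$ scale, unit noise, and shared latent factors of ~10 immune genes
each. Immune-correlated lncRNAs load on one factor with loading
$a = \sqrt{r/(1-r)}$, giving population correlation $r$ (default 0.6) with
that factor's immune genes. DE lncRNAs are drawn from the
immune-correlated set with $|\log_2 FC| = 2$, 90% upregulated — tumor
cohorts in this setting show strongly asymmetric DE. Planted prognostic
pairs share a baseline and shift within each pair, so their indicator
frequency concentrates near 0.5 and survives the validity filter; the
hazard is exponential, $h_0 \exp(\sum_i \beta_i (S_i - 1/2))$ with
$h_0 = 5\times10^{-4}$/day (median baseline survival ≈ 3.8 years, a
realistic liver-cancer scale), uniform censoring on (0, 10 years) (~46%
censoring at baseline), and times rounded to whole days so ties occur as
in registry data. Clinical covariates (stage, ECOG, vascular invasion,
grade, Child-Pugh) are sampled with logistic tilts along the standardized
linear predictor, so they associate with risk as real staging variables
do, and Child-Pugh carries occasional "unknown" entries.

Cohort defaults are 374 tumor / 50 normal samples — the TCGA-LIHC shape —
with 60 immune genes, 300 lncRNAs (60 immune-correlated, 40 DE) and **10
planted pairs at $\beta = 1$**. Ten pairs was chosen once, on realism
grounds: the reference signature in this literature has 30 pairs, and a
10-pair planted signature yields a linear-predictor SD ≈ 1.6 and a
population C-index ≈ 0.78, typical of published pair signatures; a 5-pair
signature sits at the edge of the C ≈ 0.7 regime where out-of-sample
discrimination claims become knife-edge.

What the generator does **not** emulate: batch effects, library-size
artifacts (irrelevant by rank invariance, but real data would still carry
them into the screening stage), count-level noise at low abundance,
correlated censoring, and biologically structured immune infiltration
(the infiltration and IC50 generators plant monotone associations with
risk, nothing more). Passing tests therefore demonstrate that the
*procedure* recovers what it is designed to recover under its own model
class — not that any particular real-data signature is correct.

## Numerical choices

* Cox fits use `survival::coxph` with Efron ties everywhere; penalized
  fits use `glmnet`. The stability loop fixes `nlambda = 15`,
  `lambda.min.ratio = 0.15`, `thresh = 1e-4`: only membership of the active
  set at the CV-optimal $\lambda$ matters for a selection count, and the
  dense small-$\lambda$ tail of the default path is by far the most
  expensive part of a penalized Cox fit on bootstrap data (which glmnet
  handles ~30× slower than unique-time data) while contributing nothing
  to selection in our benchmarks.
* Stepwise AIC uses $-2\ell + 2p$ on the Cox partial likelihood; a move
  must improve AIC by more than $10^{-8}$ to be accepted.
* Signature JSON is written with 17 significant digits, the smallest
  count that round-trips IEEE doubles exactly.
* Test problem sizes: screening recovery uses 50 replicates of a 350-sample
  cohort; selection recovery 20 replicates of 200 repetitions on 205 pairs
  × 300 samples; the end-to-end run uses 50 LASSO repetitions at a 10%
  frequency threshold. These sizes make the full validation suite a
  coffee-break run on one core while keeping every binomial assertion
  inside comfortable confidence bands.

## Known limitations

* The validity filter cannot reproduce the exact pair counts of the
  motivating analysis; its published pair count implies a stricter
  effective filter than the stated 30% rule, and the precise rule is not
  recoverable from the text. The threshold is a knob, not a claim.
* With `lambda_rule = "min"`, selection frequencies on signal-free data do
  not stay below the candidate threshold (see above); interpret the
  frequency table jointly with the univariate screen and stepwise stages.
* The AIC cutpoint is only as stable as the risk-score separation;
  `delta_aic_vs_null` should be inspected before trusting a split.
* Normal-tissue samples enter only the differential-expression stage;
  they carry no survival information and are excluded from all modeling.
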