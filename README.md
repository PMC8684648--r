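# lncpair

Rank-based prognostic signatures from **pairs of immune-related lncRNAs**
in tumor transcriptomes, with survival model fitting, risk stratification
and downstream immune/clinical association analyses.

## The idea

For genes A and B measured in the same sample, the pair indicator

    S_AB(s) = 1  if  x_A(s) > x_B(s),  else 0

depends only on the within-sample ranking, so a signature built from pair
indicators is invariant to normalization, platform scale, and any
monotone transform of a sample's measurements. `lncpair` implements the
full construction used for hepatocellular carcinoma cohorts:

1. **Screen** lncRNAs coexpressed with immune genes (|r| > 0.4,
   p < 0.001 on log2(FPKM+1)), then keep those differentially expressed
   between tumor and normal tissue (empirical-Bayes moderated t,
   |log2FC| > 1, BH FDR < 0.05).
2. **Pair** all retained lncRNAs into a 0/1 indicator matrix; keep pairs
   whose indicator is informative in >30% of samples on both sides.
3. **Select**: univariate Cox screen → repeated cross-validated
   LASSO-Cox on bootstrap resamples with a selection-frequency threshold
   (the 100-of-1000 rule) → bidirectional stepwise Cox → the model
   maximizing the 5-year time-dependent AUC (Kaplan–Meier-weighted
   cumulative/dynamic ROC).
4. **Stratify** at the AIC-optimal cutpoint of the risk score
   `RiskScore = Σ βᵢ Sᵢ`, then evaluate: Kaplan–Meier/log-rank,
   chi-square and rank tests against clinicopathological factors,
   univariate/multivariate Cox independence, Spearman correlation with
   immune-cell infiltration estimates, checkpoint-gene expression, and
   predicted chemotherapy IC50 between risk groups.

A synthetic-cohort generator (`simulate_cohort()`) plants immune-gene
correlation blocks, differentially expressed lncRNAs, prognostic pairs
driving an exponential proportional-hazards model, and right censoring —
so every stage can be validated against known ground truth.

## Worked example

```r
library(lncpair)

res <- run_pipeline(tempfile("demo"), config = sim_config(), seed = 11,
                    n_reps = 50)
str(res$metrics)
```

```
List of 14
 $ n_irlncrna        : int 60
 $ n_de_lncrna       : int 40
 $ n_pairs_total     : int 780
 $ n_pairs_valid     : int 374
 $ n_pairs_univariate: int 211
 $ n_candidates      : int 95
 $ n_signature_pairs : int 21
 $ auc_5yr           : num 0.966
 $ cutpoint          : num 2.05
 $ n_high            : int 149
 $ n_low             : int 184
 $ logrank_p         : num 6.38e-59
 $ holdout_cindex    : num 0.821
 $ planted_recovery  : num 0.6
```

Reading this run: of 300 simulated lncRNAs, 60 pass the immune
coexpression screen and 40 are differentially expressed, giving
C(40,2) = 780 pairs, 374 of them valid. The cascade reduces these to a
21-pair signature containing 6 of the 10 planted prognostic pairs (pairs
sharing genes are partly interchangeable, so recovery by exact identity
understates the captured signal); its 5-year time-dependent AUC is 0.966
on the training split and the held-out concordance is 0.821. The AIC
cutpoint splits the cohort 149 high / 184 low risk with log-rank
p ≈ 10⁻⁵⁹.

Individual stages are ordinary functions over tibbles —
`coexpression_screen()`, `moderated_de_test()`, `build_pair_matrix()`,
`validity_filter()`, `fit_pair_signature()`, `risk_score()`,
`stratify_cohort()`, `km_logrank()`, `independence_cox()`,
`risk_infiltration_correlation()` … — with `tidy()`/`glance()` methods on
fitted signatures and `autoplot()`/`plot_*()` for the result types. A
thin command-line wrapper with per-stage subcommands lives at
`inst/cli/lncpair.R`.

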