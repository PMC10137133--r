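# nccborrow

Time-to-event analysis for platform trials that borrow the **concurrent
observation time (COT)** of **non-concurrent controls (NCC)** via left
truncation.

## The problem

In a platform trial, experimental arms join an ongoing master protocol that
shares one control arm. When the arm of interest joins at calendar time
`t1`, control patients randomized earlier are *non-concurrent* for that
comparison. Dropping them wastes information; pooling their full follow-up
risks bias if the control hazard changed over time (e.g. an improving
standard of care). But the part of an NCC patient's follow-up that occurs
*after* `t1` — their concurrent observation time — was accrued under the
same era as the concurrent controls (CC). On the time-since-randomization
scale it starts at `L = t1 - enroll`, so it can be borrowed by **left
truncation**: the subject enters risk sets only from `L` on,

```
R_i = { j : y_j >= t_i > L_j }
```

and the delayed-entry Kaplan–Meier estimator, Cox partial likelihood
`lambda(t|x) = lambda0(t) exp(beta x)`, and log-rank test need only this
risk-set modification. Validity rests on an exchangeability assumption — CC
and post-truncation NCC share one hazard — for which the package provides a
delayed-entry log-rank diagnostic.

The audience is trial statisticians evaluating control-borrowing strategies:
the package pairs the estimation machinery with a calendar-time trial
simulator and a Monte Carlo layer that measures bias, efficiency, coverage
and type-I error of `cc_only`, `pooled_cot` and (as a biased straw man)
`pooled_full_ncc` analyses.

## Worked example

```r
library(nccborrow)

design <- default_design(n_per_arm = 100)  # NCC accrual [0,3], CC/treatment [3,6],
                                           # control hazard 0.2 -> 0.134 at t1 = 3,
                                           # treatment 0.114, study ends at 15
subjects <- simulate_trial(design, seed = 2023)
comparison_table(subjects, design$t1_entry,
                 true_hr = true_hazard_ratio(design))
#>          strategy n_records n_events n_truncated_out true_hr    hr    se ...     p
#> 1         cc_only       200      136               0    0.85 0.856 0.172 ... 0.366
#> 2      pooled_cot       277      202              23    0.85 0.764 0.151 ... 0.074
#> 3 pooled_full_ncc       300      225               0    0.85 0.740 0.147 ... 0.040
```

Pooling the truncated NCC observation time adds 77 control records (23 NCC
subjects failed before their entry time and contribute nothing) and shrinks
the standard error of the log hazard ratio from 0.172 to 0.151 — the
efficiency gain the method exists for. Over replicates the single-dataset
noise averages out:

```r
monte_carlo(design, c("cc_only", "pooled_cot"), reps = 500, seed = 20230331)
#>    strategy reps n_converged mean_beta     bias empirical_sd mean_model_se
#>     cc_only  500         500   -0.1580 0.004147       0.1649        0.1668
#>  pooled_cot  500         500   -0.1565 0.005572       0.1464        0.1492
#>  coverage rejection_rate truncated_out_mean
#>     0.954          0.142               0.00
#>     0.960          0.166              25.13
```

Both strategies are essentially unbiased for the design log HR with nominal
95% coverage; the pooled-COT analysis has the smaller spread and the higher
power. The exchangeability diagnostic on the single dataset:

```r
exchangeability_check(subjects, design$t1_entry)
#> Delayed-entry log-rank test:
#>   chi-squared = 2.8703 on 1 df, p = 0.09023
```

## Command line

```sh
Rscript inst/cli/nccborrow simulate --config design.yaml --seed 3 --out subjects.csv
Rscript inst/cli/nccborrow analyze  --subjects subjects.csv --t1 3 --out table.tsv
Rscript inst/cli/nccborrow mc       --config design.yaml --reps 500 --seed 3 --out mc.tsv
Rscript inst/cli/nccborrow km       --records records.csv --out km.tsv --plot km.pdf
```

(after installation the script also lives at
`system.file("cli", "nccborrow", package = "nccborrow")`). Exit codes: 0
success, 2 usage/config error, 3 analysis failure.

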