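# fermsens

Inverse-system soft sensing for fed-batch *Pichia pastoris* fermentation.

## The problem

In industrial *P. pastoris* cultivations producing recombinant inulinase,
the variables that matter most — cell concentration *X* (g/L), residual
methanol *S* (g/L) and enzyme concentration *E* (U/mL) — can only be
assayed offline, hours after sampling. What is measured continuously is
dissolved oxygen, pH, broth volume, the four feed rates (methanol, ammonia
water, phosphate, antifoam) and the environment (temperature, agitation,
airflow). `fermsens` reconstructs the unmeasurable states from the
measurable signals in real time — a soft sensor built on the
inverse-system method.

## What is inside

The package covers the whole chain:

1. **Grey-box process model.** Six balance ODEs for
   x = (X, S, E, C_L, [H⁺], V) with pluggable specific-rate laws
   (`default_rate_laws()`: Monod × substrate inhibition × oxygen
   limitation × logistic crowding × product burden for growth;
   yield/maintenance couplings; Luedeking–Piret enzyme production),
   integrated with a reproducible fixed-step RK4
   (`simulate_fermentation()`).
2. **Invertibility diagnostic.** The soft sensor exists because the
   time-derivative vector (z̈₁, ż₁, ż₂) of the measurable outputs
   (z₁, z₂, z₃) = (C_L, [H⁺], V) is locally an invertible function of
   (X, S, E): `jacobian_outputs()` verifies rank J = 3 numerically, with
   scale-equilibrated singular-value thresholding; `invertibility_scan()`
   sweeps a whole trajectory.
3. **Preprocessing.** Spike-suppressing moving-average filter
   (innovation clamped at a threshold D), five-point numerical
   differentiation (exact through degree-4 polynomials), min–max/z-score
   normalisation with train-frozen statistics, local least-squares
   alignment of 4-hourly offline assays.
4. **From-scratch FCNN + Adam.** Forward/backward passes, MSE loss,
   plain gradient descent and the Adam optimizer (decayed moment
   estimates with bias correction), all in plain matrix code
   (`train_fcnn()`).
5. **Soft sensor.** `soft_sensor()` fits one network per hidden state on
   the 13-feature inverse-extended-model input
   (x₄, x₅, x₆, ẋ₄, ẍ₄, ẋ₅, u₁…u₄, Tw, Sa, Fa) and returns a classed
   object with `predict`, `summary`, `coef`, `residuals`, `plot` and
   `update` (online correction on a sliding window) methods;
   `cascade_identity_check()` measures how close the cascade of process
   and inverse model is to the identity map.
6. **Synthetic campaigns.** `generate_campaign()` emulates the study
   conditions: 240 h methanol induction, near-constant demand-sized
   feeds, 0.5 h logging, 4 h offline assays (60 pairs per batch),
   Gaussian sensor noise at instrument accuracies (DO 0.5%, pH 0.02,
   flow 2%).

A thin command-line dispatcher over these functions is installed at
`inst/cli/fermsens.R` (subcommands `simulate`, `generate`,
`invertibility-check`, `train`, `predict`, `evaluate`).

## Worked example

```r
library(fermsens)

# a noisy single-batch induction campaign
cfg  <- campaign_config(jitter_frac = 0)
camp <- generate_campaign(cfg, seed = 1, noisy = TRUE)
camp
#> Synthetic campaign: 1 batch(es), 60 offline pairs each, with sensor noise

# is the inverse problem well posed at mid-induction?
tr <- camp$trajectories[[1]]
i  <- which.min(abs(tr$t_h - 120))
jacobian_outputs(trajectory_states(tr)[i, ],
                 c(fC = tr$fC_Lh[i], fN = tr$fN_Lh[i],
                   fM = tr$fM_Lh[i], fA = tr$fA_Lh[i]),
                 default_rate_laws(cfg$kinetics), cfg$config)
#> Output-derivative Jacobian w.r.t. (X, S, E):
#>                 x1         x2       x3
#> z1_ddot  2.295e+00  1.870e+00 -0.15800
#> z1_dot  -1.280e+00 -1.042e+00  0.08736
#> z2_dot   8.094e-11  1.223e-10  0.00000
#> singular values: 1.747, 0.07582, 0.0002115
#> rank = 3 (tol 1.75e-08) -> locally invertible

# fit the soft sensor and evaluate it
model <- soft_sensor(camp$dataset, epochs = 3000, seed = 1)
evaluate_soft_sensor(model)
#> Soft-sensor evaluation
#> MSE (normalised units):
#>              x1        x2        x3
#> train 9.234e-06 2.207e-07 3.712e-06
#> test  3.840e-02 2.712e-01 1.473e-02
#> Median relative error:
#>        x1        x2        x3
#> 0.0001567 0.0001145 0.0020280

# cascade of process + inverse model ~ identity map on the true states
round(cascade_identity_check(model, camp)$median_rel_err, 4)
#>     x1     x2     x3
#> 0.0181 0.0182 0.0242
```

Reading the numbers: rank 3 with singular values far above the 1e-8
threshold means the measurable outputs carry enough independent
information to pin down all three hidden states at this operating point.
Training MSEs near zero show the networks interpolate the 42
chronologically-first assay pairs; the larger test MSEs reflect genuine
extrapolation to the last 30% of a monotonically evolving process. The
cascade check is the bottom line: against the simulator's *true* states
(not the noisy assays), the reconstruction is within ~2% median relative
error per target at full instrument noise.

## Vignette

`vignettes/soft-sensing-methods.Rmd` documents the model and its
assumptions, the invertibility analysis, every preprocessing and
optimisation choice with defaults and rationale, what the synthetic
campaign does and does not emulate, and known limitations.
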