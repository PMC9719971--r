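# abxsc — antibiotic-cessation outcome estimation with recurrent embeddings and synthetic controls

Deciding when to stop intravenous antibiotics in the ICU is a daily clinical
decision with no patient-level evidence base: stopping too early risks
treatment failure, over-treating drives toxicity and antimicrobial
resistance, and cessation timing cannot ethically be randomised. `abxsc`
estimates, for each patient and each day of their antibiotic course, the
expected ICU length of stay (LOS) and in-stay mortality under the two
actions available that day — **stop** antibiotics or **continue** — from
observational, EHR-like daily data.

The method couples two components:

1. **A supervised bi-directional LSTM sequence autoencoder** (compiled core,
   analytic backpropagation) that turns a patient's trajectory up to day *t*
   into an embedding *z*ᵢᵗ, trained with a combined loss
   *w*ᵣ·*L*ᵣ + *w*ₛ·*L*ₛ — reconstruction RMSE over observed cells plus a
   supervised loss on a linear outcome head — so that proximity in embedding
   space implies similar expected outcomes.
2. **An adapted synthetic-control estimator.** For each day *t*, donor pools
   are partitioned by treatment status: stays receiving antibiotics on day
   *t* (the *continue* pool) and stays whose first antibiotic-free day is
   *t* (the *stop* pool). For a subject on day *t*, the *k* = 10
   Euclidean-nearest donors are drawn per scenario and weighted by the ridge
   objective

   Lossᵢˢ'ᵗ = Σ_d [ *z*ᵢ,dᵗ − Σⱼ *x*ⱼ,dˢ'ᵗ *w*ᵢ,ⱼˢ'ᵗ ]² + Σⱼ (*w*ᵢ,ⱼˢ'ᵗ)²,

   solved in closed form as (XᵀX + λI)⁻¹Xᵀz with λ = 1; the scenario outcome
   Ỹᵢˢ'ᵗ is the (renormalised) weighted average of the donor labels.

Because one of the two actions is always factual, every treatment day is a
stop-*impact* / continue-*control* day and the cessation day is the
stop-*control* / continue-*impact* day, which makes the estimator's
calibration measurable on real outcomes (control days) while the impact
days quantify the unobserved alternative.

Real credentialed ICU EHR data cannot ship with a package, so `abxsc`
includes a **cohort simulator** with latent infection-severity and frailty
processes, a noisy threshold + protocol-cap stopping policy, informative
missingness, and — crucially — a known, queryable counterfactual ground
truth (`true_counterfactual()`), so the whole pipeline is testable and the
true causal effect of cessation timing is a recoverable parameter.

## Worked example

```r
library(abxsc)

cfg <- experiment_config(
  sim          = sim_config(n_stays = 500),           # true effect: 0.8 days/treatment day
  encoder_los  = encoder_config("los", embedding_dim = 16, hidden_size = 32, epochs = 10),
  encoder_mort = encoder_config("mortality", embedding_dim = 16, hidden_size = 32, epochs = 10),
  k = 10, n_boot = 200, seed = 2024)

art <- run_experiment(cfg, "abxsc_out")
art$reports$los$table
#>    scenario    role n_stays n_days mean_delta p_value   mae  rmse
#> 1:     stop  impact     372   1269       2.13 2.0e-42  4.13 11.76
#> 2:     stop control     388    388       0.00 7.3e-01  1.25  2.21
#> 3: continue  impact     395    395      -1.66 7.2e-15  2.01  2.55
#> 4: continue control     475   1743      -0.48 3.6e-01  1.58  2.63
```

Reading the table: on **control** days (where the estimated scenario is the
one the patient actually took) the mean delta between true and estimated
LOS is ~0 days with non-significant rank-sum tests — the estimator
reproduces known outcomes. On **stop-impact** days the realised LOS exceeds
the stop-scenario estimate by 2.13 days on average (p ≈ 10⁻⁴²): stopping
antibiotics earlier is estimated to shorten stays, and the magnitude agrees
with the simulator's built-in causal effect (0.8 days per avoided treatment
day over an average of ~2.7 remaining treatment days). The mirrored
continue-impact delta is negative, as it should be.

```r
art$whatif[["7"]][c("n_stays", "mean_delta", "p_value")]
#> 51 stays treated > 7 days; mean estimated LOS reduction 3.03 days (p = 0.042)

# query the simulator's ground truth directly
gt <- art$cohort$ground_truth
true_counterfactual(gt, gt$stay_id[1], day = 1, scenario = "stop")
#> 6.06   # vs realised LOS 8.46
```

A command-line entry point wrapping the same pipeline lives at
`inst/cli/abxsc.R`:

```sh
Rscript inst/cli/abxsc.R --config my_experiment.yaml --out results/ --seed 7
```

See `vignettes/methods.Rmd` for the model, the simulator's assumptions, the
scenario conventions, and known limitations.

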