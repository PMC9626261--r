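# styledyn

Dynamic Dirichlet mixture modelling of creation-style distributions.

A "creation style" is the set of generative statistics behind a cultural
artefact — for a melody, its pitch and rhythm bigram probabilities; for a
lexicalized audio corpus, its token unigram probabilities. Each song becomes
a probability vector θ with a year stamp, and a yearly corpus becomes a
population of such vectors. styledyn quantifies how that population evolves
and forecasts where it is going, for researchers in cultural evolution,
computational musicology and related fields who work with year-stamped
collections of discrete probability vectors.

## The model

The year-*t* style distribution is a Dirichlet mixture whose parameters all
move in time (a *dynamic* Dirichlet mixture):

P(θ, t) = Σₖ π_k(t) · Dir(θ; α_k(t), μ_k(t)),

where π_k is cluster k's relative frequency (inter-cluster dynamics), μ_k
its centre and α_k its concentration — cluster variance is
μᵢ(1−μᵢ)/(α+1), so growing α means a contracting cluster (intra-cluster
dynamics). The pipeline:

1. **Featurize** note tables or token sequences into style vectors
   (extended-pitch-class 12×36 bigrams, 48×48 metrical-position bigrams,
   or unigrams over a fixed vocabulary).
2. **Cluster** the vectors with an EM-fitted discrete-distribution mixture
   and hard-assign each song.
3. **Estimate** π_k(t), α_k(t), μ_k(t) per year by exponential-decay
   weighted averaging with time constant τ (selected by next-year
   likelihood).
4. **Forecast** each log-parameter series with a local-linear-trend state
   space model — the latent velocity is the log relative fitness
   ln(w_k/w̄) of replicator dynamics — damped by a backtest-optimized
   fitness reduction factor ρ ∈ [0.01, 1].
5. **Evaluate** against static baselines with SKL divergences, log-squared
   concentration errors, and mixture log-likelihood gains over a K = 1
   static model.

A generative simulator (declared parameter trajectories, and an agent-based
creator-transmission model with cluster- and trait-level fitness) supplies
ground truth for every stage.

## Worked example

```r
library(styledyn)

sim <- sample_ddmm_dataset(example_trajectory_spec(years = 1985:2009), seed = 42)
ex <- run_style_experiment(sim$styles, K = 3, t0 = 1999, horizon = 10,
                           tau = 5, rho = "optimize", n_restarts = 5, seed = 42)
ex$rho
#>    pi alpha    mu
#>  1.00  0.01  0.05
ex
#> Style-evolution experiment: K = 3, t0 = 1999, horizon = 10, tau = 5
#> mean error ratios vs static:
#>   alpha 1.262
#>   mu    1.087
#>   pi    0.729
#> mean log-likelihood gain vs K = 1 static: 2.712
head(ex$gains, 3)
#> # A tibble: 3 × 5
#>       t     n model_ll baseline_ll  gain
#>   <int> <int>    <dbl>       <dbl> <dbl>
#> 1  2000    50     7.32        4.59  2.73
#> 2  2001    50     7.40        4.68  2.73
#> 3  2002    50     7.23        4.83  2.41
```

The scenario has a persistent frequency trend but constant cluster shapes,
and the output reads accordingly. The backtest picks a trend-following
ρ = 1 for the mixture probabilities and near-total damping (0.01, 0.05)
for concentrations and means. The error ratios are forecast error divided
by the static model's error: 0.729 for π means the trend-following
forecast beats freezing the referential year's frequencies by ~27%, while
ratios near 1 for α and μ mean the damped forecasts fall back to
static behaviour where no real trend exists. The mean gain of ~2.7 nats
per song says the forecast three-cluster mixture explains held-out songs
far better than a single pooled Dirichlet. `autoplot(ex)` overlays
estimated, actual and forecast trajectories; `tidy()`/`glance()` methods
return everything as tibbles.

See the vignette (`vignettes/style-evolution-methods.Rmd`) for the model,
estimation conventions, and the simulator's study conditions.

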