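---
title: "Modelling and forecasting creation-style distributions with styledyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and forecasting creation-style distributions with styledyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(styledyn)
```

## The problem

A creation style is the set of generative statistics behind a cultural
artefact: for a melody, the transition probabilities of its pitches and of
its metrical onset positions; for a lexicalized audio corpus, the unigram
probabilities of its timbre or harmony tokens. Each song is reduced to a
probability vector $\theta$ on a fixed simplex, stamped with its year of
creation. A society's repertoire in a given year is then a *population* of
such vectors, and cultural change is the motion of that population: clusters
(genres, scales, rhythmic modes) rise and fall in frequency (*inter-cluster*
dynamics), while individual clusters drift or contract (*intra-cluster*
dynamics). styledyn implements a complete pipeline for quantifying both and
for forecasting the future distribution.

## Featurization

Melodies arrive as note tables (`song_id`, `year`, `pitch`, `bar`,
`position`), already transposed to C major / A minor — transposition is an
input contract, not a computation, so no key detection is attempted. Pitch
transitions use the extended pitch class representation: a move from pitch
$p'$ to $p$ maps to the cell $(q', q)$ with $q' \equiv p' \bmod 12$ and
$q \equiv q' + p - p' \bmod 36$, giving a $12 \times 36$ table that is
independent of register and distinguishes signed intervals from $-17$ to
$+17$ semitones ($\pm 18$ coincide). Rhythm transitions are pairs of
metrical positions on a 48-unit bar grid, a $48 \times 48$ table; position
0 is the downbeat and position 12 the second beat of 4/4. Onsets that
cannot be expressed on the 48-unit grid are excluded (with a warning), and
consecutive notes are treated as adjacent regardless of rests and bar
lines: the corpora the method targets encode melodies continuously, and
breaking adjacency at rests would discard most of the evidence in sparse
songs. This is a modelling choice — long rests or section boundaries could
arguably break adjacency, and we flag it as a divergence risk for corpora
where such boundaries matter.

A song of $L$ notes yields exactly $L - 1$ bigram counts; the style vector
is the normalized count vector, with zeros preserved (probability flooring
happens only where densities or divergences are evaluated, so
featurization stays lossless).

## Clusters and their Dirichlet description

Styles are clustered with a K-component mixture of discrete distributions
fitted by EM on the raw counts: the component likelihood is multinomial, so
longer songs carry proportionally more evidence. (A configuration switch
normalizes rows first if equal song weights are preferred; counts are the
default because song length genuinely is evidence.) Random restarts
(default 10) guard against local optima, responsibilities are computed in
the log domain, component probabilities are floored at $10^{-8}$, and the
returned model is the best restart, with components canonically ordered by
descending mixture weight (the cluster numbering of any particular fit is
otherwise arbitrary). Each song is then *hard-assigned* to the component
maximizing its own count likelihood, ties to the lowest index.

Within a cluster, the population of style vectors is summarized by a
Dirichlet distribution
$\mathrm{Dir}(\theta; \alpha, \mu) = \frac{\Gamma(\alpha)}{\prod_i
\Gamma(\alpha\mu_i)} \prod_i \theta_i^{\alpha\mu_i - 1}$,
whose moments $E(\theta_i) = \mu_i$ and
$V(\theta_i) = \mu_i(1-\mu_i)/(\alpha+1)$ make $\mu$ the cluster centre and
$\alpha$ an inverse cluster size: a growing concentration is a contracting
cluster. We estimate $\mu$ as the (weighted) sample mean and $\alpha$ by
one-dimensional profile likelihood over $\ln\alpha$ on
$[\ln 10^{-2}, \ln 10^{6}]$, rather than a joint MLE over all
$\alpha\mu_i$: this mirrors the split used by the time-resolved estimator
below, and the variance identity makes $\alpha$ unidentifiable as the
dispersion vanishes, so the upper bound acts as an explicit cap (reported,
with a warning, when hit — e.g. when all member vectors coincide).

## The dynamic Dirichlet mixture and its estimation

The year-$t$ distribution of styles is modelled as
$$P(\theta, t) = \sum_{k=1}^{K} \pi_k(t)\,
\mathrm{Dir}(\theta;\, \alpha_k(t), \mu_k(t)),$$
with all three parameter families time-dependent: $\pi_k$ carries the
inter-cluster dynamics, $\mu_k$ the cluster shifts and $\alpha_k$ the
contractions.

Single-year ("slice") estimates are noisy when yearly samples are small, so
the working estimator pools all years $s \le t$ with exponential decay
weights $e^{(s-t)/\tau}$, normalized by $C(t) = \sum_s e^{(s-t)/\tau}$:
mixture probabilities and means are decay-weighted averages of the slice
values, and each concentration maximizes the decay-weighted sum of its
member songs' log Dirichlet densities with $\mu$ fixed at its weighted
value. Three conventions matter and are deliberate:

* the backward sum is truncated at the first data year (weights are finite
  and there are no data earlier);
* a (cluster, year) cell with no members contributes *no weight*, rather
  than a zero-valued statistic — the estimator averages estimates, not
  counts;
* the concentration likelihood weights member songs directly by their
  slice's decay factor, which makes the estimate independent of how finely
  the slices are binned.

The time constant is selected from the data: for each candidate $\tau$ and
each referential year $t_0$, the mixture estimated at $t_0$ from data up to
$t_0$ is scored on the *mean per-song* log-density of the styles of year
$t_0 + 1$ (mean, not sum, so years with different sample sizes are
comparable), and the curve is averaged over $t_0$. A time-window estimator
(uniform pooling over the last $w$ years; $w = 1$ is the simple slice
method) is provided as the comparison baseline.

## The state-space evolutionary model

Fitness-based replicator dynamics,
$\pi_k(t+1) = w_k \pi_k(t) / \bar w$ with
$\bar w = \sum_\ell w_\ell \pi_\ell(t)$, can be rewritten as an equation of
motion for log probabilities in which the *velocity* is the log relative
fitness, $v = \ln(w_k/\bar w)$. Observed log parameters are noisy, and
preferences themselves drift, so the package models each transformed
parameter series as

$$y(t) = x(t) + \varepsilon(t), \qquad x(t+1) = x(t) + v(t), \qquad
v(t+1) = v(t) + \eta(t),$$

with Gaussian $\varepsilon \sim N(0, \sigma^2)$ and
$\eta \sim N(0, \sigma_\eta^2)$. We read the observation noise as acting on
the observed series around a latent level advanced exactly by the velocity;
this is the standard local-linear-trend reading of noise "added to the
observed" value and makes the model a textbook state space. The two
variances are estimated by maximizing the marginal likelihood from a
forward Kalman filter with diffuse (large-variance) initialization, from
three starting points to avoid ridge-shaped local optima; smoothed level
and velocity come from the Rauch–Tung–Striebel smoother. Higher-order
variants (states for higher time derivatives, innovation entering the
highest) are available via `order`, with order 1 the default since nothing
in the data we target identifies more derivatives. Two numerical caveats:
the first `order + 1` prediction errors are excluded from the likelihood
(they are dominated by the diffuse prior), and the first few smoothed
states carry a small diffuse-initialization error, so invariants such as
"constant velocity when $\sigma_\eta^2 = 0$" hold exactly only past that
burn-in; terminal states, which forecasting uses, are unaffected (the
$\sigma_\eta^2 = 0$ fit reproduces the least-squares slope).

Forecasts extrapolate the terminal smoothed state,
$x(T+h) = x(T) + h\,\rho\,v(T)$, with a *fitness reduction factor*
$\rho \in [0.01, 1]$ damping the velocity: trends inferred from noisy,
smoothed series overshoot when trusted fully, and $\rho$ is selected per
parameter family by backtesting on held-out terminal years of the
trajectory (SKL error for $\pi$ and $\mu$, log-squared error for
$\alpha$). The smoothed rather than filtered terminal state is used — the
filtered state at $T$ ignores none of the data, but the smoothed state has
lower variance under the same information set; we flag this as a choice
the model class leaves open.

`forecast_ddmm()` applies this machinery per cluster to $\ln \pi_k$,
$\ln \alpha_k$ and $\ln \mu_{ki}$ (all three families in log domain: the
dynamics are stated for log probabilities and concentration errors are
measured in log space), then renormalizes $\pi$ across clusters and $\mu$
across components. Mean components whose past average probability is at or
below 0.01 are carried forward statically — rare components are dominated
by sampling noise and cannot be reliably extrapolated. Forecasting the
clusters independently and renormalizing is the *slow-evolution
approximation*: for velocities $v_k = \ln(w_k/\bar w)$ the normalized
decoupled update reproduces the coupled replicator update exactly at one
step, and to first order in $\max_k |v_k|$ over longer spans.

Logs of small probabilities are protected by a floor of $10^{-6}$; the
flooring operator raises deficient components to the floor and absorbs the
mass proportionally from the rest, which makes it exactly idempotent.

## Evaluation protocol

Backtests freeze a referential year $t_0$, estimate up to $t_0$, forecast
beyond it, and compare against the estimates actually realized later:

* $\pi$ error: SKL divergence (the *sum* of the two KL terms — conventions
  differ, and the choice is recorded here and in the function
  documentation) between predicted and actual K-vectors;
* $\mu$ error: unweighted mean over clusters of per-cluster SKL;
* $\alpha$ error: unweighted mean over clusters of
  $(\ln\hat\alpha - \ln\alpha)^2$;

each reported raw and normalized by the static model (the baseline that
freezes the $t_0$ parameters), whose own ratio is 1 by construction.
Aggregation across clusters and years is the unweighted mean.

Distribution-level accuracy is measured as the mean per-song mixture
log-density of held-out styles minus that of a single-cluster ($K = 1$)
static baseline. Two compensations are available because the decay
smoothing lags the data: the parameters used for target year $t_p$ can be
those predicted for $t_p + \Delta_p$ (look-ahead; values around 8 and 15
suit pitch- and rhythm-like statistics respectively), and every
concentration can be multiplied by a factor (default 5) because a single
year's distribution is more concentrated than the smoothed one. Both
default to the neutral values (0 and 1) in the synthetic experiments of
the test suite, where no smoothing-lag compensation is being studied.

## The generative simulator

`trajectory_spec()` + `sample_ddmm_dataset()` generate year-stamped
populations from a declared parameter trajectory: mixture probabilities
follow replicator dynamics with constant cluster fitness, concentrations
follow log-linear schedules, means interpolate linearly. Per song, a
cluster is drawn, then $\theta \sim \mathrm{Dir}(\alpha_k \mu_k)$, then
(by default) a count vector $\sim$ Multinomial($n$, $\theta$), emulating a
featurized symbolic sequence of finite length. The multinomial layer
matters: finite song length adds variance on top of the Dirichlet draw,
which biases likelihood-based concentration estimates downward (for
$\alpha = 40$ and $n = 300$ the moment-level attenuation alone is roughly
$\alpha_{\mathrm{eff}} \approx (1/(\alpha+1) + 1/n)^{-1} - 1 \approx 35$,
and the effect on the MLE is larger because rare cells contribute heavy
log tails). Parameter-recovery tests therefore run on the Dirichlet draws
themselves (`observe = "theta"`), which is the consistency property the
estimator owes; the finite-length attenuation is a property of real
featurized data that users should expect in absolute $\alpha$ levels.

`simulate_agents()` is the finite-population transmission model behind the
replicator equation: each new creator picks a cluster with probability
proportional to frequency times cluster fitness, picks a cultural parent
within it with probability proportional to a trait fitness
$w(\theta, k) = \exp(\beta\, s_k^\top \theta)$ (a declared linear score;
configurable), and inherits the parent's trait through Dirichlet copy
noise with concentration $\kappa$ (default exact copying, $\kappa=\infty$;
500 is a reasonable noisy-copy setting). The Dirichlet-mixture form is
only approximately closed under this process — exact closure would require
a special fitness/initial-condition pairing that is not available — so the
simulator's clusters stay *approximately* Dirichlet, which is what the
recovery tests rely on. At $N = 10^5$ the simulated cluster frequencies
track the deterministic replicator trajectory within 0.01 over ten
generations.

`sample_bigram_melody()` closes the loop from statistics back to artefacts:
it samples a playable note table from bigram conditionals (rows
renormalized; zero-mass rows fall back to the marginal) so that forecast
mean distributions can be *heard*, not just scored.

## Study conditions used by the test suite

The suite's scenarios are fixed, not tuned: three clusters on 6–8 cell
simplices with clearly separated means; constant-parameter recovery at 200
songs/year over 30 years with $n = 300$ events per song (yearly sample
sizes and song lengths of the order a popular-music chart corpus
provides); trend scenarios over 40 years with cluster fitness
(0.94, 1.0, 1.07) and one concentration doubling, 50 songs/year, forecast
from $t_0$ at year 20 over a 20-year horizon, 20 seeds; state-space
recovery at $\sigma = 0.1$, $\sigma_\eta = 0.02$, $T = 50$, 100
replicates. These sizes keep the whole suite around two minutes while
leaving comfortable statistical margins. Passing them demonstrates
internal consistency — that the estimators recover the model's own
parameters and that trend-following forecasting beats static baselines
when persistent trends exist. It does not demonstrate that real corpora
satisfy the model: real style distributions overlap, form hierarchies, and
their mean distributions evolve in correlated, low-dimensional ways that
the independent per-component forecasts only crudely capture.

## Known limitations

* Cluster number $K$ is user-specified; no model selection over $K$ is
  attempted.
* Hard assignment discards responsibility information; clusters that
  overlap heavily make both the labels and the per-cluster Dirichlet
  summaries unstable.
* Mean-distribution forecasts are the weakest family — high-dimensional,
  correlated component dynamics are forecast independently.
* The Gaussian-process baseline sometimes used as a comparison point for
  this model class is not implemented; the evaluation interfaces accept
  any trajectory, so external baselines can be plugged in.
* Forecasts are point forecasts; no predictive intervals are produced.
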