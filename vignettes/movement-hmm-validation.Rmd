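---
title: "Validating behavioural states decoded from movement HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating behavioural states decoded from movement HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Seabird tracking studies infer behaviours — above all foraging — from GPS
positions alone, usually with hidden Markov models (HMMs), and those
inferred behaviours feed into conservation decisions such as the placement
of protected areas. The inference is rarely validated, because behavioural
observations concurrent with tracking are hard to collect at sea. This
package implements the full analysis pipeline for the setting where such
validation *is* possible: an observer platform (a small boat) follows an
individual bird at a 50–200 m standoff, logging its own GPS position at
1 Hz together with the observed behaviour of the bird, and (for a subset of
tracks) the bearing and distance from the boat to the bird. The package
fits a suite of two-state HMMs to the track, decodes
foraging/not-foraging states, validates them against the observer's
ethogram, and assesses how well the platform's track stands in for the
bird's own.

```{r setup, eval = FALSE}
library(ternHMM)
```

## The model

Each track is reduced to per-second observations
$x_t = (r_t, \psi_t)$: the great-circle step length $r_t$ (km) between
consecutive fixes and the turning angle $\psi_t$ (radians), the signed
change in heading between consecutive steps. A latent first-order Markov
chain $S_t \in \{1, 2\}$ (1 = foraging, 2 = not-foraging) drives the
observations: conditional on $S_t = j$,

$$r_t \sim \mathrm{Gamma}(\mu_j, \sigma_j), \qquad
  \psi_t \sim \mathrm{vonMises}(\rho_j, \kappa_j),$$

independent of each other given the state. The gamma distribution is
parametrised by its mean and standard deviation (shape
$(\mu/\sigma)^2$, rate $\mu/\sigma^2$), the movement-ecology convention.
The chain has initial distribution $\delta$ and transition matrix
$\Gamma = (\gamma_{ij})$, and the likelihood is the usual forward product
$\delta P(x_1) \Gamma P(x_2) \cdots \Gamma P(x_T) \mathbf{1}$ with
$P(x_t)$ the diagonal matrix of state densities. We evaluate it with the
scaled forward recursion, so underflow cannot occur even on $10^5$-point
tracks.

Foraging flight is slow and tortuous; transiting flight is fast and
directionally persistent. The state with the smaller fitted mean step is
therefore labelled foraging (`label_states()`); when the step mean is
covariate-dependent the comparison is made at the median covariate value,
and with per-track step parameters the per-track means are averaged
first. Exact equality of means raises an error rather than guessing.

## The model suite

Seven variants differ in pooling and in use of the distance-to-colony
covariate $c$ (central-place foragers behave differently far from the
colony):

| model | state process | step parameters | covariate on transitions | covariate on step |
|---|---|---|---|---|
| 0 | pooled | pooled | – | – |
| 1 | per track | pooled | – | – |
| 2 | pooled | per track | – | – |
| 3 | per track | per track | – | – |
| 4 | pooled | pooled | yes | – |
| 5 | pooled | pooled | – | yes |
| 6 | pooled | pooled | yes | yes |

Turning-angle parameters are always pooled: "unique step length
parameters" is read literally, so the per-track observed-process variants
free only $(\mu_j, \sigma_j)$. The transition link is a multinomial logit
with zero diagonal linear predictors,
$\gamma_{ij} \propto \exp(\beta_{0,ij} + \beta_{1,ij} c)$, which for two
states reduces exactly to the per-off-diagonal logistic model. The
covariate enters the step distribution log-linearly,
$\mu_j = \exp(\beta^{\mu}_{0,j} + \beta^{\mu}_{1,j} c)$ and likewise for
$\sigma_j$, with separate coefficient pairs per state for the mean and the
sd. The same covariate value — that of the step's starting fix — is used
for every transition entry at a given time; the transition *into*
observation $t$ uses the covariate at $t - 1$, and the simulator uses the
identical convention so generative and inferential models agree.

$\delta$ is estimated as free simplex parameters, shared across tracks
when the state process is pooled and per-track otherwise.

## Fitting

`fit_hmm()` maximises the summed forward log-likelihood over an
unconstrained working vector: $\log \mu_j$, $\log \sigma_j$,
$\log \kappa_j$; a multinomial logit for $\delta$; free $\beta$
coefficients; $\rho_j$ unconstrained and wrapped to $(-\pi, \pi]$ on use.
Optimisation is BFGS with relative tolerance $10^{-8}$ and up to 500
iterations. Starting values are data-driven: steps are split at their
median to initialise $(\mu_j, \sigma_j)$, the angle concentration comes
from the inverse mean-resultant-length approximation, and off-diagonal
transition probabilities start at 0.1. Additional restarts perturb the
working vector with seed-controlled Gaussian noise (sd 0.4); the default
is 25 restarts, though in the well-separated regimes used throughout the
test suite the quantile-split start converges reliably and one to three
restarts suffice — the examples and tests use small restart counts for
that reason, as a deliberate problem-size choice. Invalid working points
reached during line search (e.g. an underflowed $\mu$) return a large
penalty instead of an error. Standard errors come from the numerical
Hessian at the optimum.

The distance-to-colony covariate is centred and scaled by its pooled
mean/sd before entering any linear predictor — purely for optimiser
conditioning — and the standardisation constants are stored on the fitted
object. They can also be supplied explicitly (`cov_centre`, `cov_scale`),
which matters when the generating slope is defined on a known
standardised scale and must be recovered on that same scale.

Per-track variants (models 1–3) refuse to fit a single track, since a
per-track parameter set on one track is the pooled model with extra
bookkeeping.

## Decoding and validation

`viterbi_decode()` returns the jointly most probable state sequence (log
space; exact ties break toward the lower state index). "Local" state
probabilities are smoothed forward–backward posteriors
$P(S_t = j \mid x_{1:T})$ by default; whether locally decoded
probabilities should condition on the whole track or only the past is a
genuine choice, so `local_probabilities(type = "filtered")` exposes the
alternative.

Validation compares decoded labels with the observer's, pooled over the
time points of all tracks in a colony × species × period group (per-track
metrics are also emitted for diagnostics; whether published per-group
metrics pool points or average per-track values is not derivable, and
pooling is the default). The positive class is foraging:

* PPV $= tp/(tp+fp)$, TPR $= tp/(tp+fn)$, NPV $= tn/(tn+fn)$;
  zero-denominator metrics are reported as missing, never as zero.
* F1 $= 2\,\mathrm{PPV}\cdot\mathrm{TPR}/(\mathrm{PPV}+\mathrm{TPR})$,
  defined as 0 when both inputs are 0 — appropriate because the foraging
  class is both rarer and more consequential than not-foraging.
* Log-loss is the mean negative log-likelihood of the observed labels
  under the smoothed foraging probabilities, clipped to
  $[10^{-12}, 1-10^{-12}]$.

Model selection among fitted variants uses the *lowest log-loss*, not
AIC; AIC is computed and reported because the divergence between the two
is itself informative (AIC tends to reward complexity that does not
change the decoded states). Ties break toward fewer parameters.

A *foraging event* is a maximal run of observed-foraging labels.
`event_coverage()` computes, per event, the proportion of its points
decoded as foraging, binned as: missed (exactly 0), (0, 25%), [25, 50%),
[50, 75%), [75, 100%] — an exact 25/50/75% boundary falls in the upper
bin, since the lowest bin is "less than 25%, 0% exclusive". Completely
missed events are counted and their durations summarised by the median,
in seconds.

## Track geometry conventions

* Sphere of radius 6371 km throughout; no projection. Tracks span tens of
  km, where the spherical error is far below GPS noise.
* Haversine distances; initial bearings clockwise from north in
  $[0, 2\pi)$; turning angles **counter-clockwise positive**, wrapped to
  $(-\pi, \pi]$ (compass-heading differences are negated).
* The first turning angle of a track is undefined and excluded from the
  angle likelihood only; its step still contributes.
* Exact-zero steps are replaced by $10^{-6}$ km (gamma support is open at
  0) and counted on the series' attributes; a stationary fix keeps the
  previous heading.
* The behaviour label and distance-to-colony of a step are taken from the
  step's *starting* fix.
* The bird's position is reconstructed from the platform's fix plus
  recorded bearing/distance by the standard destination-point formula;
  `destination_point()`, `initial_bearing()` and `great_circle_km()` are
  mutually inverse to $<10^{-6}$ degrees at sub-km offsets (tested
  against an independent geodesy library).
* Tracks lasting no more than 60 s, and tracks whose observed behaviour
  never changes, are dropped with an audit trail.

## What the synthetic generator emulates — and what it does not

`make_dataset()` produces the full observational setting: bird tracks
from the generative two-state model (positions advanced on the sphere by
heading + turning angle; first heading uniform), a following boat, and
per-fix behaviour labels. The default regime —
$\mu = (0.005, 0.020)$ km, $\sigma = (0.003, 0.008)$ km,
$\rho = (0, 0)$, $\kappa = (1, 20)$, switching probabilities 0.05 —
gives 1 Hz speeds of 5–20 m/s (realistic tern flight), dwell times around
20 s, and clearly separated states. These are design choices for a
plausible, testable regime, not estimates from field data.

The boat is a smoothed pursuit of a standoff point 100 m from the bird on
the boat's side: its heading is a weighted circular mean of the previous
heading (weight 0.7) and the bearing to the standoff point, its speed is
capped at 40 m/s and throttled by the alignment between heading and goal
(a skipper slows in turns). This minimal controller reproduces the two
qualitative properties that matter: the boat's turning-angle distribution
is more concentrated than the bird's (platforms turn smoothly), and the
standoff distance stays in the tens-to-hundreds-of-metres band. It is not
a model of real skipper behaviour — port speed limits, evasive-flight
distance increases and the like are out of scope. The recorded
bearing/distance columns are exact, so reconstruction is exact by
construction; real sightings would add observer error the generator does
not model.

Observer labels default to noise-free (the validation data are treated as
ground truth); an independent flip-noise option exists for robustness
studies only. The generator also omits GPS positional error, wind and
current drift, prey fields, and any environmental covariate other than
distance to colony. Passing tests on synthetic data therefore demonstrate
the *correctness of the machinery* — likelihood, decoding, selection,
event analysis — under the model's own assumptions, not the field
performance of HMMs on real tracks.

## Numerical choices

* Scaled forward/backward recursions (per-time normalisation with a
  row-max shift of the log densities); posteriors renormalised row-wise.
* Enumeration oracles in the test suite verify likelihood, Viterbi and
  posteriors against brute-force sums over all $2^T$ sequences at
  $T \le 8$ to $10^{-10}$.
* Viterbi ties to the lower state index; log-loss clipping $10^{-12}$.
* The von Mises sampler is the Best–Fisher (1979) rejection algorithm;
  infinite concentration returns the mean direction exactly.
* Problem sizes: the parameter-recovery and model-insensitivity checks
  use 10 tracks × 2000 steps (five replicate datasets); oracle checks use
  200 random instances; the geometry round-trip uses 10,000 point pairs.

## Known limitations

* Two states only in the model suite (the engine is written for general
  $N$, but labelling and the variant grid assume 2); no state-count
  selection.
* No observation-error (state-space) layer: positions are taken as exact.
* Per-track variants estimate fixed per-track effects, not random
  effects.
* Metrics assume the observed labels are themselves correct; label noise
  propagates directly into apparent error.
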