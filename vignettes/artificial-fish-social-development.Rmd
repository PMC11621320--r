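---
title: "Modeling the development of social behavior in artificial fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the development of social behavior in artificial fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curiofish)
```

## The scientific problem

Zebrafish develop collective behavior gradually: larvae begin turning toward
conspecifics around a week post-fertilization and intensify their social
interactions over the following weeks. A remarkably compact description of
this development is a single-parameter attraction rule: a fraction $p_s$ of
the time a fish interacts by turning toward one randomly chosen neighbor,
and the rest of the time it turns at random. With $N_1$ neighbors on one
side of the focal fish and $N_2$ on the other, the probability of choosing
the $N_1$ side is

$$P(N_1 \mid N_1{:}N_2) \;=\; p_s\,\frac{N_1}{N_1+N_2} + (1-p_s)\,\frac{1}{2},$$

with the complementary probability for the other side. Development is then
summarized by the growth of $p_s$: in biological fish it rises from about
0.01 at 6 dpf to 0.47 at 24 dpf and 0.54 in adults.

`curiofish` implements this rule as a generative simulator, and implements
the complementary "mechanistic" account: embodied agents ("artificial
fish") with no hard-coded interaction rules that learn social behavior from
raw egocentric vision through deep reinforcement learning driven purely by
intrinsic (curiosity) rewards. The package also implements the full
behavioral analysis suite that connects the two levels: distance
development, focal-frame maps, configuration-dependent turning
probabilities, attraction-parameter fitting, randomization significance
tests, and the social-preference assays.

## The rule model and its identities

Two consequences of the attraction rule are used as analytic anchors
throughout the test suite:

* **Normalization.** $P(N_1 \mid N_1{:}N_2) + P(N_2 \mid N_1{:}N_2) = 1$
  identically.
* **A parameter-free relation for four fish.** In groups of four, a focal
  fish sees either a 0:3 or a 1:2 configuration, and the rule implies
  $P(1 \mid 1{:}2) = \tfrac13 + \tfrac13 P(0 \mid 0{:}3)$ independent of
  $p_s$.

The developmental fit inverts the rule at three probe configurations. From
$P(2\mid2{:}1) = \tfrac12 + p_s/6$ and $P(0\mid0{:}3) = P(0\mid0{:}1) =
(1-p_s)/2$, each measured probability yields one estimate; estimates are
clipped to $[0,1]$ and averaged:

```{r}
fit_ps(0.59, 0.23, 0.23)
```

A least-squares fit over the same three probabilities is available as
`fit_ps_lsq()`; on exact inputs both routes agree, and the closed form is
the default because averaging per-probability inversions is exactly the
published procedure.

### Kinematic conventions of the rule simulator

The rule model fixes only decision-level probabilities. Trajectory-level
defaults in `rule_params()` are package conventions, chosen once at values
typical for larval zebrafish in tank units where one body length is 2
units: speed 0.1 units/step, a turn decision every 5 steps, 30 degrees per
turn, reflective walls. Neighbors within 1 degree of dead ahead or dead
behind have no well-defined side and are assigned one at random. The
independent-walker null (`simulate_independent_walkers()`) is the identical
motion model with interaction disabled.

## The embodied model

### World

The tank is a flat plane (the reference experiments restrict fish to a thin
water layer, so planarity loses nothing essential). Bodies are stadium
colliders of length 2 and radius 0.5; collisions cut back the offending
displacement until colliders separate, and never alter headings. Arenas are
a 40x40 square rearing tank, a circular test arena of radius 16, and small
circular "cups" for the preference-rearing experiment.

### Vision

Observations are panoramic ray retinas: equal-angle rays across a 160
degree field of view, each carrying the RGB color of the nearest object
(fish body, or wall) with mild depth attenuation. We use the 1-D retina
rather than a 2-D camera image because in a planar world the vertical image
dimension carries no information; equal-angle casting also makes the
renderer *exactly* mirror-equivariant, which the analysis suite exploits to
validate left/right statistics. Texture-mapped walls provide the
"naturalistic" visual variant. The probe protocol (`place_configuration_probe()`)
renders scenes with $N_1$ neighbors placed uniformly in the left half-field
and $N_2$ in the right, all within the field of view and a 12-unit view
distance so every placed fish is visible.

### Actions

Each step combines one locomotion sub-action (fast/slow in the collective
behavior experiment; forward/stay in the naturalistic and preference
experiments) with one rotation sub-action (left/none/right, 2 degrees per
step, left = counterclockwise). Speeds are 0.14 and 0.07 units/step —
conventions chosen so a fish crosses the rearing tank in a few hundred
steps.

### Learning

Policies map the retina through two 1-D convolution stages (leaky
rectifier), two 128-unit dense stages, then one categorical head per
sub-action plus a value head. All networks in the package (policy and the
four curiosity algorithms) are built from a small in-package neural-network
toolkit — dense and 1-D convolution layers with manual backpropagation and
Adam — whose gradients are verified against finite differences in the test
suite.

Policies are optimized with PPO: discount 0.99, learning rate 0.001 with
linear decay to zero, updates every 5 episodes, minibatch 500. Clip ratio
0.2, GAE $\lambda$ 0.95 and entropy bonus 0.01 are package conventions, all
exposed in `ppo_config()`.

Four intrinsic-motivation algorithms supply the only rewards:

* **ICM** — forward-model prediction error in a learned feature space; the
  encoder is trained by the inverse dynamics loss only (forward loss weight
  0.2, inverse 0.8, exposed as `beta`), with one cross-entropy head per
  sub-action factor.
* **ICM with random features** — the same forward-model error in the space
  of a frozen randomly initialized encoder.
* **RND** — squared error of a predictor imitating a frozen random target
  network.
* **CRL** — temporal contrastive learning; reward is $1 - \cos$ similarity
  of consecutive projected representations, bounded in $[0,2]$. Negative
  pairs are drawn at least 5 steps apart; the hinge margin on negative
  similarity is 0.5.

Raw squared-error rewards differ in scale by orders of magnitude across
algorithms, so rewards are standardized by the running standard deviation
of the discounted return they induce before PPO sees them (toggleable;
default on). This keeps value-regression targets of order one — without
it, value gradients through the shared encoder drown the policy gradient
at small batch sizes. The ablation experiment multiplies rewards by 0.001
*after* this standardization, preserving the published ratio of 1 to 0.001.

### Critical period

After training, weights are frozen abruptly (`freeze_policy()`); frozen
policies error on any update attempt. Twenty equally spaced checkpoints
("artificial days", ages 1-20) are saved during every training run and
restore behavior bit-exactly.

## Desk-scale study design

The package ships two preset scales (`preset()`). `full-*` presets carry
the original protocol sizes (20 fish, 2000 episodes of 1000 steps, 600
probe images, 10 pairs x 2 x 5000-step test trials, 200 randomized controls
with 10,000 resamples). `desk-*` presets preserve every protocol *ratio*
while shrinking sizes so a full experiment runs in minutes on one CPU:

* **desk-exp1**: 4 fish with one brain each, 300 episodes of 75 steps, a
  32-ray retina, and an 18x18 rearing tank. The tank is shrunk with the
  population so that fish *density* matches the reference conditions (20
  fish per 1600 square units is 1 fish per 80; 4 fish per 324 is close).
  Six PPO epochs per update (instead of 3) compensate for the small
  per-brain batches of the desk regime, and the episode count is sized to
  fill a ~20-minute single-CPU budget for the full four-algorithm,
  three-seed study. Pair testing uses 2 pairs x 2 trials x 600 steps in
  the radius-16 test arena; probe tables use 200 images; randomized
  controls use 20 seeds per trial.
* **desk-exp3**: 2 fish per pigment group reared in radius-8 cups, tested
  with 30 2AFC trials of 200 steps against shoals of 11 in a 24x24
  chamber.

Test trials read out the *modal* (arg-max) action of the frozen policy
rather than sampling. The learned left/right preferences at desk scale are
real but weakly expressed in the action probabilities; the modal readout
reports what the policy has learned rather than the residual sampling
noise, and sampling readout remains available (`deterministic = FALSE`).

## Numerical and statistical conventions

* **Turn detection** on continuous trajectories uses a heading-change
  threshold of 0.5 degrees per step (config-exposed); at the probe level
  "no rotation" responses are excluded from turning denominators (a
  half-weight alternative is exposed).
* **Focal frame**: origin at the focal fish, $+y$ along its velocity
  (forward displacement); zero-velocity frames are undefined and those
  rows are dropped. Map cells with fewer than 20 observations are masked,
  not zero-filled.
* **Randomization test**: controls pair each fish's true trajectory with
  its partner's positions at random timesteps of a *different* episode
  (both directions, 20 seeds per trial); the p-value is the fraction of
  10,000 resampled 10-pair control means at or below the experimental
  mean. Ties count as below, so the test is conservative.
* **Preference tests**: one-sample t versus 0.5 for 2AFC scores, paired
  two-tailed t for in- versus out-group distances, uncorrected. Zero
  variance is reported as the limit case (p of 0 or 1).
* **SEM conventions**: over trials for distance curves, over fish for
  preference bars, over the three inversions for $p_s$.

## What the synthetic generator does and does not emulate

The rule-based simulator generates the statistical structure the analyses
assume — planar constant-speed trajectories whose turn decisions follow the
attraction rule, plus an exchangeable independent-walker null — and is the
package's stand-in for biological trajectory data. It does not emulate
bout-structured swimming, speed modulation, body undulation, or
wall-following tendencies of real larvae. Passing recovery tests on this
generator therefore validates the *estimators* (that the fitting procedure
recovers the true parameter from finite data), not the biological accuracy
of the kinematics.

Likewise, the desk-scale reinforcement-learning runs demonstrate that the
full causal chain — curiosity rewards computed from raw pixels, PPO,
frozen readout, probe analysis — runs end to end and moves the measured
statistics in the direction seen in the reference experiments. Effect
sizes at desk scale are smaller and noisier than at full protocol scale;
the full presets exist for faithful-scale runs.

## Known limitations

* One eye: the retina faces forward, so artificial fish favor front/back
  rather than side-by-side neighbor placements.
* The 2AFC shoals are static scenery (the assay isolates the test fish's
  preference); real stimulus shoals swim.
* No homeostatic objectives besides curiosity; no 3-D motion; no
  photorealistic rendering.
* Desk-scale training uses orders of magnitude less experience than the
  full protocol; individual runs can fail to develop measurable social
  behavior, which is why stochastic claims are evaluated over seeds.
* With only two test pairs the randomization test is coarse: control
  means cluster at pair-specific levels, so resampled means form a
  handful of atoms and the p-value is effectively quantized (a single
  strongly coupled pair yields p near 0.25, not significance). The
  10-pair full protocol does not have this limitation.
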