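---
title: "Models and methods behind delayti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind delayti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transitive inference (TI) asks a subject who has only ever been rewarded
for choosing A over B, B over C, and so on, to decide novel pairs such as
B vs E. Solving it requires an inductive bias for transitivity rather
than memorization. `delayti` studies the *delay* variant of 7-item TI, in
which the two items arrive sequentially (item 1 — delay — item 2) and the
choice is expressed by presentation order, so the task additionally
demands working memory. The package generates the task, trains recurrent
and feedforward network models on it, simulates their behavior at
titrated noise, and quantifies the population-level dynamics and geometry
that different model families use to solve the task.

## Task and trial structure

Items A..G are ranked 1..7 (A highest). The 42 ordered pairs split into
12 adjacent-pair training types and 30 test types. Each item is embedded
as a 100-dimensional standard-normal vector, so inputs carry no
rank-informative features. A delay trial is rest (0.5 tau), a one-step
item-1 pulse, a delay (2 tau basic; 6 tau extended; uniform 2-6 tau for
the variable variant, with total duration fixed), a one-step item-2
pulse, and a choice period (2 or 6 tau). With dt = tau/10 the basic trial
has 5 + 1 + 20 + 1 + 20 = 47 steps. Whether the pulse steps count inside
the surrounding periods is not fixed by the source material; we place
each pulse on the single step between periods and index the delay as the
steps strictly between pulses, so that response times are measured from
the item-2 pulse.

Targets are piecewise constant with resting value 0 and activated value
5. The third ("rest") output unit is held at the activated value from
trial start through the item-2 pulse and at 0 afterwards; this is our
reading of the three-way output (choice 1 / choice 2 / rest), which the
source text does not spell out numerically for the rest unit.

## Network models

The RNN is the standard continuous-time rate network

tau dx/dt = -x + J r + B u + b + noise,  r = tanh(x),  z = W r + c,

integrated by forward Euler at dt = tau/10. Per-unit Gaussian noise of
s.d. 0.2 is drawn at every step and enters the right-hand side of the
equation, i.e. it is multiplied by dt/tau in the update. The alternative
reading — noise added to the state unscaled each step — was tried and
rejected: under it the effective perturbation is ten times larger and
recurrent-only (r-RNN) networks in the highest constraint regime plateau
far below the response threshold at any feasible training budget, which
contradicts the generalization counts the model family is known to
achieve. The literal discretization trains every variant.

Initialization: J ~ N(0, g0^2/N), B ~ N(0, h0^2/N_in); W, biases and the
initial state x0 start at zero. Five constraint regimes set
(h0, g0, alpha, beta): highest (1, 0.5, 1, 1), high (1, 0.5, 0.01, 0.01),
intermediate (1, 1, 0.01, 0.01), low (1, 2, 0, 0), lowest (1.5, 4, 0, 0).
Variants differ in what trains: f-RNN (everything), r-RNN (only J; frozen
B and W keep their random initial values — a frozen readout drawn at zero
could never produce output, so frozen W is drawn N(0, h0^2/N)), ff-RNN
(only B and W), and r-RNN with trainable W. Biases and x0 train in all
variants.

The feedforward baselines receive both items simultaneously
(concatenated, 200-dimensional input): a logistic regression (two linear
readouts) and a single-hidden-layer tanh MLP (N = 100).

## Training

The RNN objective is E = E_task + alpha R_L2 + beta R_FR, with E_task the
squared output error averaged over trials, time and output units, R_FR
the mean squared rate times dt, and R_L2 the *per-element mean* of the
squared input and output weights. The printed source formula is a raw sum
over all 10^4 entries of B; at alpha = 1 that term is ~100 at
initialization and caps trained outputs at roughly half their targets, so
highest-regime networks could never meet the response criterion —
contradicting the source's own report that all 200 highest-regime
instances generalize. The mean normalization matches the conventions of
the regularized-RNN literature the source builds on and restores
trainability in every regime.

Training uses Adam (learning rate 1e-3 by default; the source does not
state optimizer hyperparameters) with backpropagation through time on
batches of 128 trials sampled uniformly from the 12 training types, with
intrinsic noise on. Stopping: noise-free correct responses on all 42
types (checked on an exact evaluation each epoch interval), batch E_task
below 0.1, or an epoch cap (30,000 by default). Variable-delay training
additionally requires correctness with the item-2 pulse advanced by 67%
of the longest delay. The LR baseline trains with cross-entropy plus
weight decay (0.1) until its loss stops improving for 1000 epochs; the
MLP (weight decay 0.001) until noise-free correct on all types.

## Behavior

Readouts pass through the saturating function
ztilde = tanh(z - zhat/2)/2 + 1/2, where zhat = 5 is the activated target
value; the response is the first choice readout to reach 0.85 during the
choice period, and RT is the crossing time from the item-2 pulse as a
fraction of the choice period. The printed formula is typographically
ambiguous between tanh((z - zhat)/2) and tanh(z - zhat/2); under the
first reading the threshold sits at z ~ 6.7, unreachable by an output
trained toward 5, so no trained network could ever respond. We use the
second reading (midpoint at half the activated value; crossing at
z ~ 3.37). Discrete-grid ties are broken by the larger saturated value,
then unit index.

Behavioral simulation titrates intrinsic noise over 0.5-5 in steps of
0.05 (RNN; powers of 2 from 1 to 128 for LR/MLP) until performance is
above 50% on both the choice-1 and choice-2 training pools and below 96%
on the two extreme pairs, then simulates all types at that level.
Non-responding trials receive a random choice and are excluded from RT
statistics. The summaries are the classical indices: symbolic-distance
and end-item curves in both performance and RT, and the end-order index
(RT_1st - RT_2nd)/(RT_1st + RT_2nd) over end-item trials excluding the
two extreme pairs; negative values mean end-item-first trials are faster.

## Synthetic subjects

The generator emulates the human study's structure — 3 training blocks of
48 trials (each training type four times, shuffled) and 6 testing blocks
of 42 (each type once) — with an additive-Gaussian RT model (baseline
0.55 s, distance slope 0.02 s, end-item bonus 0.03 s, end-order offset
-0.04 s applied to end-item-first trials, noise s.d. 0.1 s, truncated to
a 1 s response window) and a lapse-mixed logistic accuracy model in
distance with an end-item bonus. Defaults were chosen once to produce
human-plausible block performance (~60-75%) and clearly planted effects;
they are exercised by parameter-recovery tests, not fitted to data. The
generator deliberately omits psychophysically realistic RT distributions,
learning across blocks, and stimulus features: a green test establishes
that the *analysis pipeline* recovers planted structure, not that humans
behave this way. Non-response is an independent 2% Bernoulli per trial.
The sign convention of the planted end-order offset is chosen so that a
negative offset yields a negative (1st-faster) cohort index.

## Dynamics and geometry analyses

All delay-period analyses use the 7 item-1 conditions of noise-free
simulations, in the top 10 PCs of delay-period activity (PCA over all
delay timesteps and conditions).

*Linear dynamics.* Least-squares fit of Xdot = X A with forward
differences over dt; eigenvalues are reported with imaginary parts in
cycles/delay (one delay = the trained delay duration). R^2 is uncentered
(residuals against total squared derivative): the centered definition
penalizes the common drift that a through-origin linear model is not
meant to capture and goes negative even for fits whose spectra cleanly
expose the oscillation. The comparison oscillation is the complex mode
nearest 0 + 0.5i on this plane; its 2D plane is the real and imaginary
eigenvector parts, Gram-Schmidt orthonormalized in that order.

*Fixed points.* Adam minimization of the mean-squared speed of the
autonomous dynamics, seeded from listed trial states and five batches of
50 random jittered-trial states (50,000 iterations, early stop after
5,000 without improvement), accepting speed below 1e-5, optionally
polished by guarded Newton steps (a pure numerical refinement of the same
points). Deduplication implements the verbatim "every unit differs by
more than 1e-5" rule, which merges fixed points that agree in any single
unit; because that collapses legitimate distinct points in low
dimensions, an any-unit rule is selectable and used where true counts
matter. Linearization uses the analytic Jacobian
(-I + J diag(1 - tanh(x*)^2))/tau, spot-checked against central finite
differences; classification is attractor / saddle-1 / other by the signs
of eigenvalue real parts.

*Geometry.* Collinearity (mean |cos| over unordered outer-item pairs of
XCM-referenced states; the printed 1/(S choose 2) prefactor conflicts
with the double sum over the six outer items, and only the
average-over-pairs reading keeps the index in [0,1] and reproduces the
~0.28 random reference), ordered collinearity (negative mean cosine over
high-by-low pairs), mean angle change and mean distance change (the
printed bracket for the latter is vector-valued as written; we use the
difference of pairwise norms). Early/late are the first/last delay
timesteps (window-averaged variants available). Note the ordered index is
invariant under global negation, so both orientations of a rank-ordered
line score +1; -1 corresponds to a folded arrangement. Random baselines
substitute i.i.d. Gaussian vectors for every state. Axis angles
(choice/XCM/readout axes vs the oscillation plane and each other) are
|dot| magnitudes in the top-10 (or top-2) PC space with 1000-draw random
unit-vector references. The encoding index is
log2(|projection at delay end| / |projection at delay start|) averaged
over the end items; the log form makes the 1st- vs 2nd-dominant boundary
exactly 0 (the source prints only the sign semantics of its "ratio").
Readout-axis projections use the rates (z1 = W1 r + c1), matching the
definition of the readout itself.

*Reduced oscillation.* A linear toy evolving only the oscillatory mode:
encodings are injected as pulses, plane components rotate at f
cycles/delay, the orthogonal complement persists. At f = 0.5 with ordered
collinear encodings the delay rotation negates the item-1 encoding and
the post-item-2 state is literally encoding(item2) - encoding(item1):
subtraction at the population level, linearly separable by construction.
Separability is certified: candidate hyperplanes (minimum-norm label
interpolation, then a perceptron pass) are verified point-by-point, and
failing that, a Frank-Wolfe estimate of the convex-hull distance
certifies inseparability. In this linearized toy, full-space and
plane-projected separability coincide up to the in-plane geometry of the
encodings; the advantage of full *network* activity over its
plane-projection is a property of nonlinear trajectories and is assessed
on trained networks in the acceptance suite instead.

## Scale choices and what green tests establish

The source trains 200 instances per variant-regime cell; the test suite
trains 3 (and compares cohort means within twice the printed
between-instance s.d.), titrates with 100 simulations per trial type
rather than 500, and evaluates two variants x two regimes rather than
all ten cells. These are runtime scale-downs, stated in the tests
themselves; they widen Monte-Carlo error but change no definitions.
Training, not analysis, dominates runtime (~1-10 minutes per instance on
one CPU). A green acceptance suite therefore establishes that the
implementation reproduces the qualitative and (at reduced precision)
quantitative cohort signatures, not the full-scale distributions.

## Known limitations

Desk-scale recurrent-only (r-RNN) cohorts reproduce the qualitative
geometry — early-delay collinearity at the random-vector level, a
positive change across the delay, an oscillation near 0.5 cycles/delay —
but their late-delay collinearity plateaus around 0.4-0.6 rather than
~0.73. The frozen-readout variance is not pinned down by the source
material, and our choice (row norm 1) sits near the edge of
trainability; smaller frozen readouts fail to train and sqrt(dt)-scaled
noise does not close the gap. The corresponding acceptance check is left
failing rather than widened.

Only the tanh nonlinearity is implemented. The human raw dataset is not
consumed; subject-level analyses are validated on synthetic cohorts with
planted effects. Checkpoint files use R serialization rather than HDF5.
The Adam hyperparameters beyond the learning rate, the gradient-clipping
policy (none), and the evaluation interval are package defaults, not
claims about the source.
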