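---
title: "Models and methods behind electrofish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind electrofish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrofish)
```

`electrofish` simulates collectives of weakly-electric-fish-like agents
that forage, discharge, and sense in a 2D arena, trains them with
multi-agent PPO on individual fitness, and quantifies the emergent
electro-communication. This vignette records the modelling assumptions,
the parameters that matter, the numerical choices, and what the package's
tests do and do not establish.

## The arena

The world advances in discrete steps of `dt_s = 0.04` s (25 Hz). This
timestep was chosen so that a 0.36-s behavioural window is exactly 9 steps
and so that an EOD — modelled as a binary event with no intra-pulse
waveform — occupies one step. The default arena is 200 × 200 cm with
continuous coordinates, origin at the bottom-left, headings in CCW radians.
Kinematics are first-order: heading changes by `turn * omega_max * dt`
(`omega_max = pi` rad/s), position by `thrust * v_max * dt` along the new
heading (`v_max = 20` cm/s, roughly two body lengths per second for a
~10 cm mormyrid). Walls clamp positions componentwise, which for a convex
rectangle is identical to sub-step collision integration with sliding — a
property the test suite checks against a 1000-substep oracle.

Food is patchy: `n_patches` discs of radius `patch_radius_cm`, each
initialized at `patch_capacity` items. Two regimes reproduce the study
conditions:

* **competitive** (zero-sum): a patch below capacity gains one item with
  probability `min(1, replenish_rate_per_s * dt)` per step;
* **non-competitive**: capacity acts as an unbounded target — patches are
  refilled instantly, so food is effectively unlimited.

Eating is automatic within `eat_radius_cm = 2` (the action set has no eat
verb). Biting is an explicit action: a bite lands on the nearest
conspecific within `bite_radius_cm = 4` in the frontal half-plane, and the
two parties lose `c_bite * sigma(k (d_opponent − d_self))` with `sigma` the
logistic and `k = 6`, so the encounter costs the more dominant fish less and
splits evenly (`c_bite / 2` each) at equal dominance. Dominance itself is a
fixed scalar in [0, 1] per agent, resampled at episode reset (or set
explicitly in the assay); it is not directly observable to conspecifics,
only through behaviour.

The per-step reward is exactly three terms — `r_food = +1` per item,
`-c_eod = -0.01` per discharge, and the bite deltas. The EOD cost is the
one economically necessary invention: without a per-pulse cost there is no
incentive ever to discharge less, and rate-reduction phenomena such as
freeloading could not emerge. Its magnitude (1% of a food item) keeps
discharging cheap relative to eating, as in the real energetics.
No term references proximity, coordination, or signalling.

## The electric landscape

Each discharge creates an ideal point dipole at the agent's centre with
moment `eod_amplitude * (cos h, sin h)` along the body axis. Fields follow
the 3D dipole law evaluated in the plane,

$$E(\mathbf r) = \kappa\,\frac{3(\hat r\cdot\mathbf p)\hat r-\mathbf p}{\max(|\mathbf r|, r_{\min})^3},$$

with `kappa = 1` (fields are in arbitrary units — only ratios reach the
policy) and a softening radius `r_min = 1` cm that caps the singularity.
The 1/r³ law rather than a true 2D (1/r²) solution follows electric-fish
modelling convention; the geometry is a shallow-tank cross-section, not a
genuinely 2D world.

Objects respond at first order only: a food item or conspecific body
acquires `p_ind = alpha E_emitters` (`alpha_food = 10`,
`alpha_body = 20`), with no object–object re-induction and no images of
images. At these polarizabilities the neglected second-order terms are
orders of magnitude below the first-order signal, and the per-step cost
stays O(sources × objects). Walls are insulating (tank walls and the water
surface conduct poorly): each source gets four mirror images with the
tangential moment preserved and the normal component negated, which cancels
the wall-normal field exactly — the boundary-condition test verifies this
to 10⁻⁶ relative.

## Sensing

Observations are egocentric and fixed-length: with the default 8 receptors
and 8 Knollenorgan bins, `obs_dim` = 8 + 8 + 8 + 3 = 27.

* **Active** (8 receptors on a 6 × 2 cm body ellipse): the perturbation
  `|E_total| − |E_direct|` of the illuminating discharges. Illuminators are
  the agent's own EOD and — iff `collective_sensing_enabled` — conspecific
  EODs this step. Collective sensing is thus extra illumination of the same
  channels, not a separate block: downstream circuitry need not know whose
  pulse lit the scene. The round trip (emitter → object → receptor) decays
  like ~1/r⁶, making this the short-range channel.
* **Passive** (same receptors): field magnitude of weak static dipoles
  carried by food items (`passive_amplitude = 6`, orientation drawn at
  spawn), standing in for prey bioelectric fields; effective range ≈ 5 cm.
* **Knollenorgan** (8 angular bins relative to heading): conspecific
  pulses within `comm_radius_cm = 50` deposit `A₀ / max(d, r_min)²` in the
  bin containing the sender. The deliberately slower 1/r² falloff and the
  hard communication-radius cutoff make this the long-range social channel.
  Own pulses are excluded.
* **Proprioception**: speed, last turn command, own EOD flag.

All blocks pass through `y = sign(x) log(1 + |x|/s)` with `s = 1`, because
field magnitudes span several decades and a tanh network saturates on raw
values. Gaussian sensor noise is available (`sensor_noise_sd`) and off by
default.

A note on egocentricity: the three sensing blocks are exactly invariant
under a global rotation of world plus agent — except through the wall
images, which are anchored to the arena. The invariance tests therefore
check arbitrary rotation angles with reflections disabled (to 10⁻⁸) and
quarter-turn rotations of the square arena with reflections on (an exact
symmetry of the geometry).

## Policy and learning

All agents share one parameter set ("individual instantiations of a common
network"): a plain tanh recurrent core, then parallel actor and critic
two-layer MLP heads (hidden tanh layer + linear output). Full-scale runs
use 512 units throughout; the packaged sanity tasks use 16–64. The
recurrent cell is tanh-only in this implementation — a gated cell is a
known possible extension, not currently provided.

Thrust and turn use Beta distributions on their bounded supports
(`alpha = 1 + softplus(u)` keeps them unimodal), avoiding the squashing
corrections a Gaussian would need; EOD and bite are Bernoulli logits. With
all-zero parameters the discharge probability is exactly 0.5 and the value
exactly 0, which the tests use as an architectural fingerprint.
Initialization is orthogonal for the recurrent matrix, Glorot-uniform
elsewhere, with output layers scaled by 0.01 so the initial policy is
near-uniform.

Training is PPO with the standard machinery: GAE (`gamma = 0.99`,
`lambda = 0.95`), clipped surrogate (`eps = 0.2`), entropy bonus 0.01,
value coefficient 0.5, Adam at 3e-4, gradient-norm clip 0.5, 8 parallel
environments, rollouts of 256 steps split into recurrent segments of 32
with segment-initial hidden states stored during collection and replayed
exactly (burn-in 0 — exactness over sophistication). Hidden states are
zeroed at episode boundaries in both collection and replay. The critic is
decentralized by default; `centralized_critic = TRUE` feeds the
concatenated observations of all agents in the environment into the critic
hidden layer (MAPPO-style global state) while the actor stays
decentralized. Because no autodiff framework is involved, every gradient is
derived analytically; the test suite compares them to central finite
differences at 10⁻⁴ relative on a small policy, and checks the two exact
structural properties (on-policy ratios = 1 before the first update;
clipped samples contribute exactly zero policy gradient).

Determinism: all randomness flows through named streams derived from one
root seed by hashing the stream name (adding a new consumer never perturbs
existing draws), so single-threaded runs are bit-reproducible — traces,
training logs, and parameters.

## The synthetic-trace generator

Analytics are developed and validated against traces with *planted*
structure, generated by `generate_synthetic_trace()` in the exact schema
the simulator emits: scripted or stochastic EOD trains (Bernoulli, renewal
with an arbitrary interval sampler quantized to steps, or literal bit
strings), scripted trajectories (stationary, straight, waypoint paths),
interaction windows that pin a pair at a chosen distance for a chosen span,
and planted consumption tallies. Default placements sit on a ≥ 40 cm grid
so no unplanned interactions occur. One numerical guard matters: renewal
event times are mapped to steps with `ceiling(t/dt − 1e-9)` so events on
exact step boundaries do not drift one step late through float noise.

What the generator does *not* emulate: field physics, sensing, rewards, or
any policy — its traces contain behaviour by construction, not by
mechanism. Tests built on it therefore establish that the analytics
recover known structure, not that trained agents produce that structure;
the latter requires actual training runs (the packaged scaled-down run
shows foraging competence, while full-scale condition contrasts need
multi-hour training outside the test suite).

## Analytics: definitions and numerical choices

* **SPI** (sequential pulse interval): diffs of discharge step indices ×
  `dt`. The tail fit works on the empirical log-survival function (bin-free,
  unlike a log-density): a least-squares line over intervals below the 0.9
  quantile, and `excess_mass` = mean positive deviation of the empirical
  log-survival above that line beyond the cut. For an exponential train the
  slope estimates −rate (recovered within 5% at 10⁴ intervals) and excess
  mass ≈ 0; a two-exponential mixture yields large positive excess. A
  degenerate train (constant intervals leaves < 2 usable survival points)
  falls back to the exponential slope −1/mean rather than erroring.
* **EOD probability**: discharge fraction per agent and episode; pooled
  comparisons bootstrap over episodes (1000 seeded resamples) — the episode,
  not the agent-step, is the exchangeable unit.
* **Displacement windows**: non-overlapping 9-step (0.36 s) windows,
  distance between first and last position.
* **Theil index**: `mean((x/mu) log(x/mu))` with `0 log 0 := 0`; 0 at
  equality, `log N` when one agent eats everything; undefined (an error) on
  all-zero input.
* **Social EOD motifs**: within maximal windows where a pair stays ≤ 15 cm
  for ≥ 4 steps, a 4-step window slides one step at a time; each position
  yields the pair's two 4-bit EOD strings, canonicalized lexicographically
  (the paper-level definition fixes the 15 cm / 4 step thresholds; motif
  length 4 and the ordering convention are this package's choices). Counts
  are ranked with lexicographic tie-breaks for determinism and verified
  against an exhaustive enumerator.
* **Freeloading score**: per interaction window,
  `|rate_A − rate_B| / (rate_A + rate_B)` (0 if both silent): 0 for equal
  rates, 1 for one-sided silence, 0.5 for a planted 3:1 asymmetry. The
  collective-sensing interval shift is tested with a Wilcoxon rank-sum on
  pooled SPI samples.
* **Two-fish assay**: resident A inside a single fully-replenishing patch
  at the arena centre, follower B within the communication radius.
  Conditions (`baseline`, `a_removed`, `ko_off`) run with *paired* seeds so
  geometry matches across conditions; "B reaches the patch" means its
  centre enters the patch disc at any step. The packaged scripted pair — a
  periodic beacon A and a memoryless pulse-taxis B (turn toward the
  strongest Knollenorgan bin on ping steps, straight otherwise) — shows the
  social channel carries usable spatial information without any training;
  the contrast is judged by an exact one-sided sign test on discordant
  pairs.

## Problem sizes in the packaged checks

The test suite and the acceptance script are sized for a single CPU:
training sanity runs use the `solo_forage` preset (one agent, 50 × 50 cm,
six instantly-refilling patches, 500-step episodes, a 16-unit policy,
2 × 10⁵ environment steps — about two minutes per seed), evaluated over 20
episodes against an untrained baseline; tail statistics use 10⁴-interval
trains plus 100 + 100 trains of 5 × 10³ for the false-positive control;
motif verification uses traces up to 4 agents × 200 steps; the assay runs
100 paired episodes of 250 steps. These sizes are the package's own
benchmark choices and scale up linearly in the obvious knobs.

## Known limitations

* 2D kinematics, rigid bodies, binary single-step pulses: no body flexion,
  no waveform structure, no 3D hydrodynamics.
* First-order scattering and first-order images only.
* Passive sensing covers prey dipoles only, not conspecific DC fields.
* Dominance is static within an episode and invisible except through
  behaviour.
* The tanh recurrence is the only cell provided; no gated variant.
* Trained-agent condition contrasts at full scale (e.g. how the social
  channel modulates discharge rates under competition) are experiments to
  run with this package, not properties its test suite certifies.
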