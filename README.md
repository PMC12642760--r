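# electrofish

Weakly electric fish (e.g. *Gnathonemus petersii*) probe their surroundings
and talk to each other with the same signal: brief electric organ
discharges (EODs). Studying how discharge strategies, social signalling,
and foraging interact requires simultaneous recordings of many freely
moving fish — which is exactly what is hardest to obtain experimentally.
`electrofish` is an in-silico substitute: a 2D foraging arena in which
recurrent artificial agents emit and sense EODs, are trained with
multi-agent PPO on individual foraging fitness only, and are then analyzed
with the behavioral statistics used for real fish collectives (pulse-interval
distributions, social motifs, consumption inequality, freeloading, a
two-fish communication assay). It is aimed at computational
neuroethologists and anyone modelling emergent communication in embodied
multi-agent systems.

## The model

**Physics.** Every EOD is a point dipole at the fish's position with moment
along the body axis. The field is the superposition

```
E(r) = κ [ 3(p·r̂)r̂ − p ] / max(|r|, r_min)³
```

over emitters, the dipoles they induce on polarizable objects
(`p_ind = α E` at food items and conspecific bodies; first Born
approximation), and first-order mirror images across the four insulating
tank walls (tangential moment preserved, normal negated, so the wall-normal
field cancels).

**Sensing.** Each agent carries four egocentric blocks, signed-log
compressed: *active* electrosensing (perturbation `|E_total| − |E_direct|`
of the illuminating EOD fields at 8 body receptors — with collective
sensing enabled, neighbors' EODs also illuminate), *passive* sensing
(static prey dipoles on food, ~5 cm range), the *Knollenorgan* social
channel (conspecific pulses binned by bearing, 1/r² falloff, hard cutoff at
the communication radius), and proprioception.

**Control and learning.** All agents share one network: a tanh recurrent
core with parallel actor and critic two-layer MLP heads (512 units wide at
full scale). Actions are thrust and turn (Beta heads) plus binary EOD and
bite (Bernoulli heads). Training is multi-agent PPO: clipped surrogate,
GAE(γ, λ), Adam, backpropagation through time over stored recurrent
segments — all implemented in R with analytic gradients that are verified
against finite differences in the test suite. The reward is individual:
`+1` per food item, `−0.01` per EOD, and dominance-asymmetric bite
penalties `−c·σ(k(d_b − d_v))`; nothing rewards proximity, coordination, or
communication.

## Worked example

```r
library(electrofish)

cfg <- make_scenario("competitive", n_agents = 4)   # 200x200 cm, 60 s
trace <- run_episode(cfg, controller = "random", seed = 1)
#> <episode_trace> 4 agents x 1500 steps (dt 0.04 s), seed 1, with observations

spi <- extract_spi(trace, agent_id = 1)
mean(spi$intervals_s)                               # mean pulse interval (s)
#> [1] 0.398

# heavy-tail diagnosis of a pulse train: log-survival slope + excess mass
s  <- rng_stream(1, "demo")
iv <- with_stream(s, { m <- runif(1e4) < 0.9
                       ifelse(m, rexp(1e4, 10), rexp(1e4, 0.5)) })
glance(fit_spi_tail(spi_series(iv)))
#>   slope intercept excess_mass cut_value_s n_intervals
#> 1 -6.70    -0.106        10.8       0.405       10000

final <- dplyr::filter(trace$states, step == max(step))
theil_index(final$food_eaten)                       # consumption (0,0,0,1)
#> [1] 1.386294                                      # = log(4), maximal inequality

# two-fish assay: does hearing a conspecific's EODs help reach its patch?
res <- two_fish_assay(n_runs = 20, seed = 7, n_steps = 250,
                      conditions = c("baseline", "ko_off"))
glance(res)
#>   condition dom_a dom_b reach_rate mean_food_b n_runs
#> 1 baseline    0.5   0.5        0.7         0.7     20
#> 2 ko_off      0.5   0.5        0.1         0       20
assay_sign_test(res, "baseline", "ko_off")$p_value
#> [1] 0.000244
```

The mixture train's fitted log-survival slope recovers the dominant
exponential rate (−6.7/s for a 0.9/0.1 mix of rates 10 and 0.5) while the
positive `excess_mass` flags the heavy tail; the assay shows the
Knollenorgan-guided follower reaching the resident's patch seven times as
often as one deprived of the social channel, under identical seeds.

Training is one call (`rnn_width = 16` and a small arena make this a
minutes-scale sanity run; use 512 and the full arena for real experiments):

```r
fit <- train(make_scenario("solo_forage"),
             policy_cfg = policy_config(obs_dim(make_scenario("solo_forage")),
                                        rnn_width = 16),
             train_cfg = train_config(total_steps = 2e5, seed = 1))
tidy(fit)        # per-iteration telemetry: mean food, EOD rate, losses
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/efish` (`rollout`, `train`, `analyze`, `assay`, `render`,
`synth`); every run writes a JSON manifest first and threads `--seed`
through all random streams.

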