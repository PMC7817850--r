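# actinf

Discrete-state active inference with two routes to action: a
**representational** pathway that infers hidden states and plans by expected
free energy, and a **deontic** pathway that maps observed cues directly to
policies, bypassing state inference and planning entirely. The package is for
computational cognitive scientists who want a small, fully tested engine for
studying how the two pathways coexist — in particular how habits are
acquired by the representational route and then taken over by the deontic
one.

## The model

The agent carries a categorical (POMDP-style) generative model
`P(s, π, o)` over hidden states `s`, policies `π` (fixed-length action
sequences) and outcomes `o`:

- `A[o, s] = P(o | s)` — likelihood matrix (columns are distributions);
- `B[[a]][s', s] = P(s' | s, a)` — one transition matrix per action;
- `D` — prior over the initial state;
- `ln C(o, τ)` — log-preferences over outcomes, a proper distribution per
  future time step;
- `E[o, π] = P(o | π)` — the optional *deontic* matrix: how likely each cue
  is given that a typical agent is executing each policy.

**Perception.** Given an observation, the posterior over states is obtained
by minimizing the variational free energy

```
F = Σ_s Q(s) [ln Q(s) − ln(P(s) P(o|s))] = KL[Q ‖ P(s|o)] − ln P(o),
```

an upper bound on surprisal that is tight exactly when `Q` equals the exact
posterior. Both a closed-form fixed point and a monotone mirror-descent
iteration are provided, and they agree.

**Planning.** Each policy is scored by its expected free energy

```
G(π, τ) = −E[ln C(o_τ)]  +  E[ln Q(s_τ|π) − ln P(s_τ|o_τ, π)]
          (instrumental)    (epistemic, ≤ 0)
```

with expectations under `Q(s_τ|π) P(o_τ|s_τ)`. The policy posterior is
`σ(−γ ΣτG)` (softmax, temperature `γ`, default 1): low-`G` policies — those
that both seek preferred outcomes and resolve uncertainty — are favored.

**Deontic action.** The deontic value of a cue is `ln P(o | π)`, read
straight off `E`. It can *supplement* planning (added to `−γG`) or
*supplant* it (softmax of the deontic vector alone; no state inference, no
EFE evaluation — verified by call-count in the tests). `E` is learned by
Dirichlet count accumulation from (cue, chosen-policy) co-occurrences.

## Worked example

The epistemic-probe scenario has two perceptually identical contexts and a
probing action whose outcome disambiguates them; preferences are uniform at
`τ = 1` and peaked at `τ = 2`.

```r
library(actinf)
scen <- make_epistemic_probe_scenario()
rep <- efe_table(scen$model, scen$model$D)
print(rep)
#>  policy tau instrumental  epistemic            G
#>       1   1    0.6931472 -0.6931472 4.440892e-16
#>       1   2    1.2039728 -0.6931472 5.108256e-01
#>       2   1    0.6931472  0.0000000 6.931472e-01
#>       ...
#> G_total: 0.510826 1.20397 0.510826 2.99573
policy_posterior(rep$G_total)
#> Q(pi) [representational]: 0.3871 0.1935 0.3871 0.03226
```

Policies 1 and 3 probe first: their `τ = 1` epistemic term is `−ln 2`
(one bit of information gain) while the stay-first policies gain nothing, so
the agent *first consolidates knowledge, then optimizes* — the max-posterior
policy at `t = 0` is a probing one even though probing brings no immediate
reward.

Habit acquisition in the traffic-light world (phase 1: representational
agent stops on red by preference; phase 2: the learned deontic mapping acts
alone):

```r
run_habitization_experiment(50, seed = 7)
#> phase 1 (representational): 50 episodes, cue-consistent frequency 1.000
#> phase 2 (supplant): 50 episodes, cue-consistent frequency 1.000
#> learned E[red, stop] = 0.9762 (n_red = 19)
```

After 19 red-light encounters the learned likelihood is
`(1 + 19)/(2 + 19) = 0.952` at the end of phase 1 (the printed 0.976
includes phase-2 self-reinforcement), and the deontic agent stops on red
without ever computing a belief or an expected free energy.

## Command line

```sh
AIF=$(Rscript -e 'cat(system.file("scripts", "aif.R", package = "actinf"))')
Rscript "$AIF" validate inst/extdata/traffic-light.json
Rscript "$AIF" infer inst/extdata/traffic-light.json --obs 1
Rscript "$AIF" efe inst/extdata/traffic-light.json
Rscript "$AIF" habitize --episodes 50 --seed 7
```

The JSON model-spec format is documented by
`inst/extdata/model-schema.json`.

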