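---
title: "Two routes to action: representational planning and deontic habit in discrete-state active inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two routes to action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinf)
```

## The model and its assumptions

`actinf` implements a single-factor, single-modality categorical generative
model of the kind used throughout discrete-state active inference. The
agent's world has `n_states` hidden states emitting `n_outcomes` observable
outcomes through a likelihood matrix `A`; `n_actions` discrete actions move
the state through per-action transition matrices `B`; a prior `D` fixes the
initial state; log-preferences `lnC` say which outcomes the agent wants to
encounter at each future time step; and policies are explicitly enumerated
fixed-length action sequences over a planning horizon `T`. Columns of every
parameter matrix are categorical distributions, so belief propagation is a
matrix–vector product.

Assumptions worth making explicit:

* **Single level, single factor.** No hierarchical (temporally deep) models,
  no factorized states, no multi-modality outcomes. These are real features
  of richer agents but orthogonal to what this package studies: the
  coexistence of two action-selection pathways.
* **Enumerable policies.** The policy is a random variable with a categorical
  posterior, so the policy set must be finite and explicit. Full enumeration
  is the default up to 256 sequences; beyond that the caller supplies the
  set. No tree search or sophisticated (recursive) planning.
* **Known parameters.** Perception is inference over states, not learning of
  `A` or `B`. The only learned object is the deontic matrix.

## Perception as bound minimization

For one observation `o`, the variational free energy of a belief `Q(s)` is

\[
F \;=\; \sum_s Q(s)\,[\ln Q(s) - \ln(P(s)\,P(o\mid s))]
  \;=\; \underbrace{KL[Q \,\|\, P(s\mid o)]}_{\ge 0} \;-\; \ln P(o).
\]

`variational_free_energy()` reports all three quantities and the identity is
asserted to `1e-9` throughout the test suite. For categorical single-factor
posteriors the minimizer has a closed form — the normalized exponential of
`ln D + ln A[o, ]` — which is the exact posterior, so the bound is tight at
the solution. `infer_states()` returns that fixed point by default; a
mirror-descent iteration (`method = "mirror_descent"`, multiplicative update
`Q ← Q^{1-η} target^{η}`) is provided to exhibit gradient-flow-style
dynamics, with a free-energy trace that the tests assert is non-increasing.
Which descent scheme a brain might implement is not a claim this package
makes; both schemes are implementation choices required to agree (total
variation `< 1e-6` against the enumeration oracle).

## Planning by expected free energy

Each policy is scored per future time step by

\[
G(\pi,\tau) \;=\;
\underbrace{-\,\mathbb{E}[\ln C(o_\tau)]}_{\text{instrumental}}
\;+\;
\underbrace{\mathbb{E}[\ln Q(s_\tau\mid\pi) - \ln P(s_\tau\mid o_\tau,\pi)]}_{\text{epistemic}},
\]

with all expectations under the joint weight
`Q(s_τ|π)·P(o_τ|s_τ)` — exactly the printed decomposition, not the
outcome-marginal variant. The inner posterior `P(s_τ|o_τ,π)` is the Bayes
inversion of the predictive state belief through `A`. The epistemic term is
minus an expected information gain, hence `≤ 0`, strictly negative whenever
outcomes can disambiguate states; the tests verify the decomposition against
an independent brute-force double sum on a hundred random models, and the
sign property everywhere.

The policy posterior is `softmax(−γ · Σ_τ G(π,τ))`. The total over `τ` is an
unweighted sum (no horizon discounting — none is standard in this setting).

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| `gamma` | dimensionless (inverse nats) | 1 | with `γ = 1` the policy prior is literally `σ(−G)`; precision learning is out of scope, so `γ` is a fixed temperature |
| `epsilon` (log floor) | probability | 1e-16 | one-hot columns appear in fixtures; `ln 0` must be avoided without visible distortion (everything downstream is tested at ≥ 1e-12 tolerances) |
| `tol` (inference) | total variation | 1e-8 | far below any behavioral difference; mirror descent reaches it in tens of iterations |
| `max_iter` | iterations | 500 | generous; non-convergence raises a typed error carrying the last iterate |
| `eta` (deontic increment) | counts | 1 | one observation, one count — the minimal conjugate update |
| `prior_count` | counts | 1 | flat Dirichlet prior: uniform `E` before any experience |

## The deontic pathway

The deontic matrix `E[o, π] = P(o | π)` is a *policy-conditioned outcome
likelihood*: what a typical agent executing `π` would be seeing. At decision
time the pathway conditions on the **current** cue (not predicted future
outcomes): `deontic_log_likelihood()` reads `ln E[o, ]` across policies, and
`combine_pathways()` either adds it to `−γG` ("supplement", weighted 1:1 —
no weighting is principled here, so none is imposed) or uses it alone
("supplant"). In supplant mode nothing representational is consulted: the
episode loop never calls inference or EFE (a call counter in the episode log
and a namespace mock in the tests both verify zero invocations), and action
sequences are byte-identical under arbitrary perturbation of `A`, `B`, `D`
and preferences.

Learning is Dirichlet count accumulation: each (cue, chosen-policy) pair
adds `eta` to one cell, and `E` is the column-normalized counts. The update
commutes, strictly favors the updated cell within its column, and converges
to the stationary cue frequency (tested at `n = 1000` within `0.05`). The
choice of rule is ours: the underlying account names cue–policy learning but
gives no equation, and count accumulation is the minimal conjugate mechanism
that keeps `E` a valid likelihood.

One genuinely open reading we resolved narrowly: deontic value could also
enter the generative model's own outcome predictions. We implement only its
decision-level role (policy selection); the generative-level reading would
change perception itself and is out of scope.

## What the synthetic worlds emulate — and what they do not

There are no external datasets: all inputs are constructed worlds.

* `make_random_model()` draws every stochastic column from a flat Dirichlet.
  This emulates "a generic categorical world" for property tests (bounds,
  identities, oracle agreement) — it does **not** emulate any structured
  ecology, so green property tests establish mathematical correctness of the
  machinery, not behavioral claims.
* The **traffic-light** world (2 states, 2 cues, stop/go, horizon 1) encodes
  a minimal norm-governed contingency: stopping lets a red light cycle to
  green, going on green keeps it green, and preferences are near one-hot on
  the safe outcome. Its point is that the representational phase is
  *deterministically* cue-consistent, which makes the learned deontic
  likelihood match a closed-form count prediction exactly — a sharp test of
  the learning rule, not a model of real traffic.
* The **epistemic-probe** world (3 states, horizon 2) has two perceptually
  identical contexts and one action whose outcome disambiguates them, with
  uniform immediate preferences and peaked later ones. It isolates the
  epistemic term: the probing policies gain exactly `ln 2` nats of
  information at `τ = 1`, so policy ranking at `t = 0` is driven by
  information seeking. What a green test establishes is the *ordering* of
  policies, not any quantitative claim about exploration in richer worlds.
* In `run_habitization_experiment()` the two phases switch by a hard mode
  change at the halfway point. A graded alternative (supplement mode with
  growing counts) is available through `run_episode(mode = "supplement",
  learn_deontic = TRUE)`; the hard switch is the default because it exhibits
  the two pathways side by side in their pure forms. Episodes are one step
  long with a uniformly drawn light state; deontic counts update in both
  phases (self-reinforcing habits), and the phase-1 snapshot is kept so the
  closed form stays checkable.

The environment (generative process) is a separate object from the model and
may disagree with it; the agent touches it only through sampled outcomes via
a two-generic interface, which a test double with hidden internals verifies.

## Numerical choices

* **Flooring.** Probabilities are floored at `1e-16` before every logarithm
  (`safe_log`, `floor_and_normalize`). Consequence: quantities that are
  "exactly zero" analytically (the epistemic term under equal likelihood
  columns) are zero only to ~`1e-15`; the tests assert `≤ 1e-12`, the bound
  the report types guarantee.
* **Ties.** MAP action selection breaks ties toward the lowest policy index
  (`which.max`), documented and tested; scenario fixtures order the
  "interesting" policy first so tie-breaking never hides an effect.
* **Degenerate inputs.** All-zero vectors normalize only with a positive
  floor; an all-zero vector with `epsilon = 0` is an error. 1×1 models are
  valid and fully supported (every matrix is `[1]`).
* **Seeds.** Every stochastic entry point takes an explicit seed and runs
  under `withr::with_seed`, leaving the caller's RNG untouched; fully
  deterministic worlds produce seed-independent logs (tested).
* **Serialization.** JSON numbers are written at full precision
  (`digits = NA`); round-trips are lossless to `1e-12` per entry. YAML is
  accepted on input as a convenience; note `yaml::as.yaml` defaults to ~7
  significant digits, so re-emitting YAML at low precision can fail
  validation by design rather than load a distorted model.

## Known limitations

* No precision learning: `gamma` is fixed per model.
* No hierarchical or factorized models; no continuous-state formulation.
* Policy sets are explicit and small; no policy pruning is performed — the
  posterior always retains every enumerated policy.
* The deontic pathway's social origin (why cues are trustworthy) is not
  modeled — only the learning loop that exploits an already reliable
  contingency.
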