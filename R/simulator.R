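#' Construct an environment (the generative process)
#'
#' The environment is the world that actually produces outcomes, held
#' strictly distinct from the agent's generative model: its emission and
#' dynamics may differ from the model's `A` and `B`, and the agent only
#' ever sees sampled outcomes — never the true state or the true
#' parameters. Anything implementing the [observe_environment()] and
#' [step_environment()] generics can stand in for it.
#'
#' @param state Initial true state index.
#' @param emission True `P(o | s)` matrix, `n_outcomes x n_states`,
#'   categorical columns.
#' @param dynamics List of true per-action transition matrices
#'   `n_states x n_states`, categorical columns.
#' @return A list of class `"aif_environment"`.
#' @export
make_environment <- function(state, emission, dynamics) {
  emission <- as.matrix(emission)
  if (!is.list(dynamics)) dynamics <- list(as.matrix(dynamics))
  dynamics <- lapply(dynamics, as.matrix)
  for (s in seq_len(ncol(emission))) {
    assert_categorical(emission[, s], sprintf("emission column %d", s))
  }
  for (a in seq_along(dynamics)) {
    for (s in seq_len(ncol(dynamics[[a]]))) {
      assert_categorical(dynamics[[a]][, s],
                         sprintf("dynamics[[%d]] column %d", a, s))
    }
  }
  stopifnot(state >= 1L, state <= ncol(emission))
  structure(list(state = as.integer(state), emission = emission,
                 dynamics = dynamics), class = "aif_environment")
}

#' Sample an outcome from the environment's current state
#'
#' @param env An environment object.
#' @param ... Passed to methods.
#' @return Outcome index, sampled with the current RNG stream.
#' @export
observe_environment <- function(env, ...) UseMethod("observe_environment")

#' @export
observe_environment.aif_environment <- function(env, ...) {
  sample_categorical(env$emission[, env$state])
}

#' True state of the environment (experimenter-side accessor)
#'
#' Used only for logging and analysis; the agent's side of [run_episode()]
#' never consults it. Methods for custom environment classes may return
#' `NA` to keep the true state hidden even from the log.
#'
#' @param env An environment object.
#' @return State index (or `NA`).
#' @export
env_state <- function(env) UseMethod("env_state")

#' @export
env_state.aif_environment <- function(env) env$state

#' @export
env_state.default <- function(env) NA_integer_

#' Advance the environment by one action
#'
#' Samples the next true state from the dynamics column of the current
#' state under `action`, then an outcome from the emission column of the
#' next state. Deterministic for a fixed RNG state.
#'
#' @param env An environment object.
#' @param action Action index.
#' @param ... Passed to methods.
#' @return List with `env` (updated), `state` and `outcome`.
#' @export
step_environment <- function(env, action, ...) UseMethod("step_environment")

#' @export
step_environment.aif_environment <- function(env, action, ...) {
  check_action_index(length(env$dynamics), action)
  s_next <- sample_categorical(env$dynamics[[action]][, env$state])
  o <- sample_categorical(env$emission[, s_next])
  env$state <- s_next
  list(env = env, state = s_next, outcome = o)
}

#' Run one agent-environment episode
#'
#' The closed loop, one iteration per step:
#' \enumerate{
#'   \item observe the outcome emitted by the environment;
#'   \item (representational / supplement modes) infer hidden states from
#'     the observation and the transition-propagated prior, then evaluate
#'     expected free energy for every policy — both skipped entirely in
#'     `"supplant"` mode;
#'   \item form the policy posterior through [combine_pathways()] and
#'     [policy_posterior()], using the current observation as the deontic
#'     cue in the deontic modes;
#'   \item select the first action of the chosen policy, optionally update
#'     the deontic counts with the (cue, chosen policy) pair, and execute
#'     the action in the environment.
#' }
#' Between steps the state prior is the previous posterior pushed through
#' the executed action's transition matrix (in supplant mode, the prior is
#' propagated the same way without being consulted, so a later mode switch
#' can re-engage inference). The loop is reproducible for a fixed seed.
#'
#' @param model A valid `"generative_model"` (deontic matrix required in
#'   the deontic modes).
#' @param env An environment object.
#' @param steps Number of interaction steps, `>= 1`.
#' @param mode `"representational"`, `"supplement"` or `"supplant"`.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param rule Action-selection rule passed to [select_action()].
#' @param learn_deontic Update deontic counts from each (cue, chosen
#'   policy) pair (default `FALSE`; the habitization experiment turns it
#'   on in both modes).
#' @param cfg A [deontic_update_config()].
#' @return An object of class `"episode_log"`: per-step records (true
#'   state, outcome, belief, policy posterior, action, `F`, per-policy
#'   `G_total`, mode), the action/outcome sequences, call counters
#'   `efe_calls` and `infer_calls`, and the final `"deontic_model"` when
#'   learning is on.
#' @export
run_episode <- function(model, env, steps, mode = "representational",
                        seed = NULL, rule = "map", learn_deontic = FALSE,
                        cfg = deontic_update_config()) {
  assert_valid_model(model)
  stopifnot(steps >= 1L)
  mode <- match.arg(mode, c("representational", "supplement", "supplant"))
  deontic_needed <- mode != "representational" || learn_deontic
  dm <- if (deontic_needed) {
    if (is.null(model$E)) {
      deontic_model(n_outcomes = model$n_outcomes,
                    n_policies = model$n_policies,
                    prior_count = cfg$prior_count)
    } else as_deontic(model)
  } else NULL

  body <- function() {
    prior <- model$D
    o <- observe_environment(env)
    records <- vector("list", steps)
    actions <- integer(steps)
    outcomes <- integer(steps)
    efe_calls <- 0L
    infer_calls <- 0L

    for (t in seq_len(steps)) {
      tryCatch({
        if (mode == "supplant") {
          belief <- NULL; F_t <- NA_real_; G_total <- rep(NA_real_, model$n_policies)
          post <- policy_posterior(NULL, deontic_log_likelihood(dm, o),
                                   mode = "supplant")
        } else {
          inf <- infer_states(model, prior, o)
          infer_calls <- infer_calls + 1L
          belief <- inf$belief$Q
          F_t <- inf$report$F
          efe <- efe_table(model, belief)
          efe_calls <- efe_calls + 1L
          G_total <- efe$G_total
          dlog <- if (mode == "supplement") deontic_log_likelihood(dm, o) else NULL
          post <- policy_posterior(G_total, dlog, mode = mode,
                                   gamma = model$gamma)
        }
        act <- select_action(post, model$policies, t = 1L, rule = rule)
        pol <- attr(act, "policy")
        if (learn_deontic && !is.null(dm)) {
          dm <<- update_deontic_model(dm, o, pol, cfg)
        }
        records[[t]] <- list(t = t, true_state = env_state(env), outcome = o,
                             belief = belief, policy_posterior = post$Q_pi,
                             action = as.integer(act), policy = pol,
                             F = F_t, G_total = G_total, mode = mode)
        actions[t] <- as.integer(act)
        outcomes[t] <- o
        res <- step_environment(env, act)
        env <<- res$env
        o <- res$outcome
        prior <- if (is.null(belief)) {
          as.numeric(model$B[[act]] %*% prior)
        } else {
          as.numeric(model$B[[act]] %*% belief)
        }
      }, error = function(e) {
        stop(sprintf("episode step %d: %s", t, conditionMessage(e)),
             call. = FALSE)
      })
    }
    structure(list(steps = records, actions = actions, outcomes = outcomes,
                   efe_calls = efe_calls, infer_calls = infer_calls,
                   mode = mode, deontic = dm, n_steps = steps),
              class = "episode_log")
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

#' @export
print.episode_log <- function(x, ...) {
  cat(sprintf("Episode: %d steps, mode '%s', %d EFE evaluations, %d inferences\n",
              x$n_steps, x$mode, x$efe_calls, x$infer_calls))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.episode_log <- function(x, ...) {
  do.call(rbind, lapply(x$steps, function(r) {
    data.frame(t = r$t, true_state = r$true_state, outcome = r$outcome,
               action = r$action, policy = r$policy, F = r$F,
               mode = r$mode, stringsAsFactors = FALSE)
  }))
}

#' Write an episode log to disk
#'
#' One JSON-lines record per step (`episode.jsonl`) plus a CSV summary
#' (`episode.csv`) in `dir`.
#'
#' @param log An `"episode_log"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_episode_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jl <- file.path(dir, "episode.jsonl")
  con <- file(jl, open = "wt")
  on.exit(close(con))
  for (r in log$steps) {
    writeLines(as.character(jsonlite::toJSON(r, auto_unbox = TRUE,
                                             digits = NA, null = "null")), con)
  }
  utils::write.csv(as.data.frame(log), file.path(dir, "episode.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Traffic-light scenario
#'
#' A minimal habit-learning world: two states (the light is red / green),
#' two outcomes (the perceived cue, emitted faithfully), two actions
#' (stop = 1, go = 2), horizon 1, two single-action policies. Stopping at a
#' red light lets it cycle to green; going on red keeps you in the unsafe
#' red situation; stopping on green wastes the green (back to red) while
#' going keeps it. Preferences are (near) one-hot on the safe outcome
#' (green), so the representational agent deterministically stops on red
#' and goes on green. The deontic matrix starts flat with counts enabled,
#' ready for habitization. The environment mirrors the model exactly.
#'
#' @param initial_state True initial light state (default 1, red).
#' @return List with `model` and `env`.
#' @export
make_traffic_light_scenario <- function(initial_state = 1L) {
  A <- diag(2)                                   # faithful cue
  B_stop <- matrix(c(0, 1, 1, 0), 2, 2)          # stopping lets the light cycle
  B_go <- diag(2)                                # going preserves the situation
  C <- safe_log(floor_and_normalize(c(0, 1)))    # prefer the safe (green) outcome
  model <- generative_model(
    A = A, B = list(B_stop, B_go), D = c(0.5, 0.5), C = C, horizon = 1L,
    policies = matrix(c(1L, 2L), ncol = 1L), gamma = 1,
    E = matrix(0.5, 2, 2), E_counts = matrix(1, 2, 2))
  env <- make_environment(initial_state, emission = A,
                          dynamics = list(B_stop, B_go))
  list(model = model, env = env)
}

#' Epistemic-probe scenario
#'
#' Three states: two perceptually identical contexts (`ctx1`, `ctx2`,
#' both emitting cue A) and a `revealed` state emitting cue B. The initial
#' belief is split 50/50 over the two contexts. Action 1 ("probe") sends
#' `ctx2` to `revealed` while leaving `ctx1` alone — so its outcome
#' disambiguates the context — whereas action 2 ("stay") is the identity
#' and yields no information (the reachable states share an emission
#' column). Horizon 2; preferences are uniform at `tau = 1` and peaked on
#' cue B at `tau = 2`. Under expected free energy the probing policy wins
#' at `t = 0`: the agent first consolidates knowledge about the world,
#' then works toward preferred outcomes.
#'
#' @param initial_state True initial context (default 2, `ctx2`).
#' @return List with `model` and `env`.
#' @export
make_epistemic_probe_scenario <- function(initial_state = 2L) {
  A <- matrix(c(1, 0,   # ctx1 -> cue A
                1, 0,   # ctx2 -> cue A
                0, 1),  # revealed -> cue B
              nrow = 2, ncol = 3)
  B_probe <- matrix(c(1, 0, 0,
                      0, 0, 1,
                      0, 0, 1), nrow = 3, ncol = 3)
  B_stay <- diag(3)
  C <- cbind(safe_log(c(0.5, 0.5)), log(c(0.1, 0.9)))
  model <- generative_model(
    A = A, B = list(B_probe, B_stay), D = c(0.5, 0.5, 0), C = C,
    horizon = 2L, gamma = 1)
  env <- make_environment(initial_state, emission = A,
                          dynamics = list(B_probe, B_stay))
  list(model = model, env = env)
}

#' Habit-acquisition experiment in the traffic-light scenario
#'
#' Two phases of one-step episodes, each starting at a uniformly drawn
#' light state. Phase 1 runs the representational agent (MAP action rule;
#' its safe-outcome preferences make it stop on red and go on green
#' deterministically) while accumulating deontic counts from each
#' (cue, chosen policy) pair. Phase 2 hands control to the deontic pathway:
#' supplant mode with the learned matrix, sampling actions from
#' `softmax(ln P(o | policy))`. The summary records, per episode, the cue,
#' the action, whether the action was cue-consistent (stop on red, go on
#' green), the current `E[red, stop]`, and the mode in force.
#'
#' @param n_episodes Episodes per phase, `>= 1`.
#' @param seed Integer seed.
#' @param cfg A [deontic_update_config()].
#' @return List of class `"habitization_result"`: `summary` (data frame,
#'   one row per episode), `deontic` (the final `"deontic_model"`),
#'   `deontic_phase1` (its state at the end of phase 1), and `n_red` (red
#'   cues encountered in phase 1, for the closed-form count check
#'   `E[red, stop] = (prior + n_red * eta) / (2 * prior + n_red * eta)` at
#'   the end of phase 1).
#' @export
run_habitization_experiment <- function(n_episodes, seed,
                                        cfg = deontic_update_config()) {
  if (n_episodes < 1L) stop("n_episodes must be >= 1", call. = FALSE)
  scen <- make_traffic_light_scenario()
  model <- scen$model
  withr::with_seed(seed, {
    dm <- deontic_model(n_outcomes = 2, n_policies = 2,
                        prior_count = cfg$prior_count)
    rows <- vector("list", 2L * n_episodes)
    n_red <- 0L
    dm_phase1 <- NULL
    for (phase in 1:2) {
      if (phase == 2L) dm_phase1 <- dm
      mode <- if (phase == 1L) "representational" else "supplant"
      for (ep in seq_len(n_episodes)) {
        s0 <- sample.int(2L, 1L)
        env <- make_environment(s0, scen$env$emission, scen$env$dynamics)
        cue <- observe_environment(env)
        if (phase == 1L) {
          belief <- infer_states(model, model$D, cue)$belief$Q
          efe <- efe_table(model, belief)
          post <- policy_posterior(efe$G_total, mode = "representational",
                                   gamma = model$gamma)
          act <- select_action(post, model$policies, 1L, rule = "map")
        } else {
          post <- policy_posterior(NULL, deontic_log_likelihood(dm, cue),
                                   mode = "supplant")
          act <- select_action(post, model$policies, 1L, rule = "sample")
        }
        pol <- attr(act, "policy")
        dm <- update_deontic_model(dm, cue, pol, cfg)
        if (phase == 1L && cue == 1L) n_red <- n_red + 1L
        rows[[(phase - 1L) * n_episodes + ep]] <- data.frame(
          episode = (phase - 1L) * n_episodes + ep, phase = phase,
          mode = mode, cue = cue, action = as.integer(act),
          cue_consistent = (cue == 1L && act == 1L) ||
                           (cue == 2L && act == 2L),
          E_red_stop = dm$E[1, 1], stringsAsFactors = FALSE)
      }
    }
    structure(list(summary = do.call(rbind, rows), deontic = dm,
                   deontic_phase1 = dm_phase1, n_red = n_red),
              class = "habitization_result")
  })
}

#' @export
print.habitization_result <- function(x, ...) {
  s <- x$summary
  for (ph in unique(s$phase)) {
    sub <- s[s$phase == ph, ]
    cat(sprintf("phase %d (%s): %d episodes, cue-consistent frequency %.3f\n",
                ph, sub$mode[1], nrow(sub), mean(sub$cue_consistent)))
  }
  cat(sprintf("learned E[red, stop] = %.4f (n_red = %d)\n",
              x$deontic$E[1, 1], x$n_red))
  invisible(x)
}
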