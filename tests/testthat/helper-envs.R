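# Access-tracking environment double: exposes only the sampling interface
# (observe / step); the true emission, dynamics and state live in a closed
# environment that the agent cannot reach through the object, proving that
# run_episode needs nothing but sampled outcomes.

make_spy_env <- function(inner) {
  vault <- new.env(parent = emptyenv())
  vault$inner <- inner
  vault$observes <- 0L
  vault$steps <- 0L
  structure(list(vault = vault), class = "spy_env")
}

observe_environment.spy_env <- function(env, ...) {
  v <- env$vault
  v$observes <- v$observes + 1L
  observe_environment(v$inner)
}

step_environment.spy_env <- function(env, action, ...) {
  v <- env$vault
  v$steps <- v$steps + 1L
  res <- step_environment(v$inner, action)
  v$inner <- res$env
  list(env = env, state = res$state, outcome = res$outcome)
}

.S3method("observe_environment", "spy_env", observe_environment.spy_env)
.S3method("step_environment", "spy_env", step_environment.spy_env)
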