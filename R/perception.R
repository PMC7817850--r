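#' Marginal likelihood of an outcome under a state prior
#'
#' `P(o) = sum_s prior(s) * A[o, s]`: the model evidence for a single
#' observation, marginalized over hidden states.
#'
#' @param model A `"generative_model"`.
#' @param prior Categorical over states.
#' @param o Outcome index (1-based).
#' @return Scalar probability.
#' @export
marginal_likelihood <- function(model, prior, o) {
  check_outcome_index(model, o)
  assert_categorical(prior, "prior")
  sum(prior * model$A[o, ])
}

#' Exact Bayesian posterior over hidden states
#'
#' `P(s | o) = prior(s) * A[o, s] / P(o)`. This is the enumeration oracle
#' that approximate inference is tested against; it is exact for the
#' single-factor categorical models handled here.
#'
#' @inheritParams marginal_likelihood
#' @return A `"belief_state"`: list with `Q`, the posterior categorical.
#' @export
exact_posterior <- function(model, prior, o) {
  ml <- marginal_likelihood(model, prior, o)
  if (ml <= 0) {
    stop("impossible observation: marginal likelihood is zero", call. = FALSE)
  }
  belief_state(prior * model$A[o, ] / ml)
}

#' @rdname exact_posterior
#' @param Q A probability vector over states.
#' @export
belief_state <- function(Q) {
  assert_categorical(Q, "belief")
  structure(list(Q = as.numeric(Q)), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat("Q(s):", paste(signif(x$Q, 4), collapse = " "), "\n")
  invisible(x)
}

# accept either a belief_state or a bare probability vector
belief_vec <- function(Q) if (inherits(Q, "belief_state")) Q$Q else Q

#' Variational free energy of an approximate posterior
#'
#' For a single observation,
#' `F = sum_s Q(s) * (ln Q(s) - ln(prior(s) * A[o, s]))`,
#' the free energy of the approximate posterior `Q` under the generative
#' model. The report decomposes `F` into the KL divergence from the exact
#' posterior (the bound term, always non-negative) and the negative log
#' marginal likelihood (the evidence term): `F = KL + (-ln P(o))`, so `F`
#' is an upper bound on surprisal that is tight exactly when `Q` equals the
#' exact posterior.
#'
#' @inheritParams marginal_likelihood
#' @param Q A `"belief_state"` or probability vector over states.
#' @return A list of class `"free_energy_report"` with components `F`
#'   (nats), `kl_term` (nats, `>= 0`) and `neg_log_evidence` (nats).
#' @export
variational_free_energy <- function(model, prior, Q, o) {
  check_outcome_index(model, o)
  q <- belief_vec(Q)
  assert_categorical(q, "Q")
  assert_categorical(prior, "prior")
  joint <- prior * model$A[o, ]
  F <- sum(q * (safe_log(q) - safe_log(joint)))
  ml <- sum(joint)
  post <- exact_posterior(model, prior, o)$Q
  kl <- kl_divergence(q, post)
  structure(list(F = F, kl_term = kl, neg_log_evidence = -safe_log(ml)),
            class = "free_energy_report")
}

#' @export
print.free_energy_report <- function(x, ...) {
  cat(sprintf("F = %.6f nats (KL = %.6f, -ln evidence = %.6f)\n",
              x$F, x$kl_term, x$neg_log_evidence))
  invisible(x)
}

#' Infer hidden states by free-energy minimization
#'
#' Finds the belief `Q(s)` minimizing the variational free energy for one
#' observation. Two schemes are provided and must agree:
#' \describe{
#'   \item{`"fixed_point"`}{(default) the closed-form minimizer: the
#'     normalized exponential of `ln prior + ln A[o, ]`. For single-factor
#'     categorical posteriors this is the exact posterior, so the bound is
#'     tight at the solution.}
#'   \item{`"mirror_descent"`}{an iterative multiplicative (mirror-descent)
#'     update on the simplex, `Q <- Q^(1-step) * target^step` renormalized,
#'     exhibiting gradient-flow-style dynamics. The free energy is
#'     non-increasing along the iteration trace, which is returned for
#'     inspection.}
#' }
#'
#' @inheritParams marginal_likelihood
#' @param tol Convergence tolerance in total-variation distance
#'   (default `1e-8`).
#' @param max_iter Iteration cap for mirror descent (default 500).
#' @param method `"fixed_point"` or `"mirror_descent"`.
#' @param step Mirror-descent step size in (0, 1], default 0.5.
#' @return List with `belief` (a `"belief_state"`), `report` (a
#'   `"free_energy_report"` at the returned belief), `iterations`, and
#'   `trace` (free-energy value per iteration; length 1 for the
#'   fixed-point route).
#' @export
infer_states <- function(model, prior, o, tol = 1e-8, max_iter = 500L,
                         method = c("fixed_point", "mirror_descent"),
                         step = 0.5) {
  method <- match.arg(method)
  check_outcome_index(model, o)
  assert_categorical(prior, "prior")
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  log_target <- safe_log(prior) + safe_log(model$A[o, ])
  target <- softmax(log_target)

  if (method == "fixed_point") {
    q <- target
    rep <- variational_free_energy(model, prior, q, o)
    return(list(belief = belief_state(q), report = rep,
                iterations = 1L, trace = rep$F))
  }

  q <- rep(1 / model$n_states, model$n_states)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    trace <- c(trace, variational_free_energy(model, prior, q, o)$F)
    q_new <- softmax((1 - step) * safe_log(q) + step * log_target)
    if (total_variation(q_new, q) < tol) {
      q <- q_new
      converged <- TRUE
      break
    }
    q <- q_new
  }
  if (!converged) {
    cond <- structure(
      class = c("actinf_convergence_error", "error", "condition"),
      list(message = sprintf("infer_states: no convergence in %d iterations",
                             max_iter),
           call = sys.call(-1), last_iterate = q))
    stop(cond)
  }
  rep <- variational_free_energy(model, prior, q, o)
  list(belief = belief_state(q), report = rep,
       iterations = it, trace = c(trace, rep$F))
}

check_outcome_index <- function(model, o) {
  if (!is.numeric(o) || length(o) != 1L || o < 1L || o > model$n_outcomes ||
      o != round(o)) {
    stop(sprintf("outcome index %s out of range 1..%d",
                 format(o), model$n_outcomes), call. = FALSE)
  }
  invisible(TRUE)
}

check_action_index <- function(n_actions, a) {
  if (!is.numeric(a) || length(a) != 1L || a < 1L || a > n_actions ||
      a != round(a)) {
    stop(sprintf("action index %s out of range 1..%d", format(a), n_actions),
         call. = FALSE)
  }
  invisible(TRUE)
}
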