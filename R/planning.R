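#' Predictive beliefs about future hidden states under a policy
#'
#' Rolls the current belief forward through the action-indexed transition
#' matrices: `Q(s_tau | policy) = B[[a_tau]] %*% ... %*% B[[a_1]] %*% Q0`.
#'
#' @param model A `"generative_model"`.
#' @param Q0 Current belief: `"belief_state"` or probability vector.
#' @param policy Integer vector of action indices, length = horizon.
#' @return List of length `horizon`; element `tau` is the categorical
#'   `Q(s_tau | policy)`.
#' @export
predictive_state_beliefs <- function(model, Q0, policy) {
  q <- belief_vec(Q0)
  assert_categorical(q, "Q0")
  policy <- as.integer(policy)
  if (length(policy) != model$horizon) {
    stop("policy length must equal the planning horizon", call. = FALSE)
  }
  out <- vector("list", model$horizon)
  for (tau in seq_len(model$horizon)) {
    check_action_index(model$n_actions, policy[tau])
    q <- as.numeric(model$B[[policy[tau]]] %*% q)
    out[[tau]] <- q
  }
  out
}

#' Predictive outcome distribution from a state belief
#'
#' `Q(o_tau | policy)(o) = sum_s A[o, s] * Q(s_tau | policy)(s)`: the
#' outcome marginal obtained by pushing a state belief through the
#' likelihood matrix.
#'
#' @param model A `"generative_model"`.
#' @param Q_s_tau Categorical over states.
#' @return Categorical over outcomes.
#' @export
predictive_outcome_beliefs <- function(model, Q_s_tau) {
  q <- belief_vec(Q_s_tau)
  assert_categorical(q, "Q_s_tau")
  as.numeric(model$A %*% q)
}

#' Expected free energy of a policy
#'
#' For each future time step `tau`, with `Qs = Q(s_tau | policy)` and all
#' expectations taken under the joint weight `Qs(s) * A[o, s]`:
#' \describe{
#'   \item{instrumental}{`-E[ln C(o_tau)]`, the (negated) expected log
#'     preference — the goal-seeking, pragmatic term;}
#'   \item{epistemic}{`E[ln Qs(s) - ln P(s | o, policy)]` where
#'     `P(s | o, policy)` is the Bayes inversion of `Qs` through `A` —
#'     minus the expected information gain, hence always `<= 0`, and
#'     strictly negative whenever an outcome could disambiguate states.}
#' }
#' `G(policy, tau) = instrumental + epistemic`, and the per-policy total is
#' the plain sum over `tau`. Smaller `G` marks a better policy: the agent
#' both seeks preferred outcomes and resolves uncertainty about states.
#'
#' @inheritParams predictive_state_beliefs
#' @return A data frame with one row per `tau`: columns `tau`,
#'   `instrumental`, `epistemic`, `G`; attribute `"G_total"` holds the sum
#'   of `G` over `tau`.
#' @export
expected_free_energy <- function(model, Q0, policy) {
  qs <- predictive_state_beliefs(model, Q0, policy)
  A <- model$A
  rows <- lapply(seq_len(model$horizon), function(tau) {
    Qs <- qs[[tau]]
    lnC <- model$lnC[, tau]
    instrumental <- 0
    epistemic <- 0
    lnQs <- safe_log(Qs)
    for (o in seq_len(model$n_outcomes)) {
      w <- Qs * A[o, ]                       # joint weight Qs(s) * P(o | s)
      if (sum(w) <= 0) next
      post <- floor_and_normalize(w)         # P(s | o, policy) by Bayes
      epistemic <- epistemic + sum(w * (lnQs - safe_log(post)))
      instrumental <- instrumental - sum(w) * lnC[o]
    }
    data.frame(tau = tau, instrumental = instrumental,
               epistemic = epistemic, G = instrumental + epistemic)
  })
  out <- do.call(rbind, rows)
  attr(out, "G_total") <- sum(out$G)
  out
}

#' Per-policy expected-free-energy table
#'
#' Evaluates [expected_free_energy()] for every policy in the model's
#' policy set.
#'
#' @inheritParams predictive_state_beliefs
#' @return A list of class `"efe_report"`: `table`, a data frame with
#'   columns `policy`, `tau`, `instrumental`, `epistemic`, `G`; and
#'   `G_total`, the per-policy vector of summed `G`.
#' @export
efe_table <- function(model, Q0) {
  tabs <- lapply(seq_len(model$n_policies), function(p) {
    tab <- expected_free_energy(model, Q0, model$policies[p, ])
    cbind(policy = p, tab)
  })
  table <- do.call(rbind, tabs)
  G_total <- vapply(tabs, function(t) sum(t$G), numeric(1))
  structure(list(table = table, G_total = G_total), class = "efe_report")
}

#' @export
print.efe_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("G_total:", paste(signif(x$G_total, 6), collapse = " "), "\n")
  invisible(x)
}

#' Posterior distribution over policies
#'
#' Applies the softmax operator to the (temperature-scaled) policy
#' log-prior produced by the selected pathway:
#' \describe{
#'   \item{`"representational"`}{`softmax(-gamma * G_total)` — the policy
#'     with the least expected free energy is the most probable.}
#'   \item{`"supplement"`}{`softmax(-gamma * G_total + deontic_logvec)` —
#'     deontic evidence added to planning.}
#'   \item{`"supplant"`}{`softmax(deontic_logvec)` — expected free energy
#'     ignored entirely.}
#' }
#'
#' @param G_total Numeric vector of per-policy expected free energies.
#' @param deontic_logvec Optional per-policy deontic log-likelihoods (nats),
#'   required in the deontic modes.
#' @param mode Pathway mode (see above).
#' @param gamma Softmax temperature, `> 0`.
#' @return A list of class `"policy_posterior"` with `Q_pi`, a categorical
#'   over policies, and `mode`.
#' @export
policy_posterior <- function(G_total, deontic_logvec = NULL,
                             mode = c("representational", "supplement",
                                      "supplant"),
                             gamma = 1) {
  mode <- match.arg(mode)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  # temperature scales the planning term only; deontic evidence is a
  # log-likelihood and enters at its natural scale; in supplant mode
  # G_total may be NULL since it is never consulted
  scaled_G <- if (mode == "supplant") NULL else gamma * G_total
  logp <- combine_pathways(scaled_G, deontic_logvec, mode)
  structure(list(Q_pi = softmax(logp), mode = mode),
            class = "policy_posterior")
}

#' @export
print.policy_posterior <- function(x, ...) {
  cat(sprintf("Q(pi) [%s]:", x$mode),
      paste(signif(x$Q_pi, 4), collapse = " "), "\n")
  invisible(x)
}

#' Select an action from the policy posterior
#'
#' @param posterior A `"policy_posterior"`.
#' @param policies Integer policy matrix (rows = policies).
#' @param t Time index within the horizon (1-based).
#' @param rule `"map"` (default): the action at time `t` of the
#'   max-posterior policy, ties broken toward the lowest policy index;
#'   `"sample"`: draw a policy from `Q_pi`, then take its action at `t`.
#' @param seed Optional seed for the `"sample"` rule; `NULL` uses the
#'   current RNG stream.
#' @return The selected action index, with attribute `"policy"` giving the
#'   selected policy index.
#' @export
select_action <- function(posterior, policies, t, rule = c("map", "sample"),
                          seed = NULL) {
  rule <- match.arg(rule)
  if (nrow(policies) == 0L) stop("empty policy set", call. = FALSE)
  if (t < 1L || t > ncol(policies)) {
    stop("time index outside the planning horizon", call. = FALSE)
  }
  p <- if (rule == "map") {
    which.max(posterior$Q_pi)    # which.max already takes the first maximum
  } else if (is.null(seed)) {
    sample_categorical(posterior$Q_pi)
  } else {
    withr::with_seed(seed, sample_categorical(posterior$Q_pi))
  }
  structure(policies[p, t], policy = p)
}
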