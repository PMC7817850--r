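#' Construct a discrete-state generative model
#'
#' Bundles the categorical parameter arrays of a single-factor,
#' single-modality POMDP-style generative model:
#' \describe{
#'   \item{A}{likelihood matrix, `n_outcomes x n_states`; column `s` is
#'     `P(o | s)`.}
#'   \item{B}{transition model: a list with one `n_states x n_states` matrix
#'     per discrete action; column `s` of `B[[a]]` is `P(s' | s, a)`.}
#'   \item{D}{initial-state prior, a categorical over states.}
#'   \item{C}{outcome preferences, stored internally as the log of a proper
#'     distribution (`lnC`), one column per future time step. `C` may be a
#'     vector (recycled over the horizon) or an `n_outcomes x horizon`
#'     matrix. With `preferences = "utilities"` raw utilities are accepted
#'     and normalized per time step via log-softmax; with the default
#'     `"log_probs"` entries must already be the log of a distribution.}
#'   \item{policies}{explicit policy set: an integer matrix with one row per
#'     policy and `horizon` columns of 1-based action indices. `NULL`
#'     enumerates all `n_actions^horizon` sequences provided that count is
#'     at most 256.}
#'   \item{E}{optional deontic matrix, `n_outcomes x n_policies`; column
#'     `p` is `P(o | policy p)`. `E_counts` optionally carries the
#'     concentration counts from which `E` is obtained by column
#'     normalization (see [update_deontic_model()]).}
#' }
#'
#' Matrix orientation follows the convention that columns are distributions,
#' so belief propagation is a plain matrix-vector product. The constructor
#' assembles the object without enforcing invariants; use [validate_model()]
#' for a full report, or [load_model()] which refuses invalid input.
#'
#' @param A Likelihood matrix `n_outcomes x n_states`.
#' @param B List of per-action transition matrices `n_states x n_states`.
#' @param D Initial state prior vector of length `n_states`.
#' @param C Preferences: vector of length `n_outcomes` or matrix
#'   `n_outcomes x horizon`.
#' @param horizon Planning horizon `T >= 1` (number of future time steps).
#' @param policies Integer policy matrix (`n_policies x horizon`) or `NULL`.
#' @param gamma Softmax temperature (precision) over policies, `> 0`.
#'   Default 1 so that the policy prior is exactly `softmax(-G)`.
#' @param E Optional deontic matrix `n_outcomes x n_policies`.
#' @param E_counts Optional non-negative concentration counts, same shape
#'   as `E`.
#' @param preferences Either `"log_probs"` (default) or `"utilities"`.
#' @return An object of class `"generative_model"`.
#' @seealso [validate_model()], [load_model()], [make_random_model()]
#' @export
generative_model <- function(A, B, D, C, horizon,
                             policies = NULL, gamma = 1,
                             E = NULL, E_counts = NULL,
                             preferences = c("log_probs", "utilities")) {
  preferences <- match.arg(preferences)
  A <- as.matrix(A)
  if (!is.list(B)) B <- list(as.matrix(B))
  B <- lapply(B, as.matrix)
  D <- as.numeric(D)
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) {
    stop("horizon must be a positive integer", call. = FALSE)
  }
  n_outcomes <- nrow(A)
  n_actions <- length(B)

  lnC <- normalize_preferences(C, n_outcomes, horizon, preferences)

  if (is.null(policies)) {
    policies <- enumerate_policies(n_actions, horizon)
  } else {
    policies <- matrix(as.integer(policies), nrow = NROW(policies))
  }
  if (!is.null(E)) E <- as.matrix(E)
  if (!is.null(E_counts)) E_counts <- as.matrix(E_counts)

  structure(
    list(A = A, B = B, D = D, lnC = lnC, policies = policies,
         horizon = horizon, gamma = as.numeric(gamma),
         E = E, E_counts = E_counts,
         n_states = ncol(A), n_outcomes = n_outcomes,
         n_actions = n_actions, n_policies = nrow(policies)),
    class = "generative_model"
  )
}

# preferences -> lnC matrix [n_outcomes x horizon]
normalize_preferences <- function(C, n_outcomes, horizon, preferences) {
  if (is.null(dim(C))) C <- matrix(as.numeric(C), ncol = 1L)
  C <- as.matrix(C)
  if (ncol(C) == 1L && horizon > 1L) {
    C <- C[, rep(1L, horizon), drop = FALSE]
  }
  if (identical(preferences, "utilities")) {
    # log-softmax per time step turns raw utilities into log-probabilities
    C <- apply(C, 2L, function(u) u - log(sum(exp(u - max(u)))) - max(u))
    C <- matrix(C, nrow = n_outcomes)
  }
  C
}

#' Enumerate all fixed-length action sequences
#'
#' @param n_actions Number of discrete actions.
#' @param horizon Sequence length.
#' @param cap Refuse enumeration beyond this many policies (default 256);
#'   larger policy sets must be supplied explicitly.
#' @return Integer matrix, one row per policy, `horizon` columns; the first
#'   time step varies fastest, so policy 1 is all-ones.
#' @export
enumerate_policies <- function(n_actions, horizon, cap = 256L) {
  n <- n_actions^horizon
  if (n > cap) {
    stop(sprintf("policy enumeration would produce %d > %d sequences; %s",
                 n, cap, "supply an explicit policy matrix"), call. = FALSE)
  }
  g <- expand.grid(rep(list(seq_len(n_actions)), horizon))
  m <- as.matrix(g)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf(
    "Generative model: %d states, %d outcomes, %d actions, horizon %d, %d policies\n",
    x$n_states, x$n_outcomes, x$n_actions, x$horizon, x$n_policies))
  cat(sprintf("gamma = %g; deontic matrix: %s\n",
              x$gamma, if (is.null(x$E)) "absent" else "present"))
  invisible(x)
}

#' Validate a generative model
#'
#' Checks every structural invariant and returns a report instead of
#' throwing: column stochasticity of `A`, `B` (per action) and `E`,
#' validity of `D`, per-step normalization of the stored log-preferences,
#' action-index ranges in the policy matrix, agreement between `E` and its
#' concentration counts, cross-component dimension consistency, and
#' `gamma > 0`.
#'
#' @param model A `"generative_model"`.
#' @return A data frame of class `"aif_validation"` with columns `code`
#'   (machine-readable) and `message`; zero rows iff the model is valid.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(code, message) {
    v[[length(v) + 1L]] <<- data.frame(code = code, message = message,
                                       stringsAsFactors = FALSE)
  }
  ns <- model$n_states; no <- model$n_outcomes

  if (!is.matrix(model$A) || nrow(model$A) != no || ncol(model$A) != ns) {
    add("A_shape", "A is not an n_outcomes x n_states matrix")
  } else {
    for (s in seq_len(ns)) {
      if (!is_categorical(model$A[, s])) {
        add("A_col_stochastic",
            sprintf("A column %d is not a categorical over outcomes", s))
      }
    }
  }

  for (a in seq_along(model$B)) {
    Ba <- model$B[[a]]
    if (!is.matrix(Ba) || nrow(Ba) != ns || ncol(Ba) != ns) {
      add("B_shape", sprintf("B[[%d]] is not n_states x n_states", a))
      next
    }
    for (s in seq_len(ns)) {
      if (!is_categorical(Ba[, s])) {
        add("B_col_stochastic",
            sprintf("B[[%d]] column %d is not a categorical over next states",
                    a, s))
      }
    }
  }

  if (length(model$D) != ns || !is_categorical(model$D)) {
    add("D_invalid", "D is not a valid categorical over states")
  }

  if (!is.matrix(model$lnC) || nrow(model$lnC) != no ||
      ncol(model$lnC) != model$horizon) {
    add("C_shape", "lnC is not an n_outcomes x horizon matrix")
  } else {
    for (tau in seq_len(model$horizon)) {
      if (abs(sum(exp(model$lnC[, tau])) - 1) > .CAT_TOL) {
        add("C_not_normalized",
            sprintf("exp(lnC) at tau = %d does not sum to 1", tau))
      }
    }
  }

  P <- model$policies
  if (!is.matrix(P) || ncol(P) != model$horizon || nrow(P) < 1L) {
    add("policy_shape", "policies is not an n_policies x horizon matrix")
  } else if (any(P < 1L) || any(P > model$n_actions)) {
    add("policy_index_range",
        sprintf("policy matrix references action indices outside 1..%d",
                model$n_actions))
  }

  if (!is.null(model$E)) {
    E <- model$E
    if (!is.matrix(E) || nrow(E) != no || ncol(E) != model$n_policies) {
      add("E_shape", "E is not an n_outcomes x n_policies matrix")
    } else {
      for (p in seq_len(ncol(E))) {
        if (!is_categorical(E[, p])) {
          add("E_col_stochastic",
              sprintf("E column %d is not a categorical over outcomes", p))
        }
      }
      if (!is.null(model$E_counts)) {
        ct <- model$E_counts
        if (!identical(dim(ct), dim(E)) || any(ct < 0)) {
          add("E_counts_shape", "E_counts shape/negativity violation")
        } else {
          En <- sweep(ct, 2L, colSums(ct), "/")
          if (max(abs(En - E)) > .CAT_TOL) {
            add("E_counts_mismatch",
                "E does not equal column-normalized E_counts")
          }
        }
      }
    }
  }

  if (!is.numeric(model$gamma) || length(model$gamma) != 1L ||
      !is.finite(model$gamma) || model$gamma <= 0) {
    add("gamma_nonpositive", "gamma must be a positive scalar")
  }

  out <- if (length(v)) do.call(rbind, v) else
    data.frame(code = character(0), message = character(0),
               stringsAsFactors = FALSE)
  class(out) <- c("aif_validation", class(out))
  out
}

#' @export
print.aif_validation <- function(x, ...) {
  if (nrow(x) == 0L) cat("valid model: no violations\n")
  else {
    cat(sprintf("%d violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x))) cat(sprintf("  [%s] %s\n", x$code[i], x$message[i]))
  }
  invisible(x)
}

# stop with a readable summary if the model is invalid
assert_valid_model <- function(model) {
  rep <- validate_model(model)
  if (nrow(rep) > 0L) {
    stop("invalid generative model: ",
         paste(rep$code, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' Generate a random valid generative model
#'
#' Fixture generator: every stochastic column (`A`, `B` per action, `D`,
#' and the deontic matrix when requested) is drawn from a flat Dirichlet;
#' preferences are a flat-Dirichlet draw stored in log form, shared across
#' the horizon; the policy set is the full enumeration. Deterministic for a
#' fixed seed, and the caller's RNG state is left untouched.
#'
#' @param n_states,n_outcomes,n_actions Positive dimensions.
#' @param horizon Planning horizon, `>= 1`.
#' @param seed Integer seed.
#' @param gamma Softmax temperature, default 1.
#' @param with_deontic Attach a random deontic matrix (default `FALSE`).
#' @return A valid `"generative_model"` (empty [validate_model()] report).
#' @export
make_random_model <- function(n_states, n_outcomes, n_actions, horizon,
                              seed, gamma = 1, with_deontic = FALSE) {
  dims <- c(n_states, n_outcomes, n_actions, horizon)
  if (any(dims < 1) || any(dims != round(dims))) {
    stop("all dimensions must be positive integers", call. = FALSE)
  }
  withr::with_seed(seed, {
    A <- replicate(n_states, rdirichlet_flat(n_outcomes))
    A <- matrix(A, nrow = n_outcomes)
    B <- lapply(seq_len(n_actions), function(a) {
      matrix(replicate(n_states, rdirichlet_flat(n_states)), nrow = n_states)
    })
    D <- rdirichlet_flat(n_states)
    C <- log(floor_and_normalize(rdirichlet_flat(n_outcomes)))
    policies <- enumerate_policies(n_actions, horizon)
    E <- if (with_deontic) {
      matrix(replicate(nrow(policies), rdirichlet_flat(n_outcomes)),
             nrow = n_outcomes)
    } else NULL
    generative_model(A = A, B = B, D = D, C = C, horizon = horizon,
                     policies = policies, gamma = gamma, E = E)
  })
}
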