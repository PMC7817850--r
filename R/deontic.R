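#' Deontic model: a policy-conditioned outcome likelihood
#'
#' The deontic matrix `E` (`n_outcomes x n_policies`) holds `P(o | policy)`:
#' how likely each cue is, given that a typical agent is executing each
#' policy. Inverting this mapping at decision time — "if I see this cue, I
#' am doing that" — yields a route to action that never consults beliefs
#' about hidden states. `counts` optionally carries Dirichlet-style
#' concentration parameters from which `E` is the column-normalized mean,
#' enabling learning by count accumulation.
#'
#' @param E Matrix `n_outcomes x n_policies` with categorical columns, or
#'   `NULL` to build a flat matrix from `counts`.
#' @param counts Optional non-negative matrix of the same shape.
#' @param n_outcomes,n_policies Dimensions, used when `E` is `NULL`.
#' @param prior_count Flat initialization for `counts` when only dimensions
#'   are given (default 1).
#' @return A list of class `"deontic_model"` with elements `E` and `counts`.
#' @export
deontic_model <- function(E = NULL, counts = NULL,
                          n_outcomes = NULL, n_policies = NULL,
                          prior_count = 1) {
  if (is.null(E) && is.null(counts)) {
    stopifnot(!is.null(n_outcomes), !is.null(n_policies), prior_count > 0)
    counts <- matrix(prior_count, n_outcomes, n_policies)
  }
  if (is.null(E)) E <- sweep(counts, 2L, colSums(counts), "/")
  E <- as.matrix(E)
  for (p in seq_len(ncol(E))) assert_categorical(E[, p], sprintf("E column %d", p))
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(identical(dim(counts), dim(E)), all(counts >= 0))
  }
  structure(list(E = E, counts = counts), class = "deontic_model")
}

# pull a deontic_model out of a generative_model (or pass one through)
as_deontic <- function(x) {
  if (inherits(x, "deontic_model")) return(x)
  if (inherits(x, "generative_model")) {
    if (is.null(x$E)) stop("model has no deontic matrix", call. = FALSE)
    return(deontic_model(E = x$E, counts = x$E_counts))
  }
  deontic_model(E = x)
}

#' Deontic value of an observation
#'
#' Returns `ln P(o | policy)` for every policy: the log of row `o` of the
#' (floored) deontic matrix, in the ordering of the model's policy set.
#' This vector is the cue's evidence for each policy and is what the
#' deontic pathway feeds to the softmax in place of (or on top of)
#' expected free energy.
#'
#' @param deontic A `"deontic_model"`, a `"generative_model"` carrying `E`,
#'   or a bare deontic matrix.
#' @param o Outcome (cue) index, 1-based.
#' @return Numeric vector over policies, in nats.
#' @export
deontic_log_likelihood <- function(deontic, o) {
  dm <- as_deontic(deontic)
  if (o < 1L || o > nrow(dm$E) || o != round(o)) {
    stop(sprintf("outcome index %s out of range 1..%d", format(o),
                 nrow(dm$E)), call. = FALSE)
  }
  safe_log(dm$E[o, ])
}

#' Combine the representational and deontic pathways
#'
#' Produces the unnormalized log-prior over policies passed to the softmax:
#' `-G_total` in `"representational"` mode, `-G_total + deontic_logvec`
#' when the deontic likelihood supplements planning, and `deontic_logvec`
#' alone when it supplants planning (expected free energy ignored).
#'
#' @param G_total Per-policy expected free energies (nats).
#' @param deontic_logvec Per-policy deontic log-likelihoods (nats);
#'   required in the deontic modes.
#' @param mode `"representational"`, `"supplement"` or `"supplant"`.
#' @return Unnormalized per-policy log-prior (nats).
#' @export
combine_pathways <- function(G_total, deontic_logvec = NULL,
                             mode = c("representational", "supplement",
                                      "supplant")) {
  mode <- match.arg(mode)
  if (mode == "representational") return(-G_total)
  if (is.null(deontic_logvec)) {
    stop(sprintf("mode '%s' requires a deontic log-likelihood vector", mode),
         call. = FALSE)
  }
  if (mode == "supplement" && length(deontic_logvec) != length(G_total)) {
    stop("G_total and deontic_logvec lengths differ", call. = FALSE)
  }
  switch(mode,
         supplement = -G_total + deontic_logvec,
         supplant = deontic_logvec)
}

#' Configuration of the deontic learning rule
#'
#' @param eta Concentration increment per observed (cue, policy)
#'   co-occurrence, `> 0` (default 1).
#' @param prior_count Flat initial concentration per cell, `> 0`
#'   (default 1).
#' @return A list of class `"deontic_update_config"`.
#' @export
deontic_update_config <- function(eta = 1, prior_count = 1) {
  stopifnot(eta > 0, prior_count > 0)
  structure(list(eta = eta, prior_count = prior_count),
            class = "deontic_update_config")
}

#' Learn the cue-policy mapping from one co-occurrence
#'
#' Dirichlet-style accumulation: the concentration count for cell
#' `(o, pi)` is increased by `eta` and `E` is recomputed by column
#' normalization. With a flat prior of `prior_count`, after `n` observations
#' of cue `o` under policy `pi` (and none of the other cues) the learned
#' likelihood is `(prior_count + n*eta) / (n_outcomes*prior_count + n*eta)`.
#' Updates commute, so the order of experience does not matter.
#'
#' @param deontic A `"deontic_model"`; if it has no counts they are
#'   initialized to `cfg$prior_count` everywhere.
#' @param o Observed cue (outcome index).
#' @param pi Policy index that was executed.
#' @param cfg A [deontic_update_config()].
#' @return The updated `"deontic_model"`.
#' @export
update_deontic_model <- function(deontic, o, pi,
                                 cfg = deontic_update_config()) {
  dm <- as_deontic(deontic)
  if (o < 1L || o > nrow(dm$E) || o != round(o)) {
    stop("outcome index out of range", call. = FALSE)
  }
  if (pi < 1L || pi > ncol(dm$E) || pi != round(pi)) {
    stop("policy index out of range", call. = FALSE)
  }
  if (is.null(dm$counts)) {
    dm$counts <- matrix(cfg$prior_count, nrow(dm$E), ncol(dm$E))
  }
  dm$counts[o, pi] <- dm$counts[o, pi] + cfg$eta
  dm$E <- sweep(dm$counts, 2L, colSums(dm$counts), "/")
  dm
}
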