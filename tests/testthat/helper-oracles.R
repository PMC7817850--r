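# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: everything is plain loops over enumerated states
# and outcomes, sharing only the published numerical convention (floor at
# 1e-16 before logs).

EPS <- 1e-16

olog <- function(x) log(max(x, EPS))

# exact Bayes posterior by enumeration
oracle_posterior <- function(A, prior, o) {
  joint <- numeric(length(prior))
  for (s in seq_along(prior)) joint[s] <- prior[s] * A[o, s]
  joint / sum(joint)
}

# marginal likelihood by enumeration
oracle_evidence <- function(A, prior, o) {
  total <- 0
  for (s in seq_along(prior)) total <- total + prior[s] * A[o, s]
  total
}

# variational free energy by its defining sum
oracle_F <- function(A, prior, q, o) {
  total <- 0
  for (s in seq_along(q)) {
    total <- total + q[s] * (olog(q[s]) - olog(prior[s] * A[o, s]))
  }
  total
}

# expected free energy at one tau from the joint (single-sum) form:
# G = sum_{s,o} Qs(s) A(o|s) [ln Qs(s) - ln P(s|o) - ln C(o)]
oracle_G_joint <- function(A, Qs, lnC) {
  G <- 0
  for (o in seq_len(nrow(A))) {
    marg <- 0
    for (s in seq_along(Qs)) marg <- marg + Qs[s] * A[o, s]
    for (s in seq_along(Qs)) {
      w <- Qs[s] * A[o, s]
      if (w <= 0) next
      post_s <- (Qs[s] * A[o, s] + EPS) / (marg + length(Qs) * EPS)
      G <- G + w * (olog(Qs[s]) - olog(post_s) - lnC[o])
    }
  }
  G
}

# state belief rollout by explicit matrix products
oracle_rollout <- function(B, Q0, policy) {
  out <- list()
  q <- Q0
  for (tau in seq_along(policy)) {
    nq <- numeric(length(q))
    Ba <- B[[policy[tau]]]
    for (i in seq_along(q)) nq[i] <- sum(Ba[i, ] * q)
    q <- nq
    out[[tau]] <- q
  }
  out
}

# random categorical from the test RNG stream
rand_cat <- function(n) {
  g <- stats::rgamma(n, 1, 1)
  g / sum(g)
}
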