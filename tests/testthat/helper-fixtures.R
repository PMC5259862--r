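# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# Small random bipartite network with every drug and disease connected at
# least once (avoids degenerate rows unless a test wants them).
random_network <- function(n, m, density = 0.3, seed = 1) {
  A <- withr::with_seed(seed, {
    A <- matrix(stats::rbinom(n * m, 1, density), n, m)
    # guarantee no empty rows/columns
    for (i in which(rowSums(A) == 0)) A[i, sample.int(m, 1)] <- 1
    for (j in which(colSums(A) == 0)) A[sample.int(n, 1), j] <- 1
    A
  })
  association_network(sprintf("c%03d", seq_len(n)), sprintf("d%03d", seq_len(m)), A)
}

# A fully-built transition matrix on a random planted fixture.
random_transition <- function(seed = 1, n = 15, m = 12, lambda = 0.8) {
  fx <- simulate_fixture(n, m, 3, 0.6, 0.05, 64, 0.1, seed = seed)
  sims <- build_similarities(fx$net, fx$fingerprints, fx$concepts)
  list(fx = fx, sims = sims,
       T = suppressWarnings(
         build_transition(sims$drug, sims$disease, fx$net, lambda)))
}

# Direct per-entry evaluation of the four piecewise transition formulas;
# deliberately slow and element-wise, independent of build_transition's
# vectorized path.
transition_oracle <- function(sim_drug, sim_disease, net, lambda,
                              zero_diagonal = TRUE) {
  wc <- sim_drug$values; wd <- sim_disease$values
  if (zero_diagonal) { diag(wc) <- 0; diag(wd) <- 0 }
  A <- net$adjacency
  n <- nrow(A); m <- ncol(A)
  Tm <- matrix(0, n + m, n + m)
  for (i in seq_len(n)) {
    sw <- sum(wc[i, ]); ka <- sum(A[i, ])
    for (j in seq_len(n))
      Tm[i, j] <- if (sw == 0) 0
        else if (ka == 0) wc[i, j] / sw else (1 - lambda) * wc[i, j] / sw
    for (j in seq_len(m))
      Tm[i, n + j] <- if (ka == 0) 0 else lambda * A[i, j] / ka
    if (ka > 0 && sw == 0)                  # stranded: full mass crosses
      for (j in seq_len(m)) Tm[i, n + j] <- A[i, j] / ka
  }
  for (i in seq_len(m)) {
    sw <- sum(wd[i, ]); ka <- sum(A[, i])
    for (j in seq_len(m))
      Tm[n + i, n + j] <- if (sw == 0) 0
        else if (ka == 0) wd[i, j] / sw else (1 - lambda) * wd[i, j] / sw
    for (j in seq_len(n))
      Tm[n + i, j] <- if (ka == 0) 0 else lambda * A[j, i] / ka
    if (ka > 0 && sw == 0)
      for (j in seq_len(n)) Tm[n + i, j] <- A[j, i] / ka
  }
  Tm
}

# Closed-form steady state of the restart walk: alpha (I - (1-alpha) T')^-1 P0.
rwr_closed_form <- function(T, p0, alpha) {
  Tm <- as.matrix(T$matrix)
  solve(diag(nrow(Tm)) - (1 - alpha) * t(Tm), alpha * p0)
}

# Brute-force concordance AUC: P(score_pos > score_neg), ties one half.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  sum(cmp) / (length(pos) * length(neg))
}
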