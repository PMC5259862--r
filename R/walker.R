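#' Initial distribution for a drug-centric walk
#'
#' The queried drug is the seed in the drug layer with probability 1, and
#' its known associated diseases share one unit of probability equally in
#' the disease layer; the tradeoff factor `eta` then weights the two
#' layers, giving the drug block `eta * e_i` and the disease block
#' `(1 - eta) / k(c_i)` on the associated diseases. A drug with no known
#' disease has no disease-side seed set: all mass goes to the drug node
#' (`eta` effectively 1 for that query), so new drugs remain scorable.
#'
#' @param drug_index 1-based index of the query drug.
#' @param net an [association_network()].
#' @param eta tradeoff factor in [0, 1].
#' @return A numeric probability vector of length `n + m` (drugs first)
#'   summing to 1.
#' @export
initial_drug_centric <- function(drug_index, net, eta = 0.4) {
  n <- length(net$drug_ids); m <- length(net$disease_ids)
  if (drug_index < 1L || drug_index > n) stop("drug_index out of range")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  assoc <- which(net$adjacency[drug_index, ] == 1)
  p0 <- numeric(n + m)
  if (length(assoc) == 0L) {
    p0[drug_index] <- 1
  } else {
    p0[drug_index] <- eta
    p0[n + assoc] <- (1 - eta) / length(assoc)
  }
  names(p0) <- c(net$drug_ids, net$disease_ids)
  p0
}

#' Initial distribution for a disease-centric walk
#'
#' Mirror image of [initial_drug_centric()]: the queried disease gets
#' `eta`, its associated drugs share `(1 - eta)` equally. A disease with no
#' known drug gets all mass on the disease node.
#'
#' @param disease_index 1-based index of the query disease.
#' @param net an [association_network()].
#' @param eta tradeoff factor in [0, 1].
#' @return A numeric probability vector of length `n + m` (drugs first)
#'   summing to 1.
#' @export
initial_disease_centric <- function(disease_index, net, eta = 0.4) {
  n <- length(net$drug_ids); m <- length(net$disease_ids)
  if (disease_index < 1L || disease_index > m) stop("disease_index out of range")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  assoc <- which(net$adjacency[, disease_index] == 1)
  p0 <- numeric(n + m)
  if (length(assoc) == 0L) {
    p0[n + disease_index] <- 1
  } else {
    p0[n + disease_index] <- eta
    p0[assoc] <- (1 - eta) / length(assoc)
  }
  names(p0) <- c(net$drug_ids, net$disease_ids)
  p0
}

# Two-pass fusion: the confidence score of a candidate pair is the mean of
# its drug-centric and disease-centric steady-state probabilities.
two_pass_mean <- function(drug_centric, disease_centric) {
  (drug_centric + disease_centric) / 2
}

# Shared iteration core. tT is the transposed transition matrix (column
# action: mass flows along transitions). Both rwr() and score_all() call
# this, so a single-pair score and the batch score agree bit for bit.
rwr_core <- function(tT, p0, alpha, epsilon, max_iter) {
  p <- p0
  for (t in seq_len(max_iter)) {
    p_new <- as.numeric((1 - alpha) * (tT %*% p)) + alpha * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < epsilon) {
      names(p) <- names(p0)
      return(list(p = p, n_iter = t))
    }
  }
  stop("restart walk did not converge in ", max_iter,
       " iterations (final L1 residual ", format(res), ")")
}

#' Random walk with restart
#'
#' Iterates `P(t+1) = (1 - alpha) * T' P(t) + alpha * P0` until the L1
#' change per step drops below `epsilon`, where `T'` is the transpose of
#' the row-stochastic transition matrix (the standard column-action form:
#' probability mass flows along transitions). The fixed point is unique
#' for `alpha > 0` and independent of the starting vector; the iteration
#' starts at `P0`, which only affects the step count. With a stochastic
#' `T` the residual contracts at least geometrically at rate `1 - alpha`,
#' so convergence is guaranteed well inside the default cap.
#'
#' @param T a `transition_matrix` from [build_transition()].
#' @param p0 initial/restart distribution of length `n + m`, summing to 1.
#' @param alpha restart probability in (0, 1].
#' @param epsilon L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error reporting
#'   the final residual.
#' @return A list with `p` (the steady-state vector) and `n_iter`.
#' @export
rwr <- function(T, p0, alpha = 0.3, epsilon = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(T, "transition_matrix"))
  nm <- length(T$drug_ids) + length(T$disease_ids)
  if (length(p0) != nm) stop("p0 must have length ", nm)
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("p0 must be a probability vector summing to 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  rwr_core(Matrix::t(T$matrix), p0, alpha, epsilon, max_iter)
}

#' Score one candidate drug-disease pair by the two-pass walk
#'
#' Runs the drug-centric walk seeded at the drug and reads off the steady
#' state probability at the disease node (`drug_centric_prob`), runs the
#' disease-centric walk seeded at the disease and reads off the
#' probability at the drug node (`disease_centric_prob`), and returns
#' their mean as the confidence score. The pair must be a candidate, i.e.
#' not a known association of the (training) network.
#'
#' @param drug_index,disease_index 1-based indices of the pair.
#' @param T a `transition_matrix` built from the same network.
#' @param net the [association_network()] (training edges).
#' @param cfg a [walk_config()].
#' @return A list with `drug_centric_prob`, `disease_centric_prob` and
#'   `mean_prob`.
#' @export
score_pair <- function(drug_index, disease_index, T, net, cfg = walk_config()) {
  if (net$adjacency[drug_index, disease_index] == 1)
    stop("pair (", net$drug_ids[drug_index], ", ",
         net$disease_ids[disease_index],
         ") is a known training association, not a candidate")
  n <- length(net$drug_ids)
  tT <- Matrix::t(T$matrix)
  pc <- rwr_core(tT, initial_drug_centric(drug_index, net, cfg$eta_tradeoff),
                 cfg$alpha_restart, cfg$epsilon, cfg$max_iter)$p
  pd <- rwr_core(tT, initial_disease_centric(disease_index, net, cfg$eta_tradeoff),
                 cfg$alpha_restart, cfg$epsilon, cfg$max_iter)$p
  p_dc <- pc[[n + disease_index]]
  p_cc <- pd[[drug_index]]
  list(drug_centric_prob = p_dc, disease_centric_prob = p_cc,
       mean_prob = two_pass_mean(p_dc, p_cc))
}

#' Score all candidate drug-disease pairs
#'
#' Runs one drug-centric walk per drug and one disease-centric walk per
#' disease (`n + m` walks in total, regardless of how many pairs are
#' scored) and reuses each steady state for every pair it covers. Each
#' candidate pair `(i, j)` is scored by the mean of the drug-centric
#' probability at disease `j` and the disease-centric probability at drug
#' `i`. Known training associations are excluded from the candidate list
#' by default.
#'
#' @param net the [association_network()] (training edges).
#' @param T a `transition_matrix` built from the same network.
#' @param cfg a [walk_config()].
#' @param candidates optional data frame with columns `drug_id`,
#'   `disease_id` restricting the pairs scored; default: every non-edge.
#' @return A data frame of class `score_table` with columns `drug_id`,
#'   `disease_id`, `drug_centric_prob`, `disease_centric_prob`,
#'   `mean_prob`, `rank`, sorted by `mean_prob` descending with
#'   `(drug_id, disease_id)` tie-breaking. The number of walks executed is
#'   recorded in `attr(, "n_walks")`.
#' @export
score_all <- function(net, T, cfg = walk_config(), candidates = NULL) {
  n <- length(net$drug_ids); m <- length(net$disease_ids)
  tT <- Matrix::t(T$matrix)
  # steady states: column j of P_drug is the walk seeded at drug j
  P_drug <- matrix(0, n + m, n)
  for (i in seq_len(n))
    P_drug[, i] <- rwr_core(tT, initial_drug_centric(i, net, cfg$eta_tradeoff),
                            cfg$alpha_restart, cfg$epsilon, cfg$max_iter)$p
  P_dis <- matrix(0, n + m, m)
  for (j in seq_len(m))
    P_dis[, j] <- rwr_core(tT, initial_disease_centric(j, net, cfg$eta_tradeoff),
                           cfg$alpha_restart, cfg$epsilon, cfg$max_iter)$p

  if (is.null(candidates)) {
    idx <- which(net$adjacency == 0, arr.ind = TRUE)
    cand_i <- idx[, 1L]; cand_j <- idx[, 2L]
  } else {
    cand_i <- match(as.character(candidates$drug_id), net$drug_ids)
    cand_j <- match(as.character(candidates$disease_id), net$disease_ids)
    if (anyNA(cand_i) || anyNA(cand_j))
      stop("candidate ids not present in the network")
    known <- net$adjacency[cbind(cand_i, cand_j)] == 1
    if (any(known))
      stop(sum(known), " candidate pair(s) are known training associations")
  }
  p_dc <- P_drug[cbind(n + cand_j, cand_i)]
  p_cc <- P_dis[cbind(cand_i, cand_j)]
  tab <- data.frame(drug_id = net$drug_ids[cand_i],
                    disease_id = net$disease_ids[cand_j],
                    drug_centric_prob = p_dc,
                    disease_centric_prob = p_cc,
                    mean_prob = two_pass_mean(p_dc, p_cc),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean_prob, tab$drug_id, tab$disease_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "n_walks") <- n + m
  class(tab) <- c("score_table", class(tab))
  tab
}

#' Run the full prediction pipeline
#'
#' From raw inputs to ranked candidate indications: builds the fused
#' similarity networks ([build_similarities()]), assembles the transition
#' matrix ([build_transition()]) and scores every candidate pair
#' ([score_all()]).
#'
#' @param net an [association_network()].
#' @param fingerprints,concepts feature matrices (either may be `NULL`,
#'   see [build_similarities()]), or pass precomputed similarity matrices
#'   via `sim_drug` / `sim_disease` instead.
#' @param cfg a [walk_config()].
#' @param sim_drug,sim_disease optional precomputed
#'   [similarity_matrix()] objects overriding the feature-derived fusion.
#' @param candidates optional candidate pair data frame (see [score_all()]).
#' @return A `score_table` (see [score_all()]).
#' @examples
#' fx <- simulate_fixture(12, 10, 2, 0.6, 0.05, 64, 0.1, seed = 7)
#' head(predict_indications(fx$net, fx$fingerprints, fx$concepts), 3)
#' @export
predict_indications <- function(net, fingerprints = NULL, concepts = NULL,
                                cfg = walk_config(), sim_drug = NULL,
                                sim_disease = NULL, candidates = NULL) {
  if (is.null(sim_drug) || is.null(sim_disease)) {
    sims <- build_similarities(net, fingerprints, concepts)
    if (is.null(sim_drug)) sim_drug <- sims$drug
    if (is.null(sim_disease)) sim_disease <- sims$disease
  }
  T <- build_transition(sim_drug, sim_disease, net, cfg$lambda_jump)
  score_all(net, T, cfg, candidates = candidates)
}
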