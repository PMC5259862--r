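#' Assemble the heterogeneous transition matrix
#'
#' Builds the `(n + m) x (n + m)` row-stochastic transition matrix of the
#' drug-disease heterogeneous network, ordered drugs-then-diseases, from
#' the fused similarity networks and the association adjacency `A`. With
#' jumping probability `lambda`, the blocks are defined piecewise:
#'
#' * drug-to-drug: `w_ij / sum_k w_ik` if drug `i` has no associations,
#'   else `(1 - lambda) * w_ij / sum_k w_ik`;
#' * drug-to-disease: `lambda * a_ij / k(c_i)` if `k(c_i) > 0`, else 0;
#' * the disease-side blocks are the duals.
#'
#' So a connected drug splits its mass `(1 - lambda)` over similar drugs
#' and `lambda` over its associated diseases, while a drug with no known
#' indication stays within the drug layer. Setting `lambda = 0` zeroes
#' both cross blocks: the walker can only travel within one node type.
#'
#' Conventions for degenerate rows (documented, switchable where noted):
#' * the similarity diagonal is zeroed before normalization (self-loops
#'   would siphon walk mass; set `zero_diagonal = FALSE` to keep it);
#' * a node with associations but zero similarity row-sum sends its full
#'   mass across the bipartite edges (row rescaled to 1), with a warning;
#' * a node with neither associations nor similarity mass gets an all-zero
#'   row; the walk then leaks mass which the restart term replenishes.
#'
#' @param sim_drug,sim_disease [similarity_matrix()] objects over
#'   `net$drug_ids` / `net$disease_ids`.
#' @param net an [association_network()].
#' @param lambda_jump jumping probability in [0, 1].
#' @param zero_diagonal zero the similarity diagonals before normalizing.
#' @return An object of class `transition_matrix`: list with `drug_ids`,
#'   `disease_ids`, the full `matrix` (drugs first), and `lambda_jump`.
#'   For networks beyond 3000 nodes the matrix is stored sparse
#'   (`Matrix::dgCMatrix`); results are identical.
#' @export
build_transition <- function(sim_drug, sim_disease, net, lambda_jump = 0.8,
                             zero_diagonal = TRUE) {
  stopifnot(inherits(sim_drug, "similarity_matrix"),
            inherits(sim_disease, "similarity_matrix"),
            inherits(net, "association_network"))
  if (!identical(sim_drug$ids, net$drug_ids))
    stop("drug similarity ids do not match the network's drug ids")
  if (!identical(sim_disease$ids, net$disease_ids))
    stop("disease similarity ids do not match the network's disease ids")
  if (lambda_jump < 0 || lambda_jump > 1)
    stop("lambda_jump must lie in [0, 1]")
  A <- net$adjacency
  n <- nrow(A); m <- ncol(A)

  wc <- sim_drug$values
  wd <- sim_disease$values
  if (zero_diagonal) { diag(wc) <- 0; diag(wd) <- 0 }

  blocks <- function(W, deg_assoc, Across) {
    # W: intra-type similarity; deg_assoc: association degree of each row
    # node; Across: cross-block adjacency (rows match W's rows).
    sw <- rowSums(W)
    has_assoc <- deg_assoc > 0
    intra_share <- ifelse(has_assoc, 1 - lambda_jump, 1)
    Tintra <- ifelse(sw > 0, intra_share / sw, 0) * W
    Tcross <- (ifelse(has_assoc, lambda_jump / pmax(deg_assoc, 1), 0)) * Across
    stranded <- has_assoc & sw == 0
    if (any(stranded)) {
      # no intra-type outlet: reroute the (1 - lambda) share across as well
      warning(sum(stranded),
              " node(s) with associations but no similarity mass; ",
              "full transition mass routed to the cross block")
      Tcross[stranded, ] <- Across[stranded, , drop = FALSE] /
        deg_assoc[stranded]
    }
    list(intra = Tintra, cross = Tcross)
  }

  bc <- blocks(wc, drug_degrees(net), A)
  bd <- blocks(wd, disease_degrees(net), t(A))

  full <- rbind(cbind(bc$intra, bc$cross), cbind(bd$cross, bd$intra))
  ids <- c(net$drug_ids, net$disease_ids)
  dimnames(full) <- list(ids, ids)
  if (n + m > 3000) full <- methods::as(full, "CsparseMatrix")
  structure(list(drug_ids = net$drug_ids, disease_ids = net$disease_ids,
                 matrix = full, lambda_jump = lambda_jump),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  n <- length(x$drug_ids); m <- length(x$disease_ids)
  cat(sprintf("Heterogeneous transition matrix: %d drugs + %d diseases, lambda = %g\n",
              n, m, x$lambda_jump))
  invisible(x)
}

#' Check row-stochasticity of a transition matrix
#'
#' Verifies that every row of the full transition matrix sums to 1
#' (connected node) or 0 (isolated node with no similarity mass) within
#' tolerance, and returns the ids of the zero rows.
#'
#' @param T a `transition_matrix` from [build_transition()].
#' @param tol tolerance on the row sums (default 1e-10).
#' @return Invisibly, the character vector of zero-row (absorbing-leak)
#'   node ids. Errors naming the worst row if any row sum is neither 0
#'   nor 1.
#' @export
assert_stochastic <- function(T, tol = 1e-10) {
  stopifnot(inherits(T, "transition_matrix"))
  rs <- Matrix::rowSums(T$matrix)
  ids <- c(T$drug_ids, T$disease_ids)
  dev <- pmin(abs(rs - 1), abs(rs))
  if (any(dev > tol)) {
    worst <- which.max(dev)
    stop("transition matrix is not row-stochastic: row '", ids[worst],
         "' sums to ", format(rs[worst], digits = 12))
  }
  invisible(ids[abs(rs) <= tol])
}
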