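#' Jaccard similarity between binary fingerprint vectors
#'
#' For drugs `i`, `j` with fingerprint vectors `f_i`, `f_j`, the chemical
#' similarity is `|f_i AND f_j| / |f_i OR f_j|` — the number of shared
#' substructure bits over the total number of bits set in either drug. An
#' all-zero fingerprint has no evidence to offer: its similarity to every
#' drug, itself included, is defined as 0 rather than NaN.
#'
#' @param fp a [feature_matrix()] of kind `"fingerprint"`.
#' @return A symmetric [similarity_matrix()] over the fingerprint row ids.
#' @examples
#' fp <- feature_matrix(c("a", "b"), rbind(c(1, 1, 0), c(1, 0, 1)),
#'                      kind = "fingerprint")
#' jaccard_similarity(fp)$values   # off-diagonal 1/3
#' @export
jaccard_similarity <- function(fp) {
  stopifnot(inherits(fp, "feature_matrix"))
  if (fp$kind != "fingerprint") stop("jaccard_similarity needs fingerprints")
  F <- fp$values
  inter <- tcrossprod(F)                       # |f_i AND f_j|
  sizes <- rowSums(F)
  uni <- outer(sizes, sizes, `+`) - inter      # |f_i OR f_j|
  w <- ifelse(uni > 0, inter / uni, 0)
  similarity_matrix(fp$row_ids, w, symmetric = TRUE)
}

#' Cosine similarity between nonnegative concept vectors
#'
#' Similarity between two disease phenotypes represented as nonnegative
#' concept-weight vectors: the cosine of the angle between them. Because
#' all weights are nonnegative the result lies in [0, 1]. A zero vector
#' gets similarity 0 to everything, itself included.
#'
#' @param cv a [feature_matrix()] of kind `"concept"`.
#' @return A symmetric [similarity_matrix()] over the concept row ids.
#' @export
cosine_similarity <- function(cv) {
  stopifnot(inherits(cv, "feature_matrix"))
  if (cv$kind != "concept") stop("cosine_similarity needs concept vectors")
  V <- cv$values
  dots <- tcrossprod(V)
  nrm <- sqrt(rowSums(V^2))
  denom <- outer(nrm, nrm)
  w <- ifelse(denom > 0, dots / denom, 0)
  # clip rounding excursions above 1 (e.g. identical rows)
  w <- pmin(w, 1)
  similarity_matrix(cv$row_ids, w, symmetric = TRUE)
}

#' Bipartite network projection similarity
#'
#' Two-step resource allocation across the drug-disease bipartite network.
#' On the drug side, each drug spreads one unit of resource equally over
#' its associated diseases, and each disease returns its share equally to
#' its associated drugs; `w[i, j]` is the fraction of drug `i`'s unit that
#' ends up at drug `j`:
#' `w[i, j] = (1 / k(c_i)) * sum_l a[i, l] a[j, l] / k(d_l)`,
#' with `k()` the association degrees. The disease side is the dual. The
#' measure is intentionally asymmetric. Rows of connected nodes sum to 1
#' (resource conservation); a node with no associations gets an all-zero
#' row, consistent with "no common neighbor means similarity 0".
#'
#' @param net an [association_network()].
#' @param side `"drug"` or `"disease"`.
#' @return An asymmetric [similarity_matrix()] for the requested side.
#' @export
bipartite_projection <- function(net, side = c("drug", "disease")) {
  side <- match.arg(side)
  A <- net$adjacency
  kc <- rowSums(A)
  kd <- colSums(A)
  inv <- function(k) ifelse(k > 0, 1 / k, 0)
  if (side == "drug") {
    # W = Dc^{-1} A Dd^{-1} A^T
    w <- (inv(kc) * A) %*% (inv(kd) * t(A))
    ids <- net$drug_ids
  } else {
    # W = Dd^{-1} A^T Dc^{-1} A
    w <- (inv(kd) * t(A)) %*% (inv(kc) * A)
    ids <- net$disease_ids
  }
  w <- pmin(pmax(w, 0), 1)
  similarity_matrix(ids, w, symmetric = FALSE)
}

#' Combine two similarity measures by probability disjunction
#'
#' Fuses two similarity matrices over the same nodes as if they were
#' independent probabilities of relatedness: `w = 1 - (1 - w1)(1 - w2)`.
#' The result dominates both inputs and never exceeds their sum; 0 is the
#' neutral element and 1 is absorbing.
#'
#' @param s1,s2 [similarity_matrix()] objects with identical ids in
#'   identical order.
#' @return A [similarity_matrix()]; symmetric only if both inputs are.
#' @export
disjunctive_combine <- function(s1, s2) {
  stopifnot(inherits(s1, "similarity_matrix"), inherits(s2, "similarity_matrix"))
  if (!identical(s1$ids, s2$ids))
    stop("cannot combine similarity matrices with different ids")
  w <- 1 - (1 - s1$values) * (1 - s2$values)
  similarity_matrix(s1$ids, w, symmetric = s1$symmetric && s2$symmetric)
}

#' Build the fused drug-drug and disease-disease similarity networks
#'
#' Convenience wrapper assembling both node-type similarity networks from
#' raw inputs: drug side fuses fingerprint Jaccard with the drug-side
#' bipartite projection; disease side fuses concept cosine with the
#' disease-side projection. Association-derived components must come from
#' training edges only during cross-validation; pass the training network
#' here.
#'
#' @param net an [association_network()] (training edges).
#' @param fingerprints [feature_matrix()] of kind `"fingerprint"` over
#'   `net$drug_ids`, or `NULL` to use the projection alone.
#' @param concepts [feature_matrix()] of kind `"concept"` over
#'   `net$disease_ids`, or `NULL` to use the projection alone.
#' @return A list with `drug` and `disease` [similarity_matrix()] objects.
#' @export
build_similarities <- function(net, fingerprints = NULL, concepts = NULL) {
  proj_c <- bipartite_projection(net, "drug")
  proj_d <- bipartite_projection(net, "disease")
  drug <- if (is.null(fingerprints)) proj_c else {
    if (!identical(fingerprints$row_ids, net$drug_ids))
      stop("fingerprint row ids must match the network's drug ids")
    disjunctive_combine(jaccard_similarity(fingerprints), proj_c)
  }
  disease <- if (is.null(concepts)) proj_d else {
    if (!identical(concepts$row_ids, net$disease_ids))
      stop("concept row ids must match the network's disease ids")
    disjunctive_combine(cosine_similarity(concepts), proj_d)
  }
  list(drug = drug, disease = disease)
}
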