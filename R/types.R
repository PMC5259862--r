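#' Drug-disease association network
#'
#' Container for a bipartite association network between `n` drugs and `m`
#' diseases: the adjacency matrix `A` has `a[i, l] = 1` when drug `i` has a
#' known indication for disease `l` and 0 otherwise. All downstream matrices
#' (similarities, the heterogeneous transition matrix) index nodes in the
#' order stored here.
#'
#' @param drug_ids character vector of unique drug identifiers (length n).
#' @param disease_ids character vector of unique disease identifiers (length m).
#' @param adjacency n x m matrix with entries in \{0, 1\}.
#' @return An object of class `association_network` with elements `drug_ids`,
#'   `disease_ids` and `adjacency` (stored with dimnames).
#' @examples
#' net <- association_network(c("c1", "c2"), c("d1", "d2"),
#'                            rbind(c(1, 1), c(0, 1)))
#' net
#' @export
association_network <- function(drug_ids, disease_ids, adjacency) {
  drug_ids <- as.character(drug_ids)
  disease_ids <- as.character(disease_ids)
  if (length(drug_ids) < 1L || length(disease_ids) < 1L)
    stop("need at least one drug and one disease")
  if (anyDuplicated(drug_ids))
    stop("duplicate drug ids: ", paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  if (anyDuplicated(disease_ids))
    stop("duplicate disease ids: ", paste(unique(disease_ids[duplicated(disease_ids)]), collapse = ", "))
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != length(drug_ids) || ncol(adjacency) != length(disease_ids))
    stop("adjacency must be ", length(drug_ids), " x ", length(disease_ids),
         ", got ", nrow(adjacency), " x ", ncol(adjacency))
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(drug_ids, disease_ids)
  structure(list(drug_ids = drug_ids, disease_ids = disease_ids,
                 adjacency = adjacency),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat("Drug-disease association network\n")
  cat("  drugs:    ", length(x$drug_ids), "\n")
  cat("  diseases: ", length(x$disease_ids), "\n")
  cat("  known associations: ", sum(x$adjacency), "\n")
  invisible(x)
}

#' Feature matrix (chemical fingerprints or phenotype concept weights)
#'
#' Rows are entities (drugs or diseases), columns are feature dimensions.
#' Fingerprint matrices are binary substructure indicators (as emitted by
#' fingerprint software from molecular structures); concept matrices hold
#' nonnegative term weights describing a disease phenotype (MimMiner-style
#' MeSH concept vectors).
#'
#' @param row_ids character vector of unique row identifiers.
#' @param values numeric matrix; binary for `kind = "fingerprint"`,
#'   nonnegative for `kind = "concept"`.
#' @param kind `"fingerprint"` or `"concept"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(row_ids, values, kind = c("fingerprint", "concept")) {
  kind <- match.arg(kind)
  row_ids <- as.character(row_ids)
  if (anyDuplicated(row_ids))
    stop("duplicate row ids: ", paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  values <- as.matrix(values)
  if (nrow(values) != length(row_ids))
    stop("values has ", nrow(values), " rows but ", length(row_ids), " row ids")
  storage.mode(values) <- "double"
  if (kind == "fingerprint" && !all(values %in% c(0, 1)))
    stop("fingerprint entries must be 0 or 1")
  if (kind == "concept" && any(values < 0))
    stop("concept weights must be nonnegative")
  rownames(values) <- row_ids
  structure(list(row_ids = row_ids, values = values, kind = kind),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix (%s): %d x %d\n", x$kind,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Similarity matrix for one node type
#'
#' A labeled square matrix of pairwise similarities in [0, 1] for drugs or
#' diseases. The `symmetric` flag records whether the measure is symmetric:
#' Jaccard and cosine similarities are, the bipartite-projection similarity
#' deliberately is not (resource allocated from i to j generally differs from
#' j to i).
#'
#' @param ids character vector of unique node identifiers.
#' @param values square numeric matrix with entries in [0, 1].
#' @param symmetric logical; if `TRUE` the matrix is checked for symmetry
#'   (tolerance 1e-12).
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(ids, values, symmetric) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids")
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square, got ",
         nrow(values), " x ", ncol(values))
  if (nrow(values) != length(ids))
    stop("matrix dimension does not match id count")
  storage.mode(values) <- "double"
  if (any(values < 0) || any(values > 1))
    stop("similarity values must lie in [0, 1]; range is [",
         min(values), ", ", max(values), "]")
  if (isTRUE(symmetric) && max(abs(values - t(values))) > 1e-12)
    stop("matrix flagged symmetric but is not (max asymmetry ",
         format(max(abs(values - t(values)))), ")")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, symmetric = isTRUE(symmetric)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Similarity matrix: %d nodes, %s\n", length(x$ids),
              if (x$symmetric) "symmetric" else "asymmetric"))
  invisible(x)
}

#' Random-walk configuration
#'
#' Bundles the tunable parameters of the two-pass restart walk.
#' `lambda_jump` is the probability that a walker crosses between the drug
#' and disease layers along a known association; `alpha_restart` is the
#' probability of teleporting back to the seed distribution at each step;
#' `eta_tradeoff` splits the initial probability mass between the seed node
#' and its cross-type associated nodes; `epsilon` is the L1 convergence
#' tolerance of the iteration. Defaults are (0.8, 0.3, 0.4, 1e-10).
#'
#' @param lambda_jump jumping probability, in [0, 1].
#' @param alpha_restart restart probability, in (0, 1].
#' @param eta_tradeoff seed/associate tradeoff, in [0, 1].
#' @param epsilon positive convergence tolerance on the L1 change per step.
#' @param max_iter positive integer iteration cap.
#' @param seed integer seed used by any randomized consumer of the config.
#' @return An object of class `walk_config`.
#' @examples
#' walk_config()                      # the default parameterization
#' walk_config(lambda_jump = 0)       # walker confined to one layer
#' @export
walk_config <- function(lambda_jump = 0.8, alpha_restart = 0.3,
                        eta_tradeoff = 0.4, epsilon = 1e-10,
                        max_iter = 10000L, seed = 1L) {
  if (!is.numeric(lambda_jump) || lambda_jump < 0 || lambda_jump > 1)
    stop("lambda_jump must lie in [0, 1]")
  if (!is.numeric(alpha_restart) || alpha_restart <= 0 || alpha_restart > 1)
    stop("alpha_restart must lie in (0, 1]")
  if (!is.numeric(eta_tradeoff) || eta_tradeoff < 0 || eta_tradeoff > 1)
    stop("eta_tradeoff must lie in [0, 1]")
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be positive")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop("max_iter must be a positive integer")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(lambda_jump = lambda_jump, alpha_restart = alpha_restart,
                 eta_tradeoff = eta_tradeoff, epsilon = epsilon,
                 max_iter = max_iter, seed = seed),
            class = "walk_config")
}

#' @export
print.walk_config <- function(x, ...) {
  cat(sprintf(
    "Walk config: lambda = %g, alpha = %g, eta = %g, epsilon = %g, max_iter = %d, seed = %d\n",
    x$lambda_jump, x$alpha_restart, x$eta_tradeoff, x$epsilon,
    x$max_iter, x$seed))
  invisible(x)
}

# Degree vectors of the bipartite association network.
drug_degrees <- function(net) rowSums(net$adjacency)
disease_degrees <- function(net) colSums(net$adjacency)
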