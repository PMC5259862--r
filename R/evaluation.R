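#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with ties counted one half. Equal to the
#' trapezoidal area under the (FPR, TPR) curve.
#'
#' @param scores numeric prediction scores (larger = more confident).
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return A list with `auc` and `roc_points`, a data frame of
#'   `(threshold, fpr, tpr)` rows ordered from the strictest cutoff.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc   # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc needs both classes present (got ", n1, " positives, ",
         n0, " negatives)")
  r <- rank(scores)                      # average ranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)      # last index of each tied score group
  tp <- cumsum(l)[grp_end]; fp <- (seq_along(l) - cumsum(l))[grp_end]
  roc <- data.frame(threshold = s[grp_end], fpr = fp / n0, tpr = tp / n1)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  list(auc = auc, roc_points = roc)
}

#' Count held-out associations recovered within top-rank thresholds
#'
#' For each query (by default each disease), candidate partners are ranked
#' by the chosen score, and a held-out true association counts as
#' correctly predicted at threshold `t` if its rank is at or above `t`
#' (rank <= t, inclusive boundary). Counts are reported per threshold and
#' are nondecreasing in the threshold.
#'
#' @param score_table a `score_table` (see [score_all()]) holding the
#'   candidate scores of one evaluation run.
#' @param test_edges data frame with columns `drug_id`, `disease_id`: the
#'   held-out true associations (each must appear in `score_table`).
#' @param thresholds integer vector of top-rank cutoffs.
#' @param by ranking universe: `"disease"` ranks candidate drugs within
#'   each disease (default, matching case-study style queries), `"drug"`
#'   ranks candidate diseases within each drug.
#' @param score which score column to rank by.
#' @return Named integer vector: count of recovered test edges per
#'   threshold.
#' @export
hits_at_thresholds <- function(score_table, test_edges,
                               thresholds = c(1, 10, 20, 50, 100),
                               by = c("disease", "drug"),
                               score = c("mean_prob", "drug_centric_prob",
                                         "disease_centric_prob")) {
  by <- match.arg(by)
  score <- match.arg(score)
  if (any(thresholds < 1)) stop("thresholds must be >= 1")
  qcol <- if (by == "disease") "disease_id" else "drug_id"
  ccol <- if (by == "disease") "drug_id" else "disease_id"
  s <- score_table[[score]]
  # rank within query: score descending, candidate id ascending on ties
  ord <- order(score_table[[qcol]], -s, score_table[[ccol]])
  qsorted <- score_table[[qcol]][ord]
  within_rank <- integer(length(ord))
  within_rank[ord] <- stats::ave(seq_along(ord), qsorted, FUN = seq_along)

  key <- paste(score_table$drug_id, score_table$disease_id, sep = "\r")
  tkey <- paste(as.character(test_edges$drug_id),
                as.character(test_edges$disease_id), sep = "\r")
  pos <- match(tkey, key)
  if (anyNA(pos))
    stop(sum(is.na(pos)), " test edge(s) missing from the score table")
  tranks <- within_rank[pos]
  counts <- vapply(thresholds, function(t) sum(tranks <= t), integer(1))
  names(counts) <- as.character(thresholds)
  counts
}

# Partition the known edges into n_folds test sets with sizes differing by
# at most one; returns the edge index matrix and fold labels.
make_folds <- function(net, n_folds, seed) {
  edges <- which(net$adjacency == 1, arr.ind = TRUE)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  n_edges <- nrow(edges)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (n_folds > n_edges)
    stop("n_folds (", n_folds, ") exceeds the number of known associations (",
         n_edges, ")")
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n_edges)))
  list(edges = edges, fold = fold)
}

# Score one fold: hide the test edges, rebuild the association-derived
# similarities and the transition matrix from the training edges only,
# and score every candidate pair of the training network (the hidden test
# edges are candidates by construction).
score_fold <- function(net, fingerprints, concepts, test_idx, cfg, edges) {
  A_train <- net$adjacency
  A_train[edges[test_idx, , drop = FALSE]] <- 0
  if (sum(A_train) == 0) stop("fold leaves an empty training network")
  train_net <- association_network(net$drug_ids, net$disease_ids, A_train)
  sims <- build_similarities(train_net, fingerprints, concepts)
  T <- build_transition(sims$drug, sims$disease, train_net, cfg$lambda_jump)
  list(scores = score_all(train_net, T, cfg),
       test_edges = data.frame(
         drug_id = net$drug_ids[edges[test_idx, 1L]],
         disease_id = net$disease_ids[edges[test_idx, 2L]],
         stringsAsFactors = FALSE))
}

# Metrics for one scored fold under a given score column.
fold_metrics <- function(fold_out, thresholds, score, hits_by) {
  st <- fold_out$scores
  key <- paste(st$drug_id, st$disease_id, sep = "\r")
  tkey <- paste(fold_out$test_edges$drug_id, fold_out$test_edges$disease_id,
                sep = "\r")
  labels <- as.integer(key %in% tkey)
  ra <- roc_auc(st[[score]], labels)
  list(auc = ra$auc, scores = st[[score]], labels = labels,
       hits = hits_at_thresholds(st, fold_out$test_edges, thresholds,
                                 by = hits_by, score = score))
}

cv_result <- function(fold_outputs, assignments, thresholds, score, hits_by) {
  per_fold <- lapply(fold_outputs, fold_metrics, thresholds = thresholds,
                     score = score, hits_by = hits_by)
  pooled <- roc_auc(unlist(lapply(per_fold, `[[`, "scores")),
                    unlist(lapply(per_fold, `[[`, "labels")))
  hits <- Reduce(`+`, lapply(per_fold, `[[`, "hits"))
  structure(list(score = score,
                 fold_assignments = assignments,
                 fold_auc = vapply(per_fold, `[[`, numeric(1), "auc"),
                 mean_auc = mean(vapply(per_fold, `[[`, numeric(1), "auc")),
                 pooled_auc = pooled$auc,
                 roc_points = pooled$roc_points,
                 hits_at = hits,
                 thresholds = thresholds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", length(x$fold_auc), x$score))
  cat(sprintf("  pooled AUC:    %.4f\n", x$pooled_auc))
  cat(sprintf("  mean fold AUC: %.4f\n", x$mean_auc))
  cat("  hits at top", paste(x$thresholds, collapse = "/"), ":",
      paste(x$hits_at, collapse = "/"), "\n")
  invisible(x)
}

#' Cross-validated ranking performance
#'
#' Splits the known drug-disease associations at random into `n_folds`
#' test sets of near-equal size. For each fold the test edges are hidden,
#' the association-derived similarity components and the transition matrix
#' are rebuilt from the remaining training edges only (no leakage), and
#' all candidate pairs of the training network are scored; the hidden
#' edges are the positives among them. Reported are per-fold and pooled
#' AUC (candidates of all folds pooled for the headline curve), the mean
#' fold AUC, and top-rank hit counts summed over folds.
#'
#' @param net an [association_network()] of all known associations.
#' @param fingerprints,concepts feature matrices (may be `NULL`; see
#'   [build_similarities()]).
#' @param cfg a [walk_config()].
#' @param n_folds number of folds (default 10); `n_folds` equal to the
#'   edge count gives leave-one-out.
#' @param seed integer seed for the fold split (default `cfg$seed`).
#' @param thresholds top-rank cutoffs for hit counting.
#' @param hits_by ranking universe for hits (see [hits_at_thresholds()]).
#' @return A `cv_result`: fold assignments, `fold_auc`, `mean_auc`,
#'   `pooled_auc`, pooled `roc_points`, and `hits_at` counts.
#' @export
cross_validate <- function(net, fingerprints = NULL, concepts = NULL,
                           cfg = walk_config(), n_folds = 10L,
                           seed = cfg$seed,
                           thresholds = c(1, 10, 20, 50, 100),
                           hits_by = "disease") {
  folds <- make_folds(net, n_folds, seed)
  outs <- lapply(seq_len(n_folds), function(k)
    score_fold(net, fingerprints, concepts, which(folds$fold == k), cfg,
               folds$edges))
  assignments <- data.frame(drug_id = net$drug_ids[folds$edges[, 1L]],
                            disease_id = net$disease_ids[folds$edges[, 2L]],
                            fold = folds$fold, stringsAsFactors = FALSE)
  cv_result(outs, assignments, thresholds, "mean_prob", hits_by)
}

#' Compare two-pass scoring against each single pass
#'
#' Runs one cross-validation (identical folds and identical walks for all
#' three variants) and evaluates the ranking three ways: by the two-pass
#' mean probability, by the drug-centric probability alone, and by the
#' disease-centric probability alone. The two single passes are asymmetric
#' label propagations carrying complementary information; averaging them
#' is what the two-pass scheme contributes.
#'
#' @inheritParams cross_validate
#' @return A list of three `cv_result`s: `two_pass`, `drug_centric`,
#'   `disease_centric`.
#' @export
compare_passes <- function(net, fingerprints = NULL, concepts = NULL,
                           cfg = walk_config(), n_folds = 10L,
                           seed = cfg$seed,
                           thresholds = c(1, 10, 20, 50, 100),
                           hits_by = "disease") {
  folds <- make_folds(net, n_folds, seed)
  outs <- lapply(seq_len(n_folds), function(k)
    score_fold(net, fingerprints, concepts, which(folds$fold == k), cfg,
               folds$edges))
  assignments <- data.frame(drug_id = net$drug_ids[folds$edges[, 1L]],
                            disease_id = net$disease_ids[folds$edges[, 2L]],
                            fold = folds$fold, stringsAsFactors = FALSE)
  list(two_pass = cv_result(outs, assignments, thresholds, "mean_prob", hits_by),
       drug_centric = cv_result(outs, assignments, thresholds,
                                "drug_centric_prob", hits_by),
       disease_centric = cv_result(outs, assignments, thresholds,
                                   "disease_centric_prob", hits_by))
}
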