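#' Read a drug-disease association edge list
#'
#' Reads a two-column delimited text file (`drug_id<sep>disease_id`) into an
#' [association_network()]. Node order is first-appearance order in the
#' file, so the adjacency matrix is reproducible from the same input.
#' Duplicate edges collapse to a single association (the adjacency is
#' binary) with a warning reporting how many were dropped.
#'
#' @param path path to the edge-list file.
#' @param sep field separator (default tab).
#' @param header `NA` (default) auto-detects a `drug_id/disease_id` header
#'   line; `TRUE`/`FALSE` force the choice.
#' @param comment_char lines starting with this character are skipped.
#' @return An [association_network()].
#' @export
read_associations <- function(path, sep = "\t", header = NA,
                              comment_char = "#") {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), comment_char) & nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty association file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad))
    stop("malformed line ", line_no[bad[1L]], " in ", path,
         ": expected 2 fields, got ", length(fields[[bad[1L]]]))
  tab <- data.frame(drug_id = trimws(vapply(fields, `[`, "", 1L)),
                    disease_id = trimws(vapply(fields, `[`, "", 2L)))
  if (is.na(header))
    header <- identical(tolower(unlist(tab[1L, ])),
                        c(drug_id = "drug_id", disease_id = "disease_id"))
  if (header) {
    if (nrow(tab) == 1L) stop("association file has a header but no edges")
    line_no <- line_no[-1L]
    tab <- tab[-1L, , drop = FALSE]
  }
  blank <- which(!nzchar(tab$drug_id) | !nzchar(tab$disease_id))
  if (length(blank))
    stop("malformed line ", line_no[blank[1L]], " in ", path,
         ": empty identifier")
  dup <- duplicated(tab)
  if (any(dup)) {
    warning(sum(dup), " duplicate association line(s) collapsed")
    tab <- tab[!dup, , drop = FALSE]
  }
  drugs <- unique(tab$drug_id)
  diseases <- unique(tab$disease_id)
  A <- matrix(0, length(drugs), length(diseases))
  A[cbind(match(tab$drug_id, drugs), match(tab$disease_id, diseases))] <- 1
  association_network(drugs, diseases, A)
}

#' Write an association network as an edge list
#'
#' Inverse of [read_associations()] (up to node order): one line per known
#' association, `drug_id<TAB>disease_id`, with a header.
#'
#' @param net an [association_network()].
#' @param path output path.
#' @export
write_associations <- function(net, path) {
  idx <- which(net$adjacency == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tab <- data.frame(drug_id = net$drug_ids[idx[, 1L]],
                    disease_id = net$disease_ids[idx[, 2L]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled matrix (fingerprints, concept weights, or similarities)
#'
#' Reads a tab-delimited matrix with one header row of column labels (the
#' corner cell is ignored) and row labels in the first column. The `kind`
#' argument selects validation: `fingerprint` requires binary entries,
#' `concept` nonnegative entries, `similarity` a square matrix with entries
#' in [0, 1]. The label `"."` is rejected (reserved / too easily produced
#' by accident).
#'
#' @param path path to the matrix file.
#' @param kind `"fingerprint"`, `"concept"` or `"similarity"`.
#' @param symmetric for `kind = "similarity"`: `NA` (default) detects
#'   symmetry at tolerance 1e-12; `TRUE` enforces it.
#' @return A [feature_matrix()] or, for `kind = "similarity"`, a
#'   [similarity_matrix()].
#' @export
read_matrix <- function(path, kind = c("fingerprint", "concept", "similarity"),
                        symmetric = NA) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("matrix file needs a label column and data: ", path)
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric matrix entries in ", path)
  if ("." %in% c(ids, colnames(vals)))
    stop("'.' is not allowed as a row or column label")
  if (kind == "similarity") {
    if (nrow(vals) != ncol(vals))
      stop("similarity matrix must be square, got ",
           nrow(vals), " x ", ncol(vals))
    if (!identical(ids, colnames(vals)))
      stop("similarity row labels do not match column labels")
    if (is.na(symmetric))
      symmetric <- max(abs(vals - t(vals))) <= 1e-12
    return(similarity_matrix(ids, vals, symmetric = symmetric))
  }
  feature_matrix(ids, vals, kind = kind)
}

#' Write a similarity matrix as labeled TSV
#'
#' @param sim a [similarity_matrix()].
#' @param path output path.
#' @param corner label written in the corner cell (default `"id"`).
#' @export
write_matrix <- function(sim, path, corner = "id") {
  vals <- if (inherits(sim, "similarity_matrix") ||
              inherits(sim, "feature_matrix")) sim$values else as.matrix(sim)
  df <- data.frame(rownames(vals), vals, check.names = FALSE)
  colnames(df)[1L] <- corner
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score table
#'
#' Writes the ranked candidate scores as TSV with columns `drug_id`,
#' `disease_id`, `drug_centric_prob`, `disease_centric_prob`, `mean_prob`,
#' `rank`, sorted by `mean_prob` descending with deterministic
#' `(drug_id, disease_id)` tie-breaking. Probabilities are printed with 10
#' significant digits so a write/read cycle is lossless at that precision.
#'
#' @param table a `score_table` as returned by [score_all()].
#' @param path output path.
#' @export
write_scores <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("score table must be a nonempty data frame")
  need <- c("drug_id", "disease_id", "drug_centric_prob",
            "disease_centric_prob", "mean_prob", "rank")
  if (!all(need %in% names(table)))
    stop("score table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  tab <- table[order(-table$mean_prob, table$drug_id, table$disease_id), need]
  for (col in c("drug_centric_prob", "disease_centric_prob", "mean_prob"))
    tab[[col]] <- sprintf("%.10g", tab[[col]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path path to the scores TSV.
#' @return A data frame of class `score_table`.
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(drug_id = "character",
                                          disease_id = "character"))
  class(tab) <- c("score_table", class(tab))
  tab
}
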