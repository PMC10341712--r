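#' Construct a labeled feature matrix
#'
#' The working container of the package: an `n x m` numeric matrix of
#' encoded peptides (rows = samples, columns = amino-acid index accessions)
#' with a binary label per row (1 = anticancer peptide, 0 = non-ACP).
#'
#' @param x Numeric matrix with sample ids as rownames and feature
#'   accessions as colnames.
#' @param y Integer/numeric vector of 0/1 labels, one per row of `x`.
#' @return An object of class `acp_features`.
#' @export
feature_matrix <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("one label per row required")
  if (nrow(x) < 1L) stop("feature matrix must contain at least one sample")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (is.null(colnames(x))) stop("feature matrix requires accession colnames")
  if (anyDuplicated(colnames(x))) stop("duplicate feature accession")
  if (anyNA(x)) stop("feature matrix must not contain NA values")
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  structure(list(x = x, y = y), class = "acp_features")
}

#' @export
print.acp_features <- function(x, ...) {
  cat("acp_features:", nrow(x$x), "samples x", ncol(x$x), "features;",
      sum(x$y == 1L), "positive /", sum(x$y == 0L), "negative\n")
  invisible(x)
}

#' @export
dim.acp_features <- function(x) dim(x$x)

# Resolve an index table to the usable value matrix under an NA policy:
# drop_entry removes entries containing any NA; entry_mean imputes each NA
# with the mean of that entry's non-NA residue values.
usable_index_values <- function(table, na_policy = c("drop_entry", "entry_mean")) {
  na_policy <- match.arg(na_policy)
  v <- table$values
  has_na <- rowSums(is.na(v)) > 0L
  if (na_policy == "drop_entry") {
    v <- v[!has_na, , drop = FALSE]
    if (nrow(v) == 0L) stop("all index entries contain NA values; nothing to encode")
  } else if (any(has_na)) {
    for (r in which(has_na)) {
      miss <- is.na(v[r, ])
      if (all(miss)) stop("entry ", rownames(v)[r], " has no finite values")
      v[r, miss] <- mean(v[r, !miss])
    }
  }
  v
}

# residue composition (relative frequency) matrix, n x 20
residue_frequencies <- function(sequences) {
  res <- aaindex_residues()
  freq <- t(vapply(strsplit(sequences, "", fixed = TRUE), function(ch) {
    idx <- match(ch, res)
    if (anyNA(idx)) {
      stop("residue '", ch[is.na(idx)][1L],
           "' not covered by the index table; validate sequences first")
    }
    tabulate(idx, nbins = 20L) / length(ch)
  }, numeric(20L)))
  colnames(freq) <- res
  freq
}

#' Encode one peptide as a physicochemical feature vector
#'
#' Looks up each residue's value in every usable amino-acid index entry
#' and average-pools over the sequence: entry `j` contributes
#' `mean_i value_j(residue_i)`, i.e. the composition-weighted mean of the
#' entry's residue values. A length-`L` peptide against an `m`-entry table
#' therefore yields a length-`m` vector regardless of `L`.
#'
#' @param sequence Validated peptide sequence (see [validate_sequence()]).
#' @param table An [aaindex_table()].
#' @param na_policy How entries with missing residue values are handled:
#'   `"drop_entry"` (default) removes them from the feature space;
#'   `"entry_mean"` imputes the missing residue with the entry's mean.
#' @return Named numeric vector (names = retained accessions), never NA.
#' @export
encode_peptide <- function(sequence, table, na_policy = c("drop_entry", "entry_mean")) {
  stopifnot(inherits(table, "aaindex_table"))
  v <- usable_index_values(table, na_policy)
  freq <- residue_frequencies(sequence)
  drop(freq %*% t(v))[rownames(v)]
}

#' Encode a labeled peptide set as a feature matrix
#'
#' Batch form of [encode_peptide()]: row `i` is the encoding of record
#' `i`, rows keep input order, and all rows share the same retained
#' feature accessions.
#'
#' @param records data.frame with columns `id` and `sequence`
#'   (as returned by [read_fasta()] or [make_labeled_peptides()]).
#' @param labels Binary 0/1 vector aligned with `records`.
#' @inheritParams encode_peptide
#' @return An [feature_matrix()] (`acp_features`).
#' @export
encode_dataset <- function(records, labels, table,
                           na_policy = c("drop_entry", "entry_mean")) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) != length(labels)) stop("one label per record required")
  v <- usable_index_values(table, na_policy)
  freq <- tryCatch(residue_frequencies(records$sequence), error = function(e) {
    stop("encoding failed: ", conditionMessage(e))
  })
  x <- freq %*% t(v)
  rownames(x) <- make.unique(records$id)
  feature_matrix(x, labels)
}

#' Subset a feature matrix to a given accession list
#'
#' Columns are subset and reordered to `accessions`; labels are unchanged.
#' Used to evaluate models on a previously selected feature set.
#'
#' @param fm An `acp_features` object.
#' @param accessions Character vector, a subset of `colnames(fm$x)`.
#' @return An `acp_features` with `length(accessions)` columns in the
#'   requested order.
#' @export
restrict_features <- function(fm, accessions) {
  stopifnot(inherits(fm, "acp_features"))
  missing <- setdiff(accessions, colnames(fm$x))
  if (length(missing)) {
    stop("unknown feature accession: ", paste(missing, collapse = ", "))
  }
  feature_matrix(fm$x[, accessions, drop = FALSE], fm$y)
}

#' Write a feature matrix as tab-separated values
#'
#' Layout: `sample_id`, `label`, then one column per accession in matrix
#' order. [read_feature_tsv()] inverts it.
#'
#' @param fm An `acp_features` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_tsv <- function(fm, path) {
  stopifnot(inherits(fm, "acp_features"))
  df <- data.frame(sample_id = rownames(fm$x), label = fm$y,
                   fm$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$sample_id
  feature_matrix(x, df$label)
}
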