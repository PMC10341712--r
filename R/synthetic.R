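#' Generate a synthetic amino-acid index table
#'
#' Emulates the structure of the AAindex1 library: `m` entries with
#' synthetic accessions, residue values drawn i.i.d. standard normal, and
#' a chosen fraction of entries carrying one missing residue value (the
#' public release also contains NA entries). Deterministic per seed; the
#' serialized form (see [write_aaindex()]) is byte-identical across runs
#' with the same arguments.
#'
#' @param m Number of entries (the real library has 566).
#' @param na_fraction Fraction of entries given exactly one NA residue
#'   (`round(m * na_fraction)` entries).
#' @param seed RNG seed.
#' @return An [aaindex_table()].
#' @export
make_index_table <- function(m, na_fraction = 0, seed = 1) {
  stopifnot(m >= 1, na_fraction >= 0, na_fraction < 1)
  set.seed(seed)
  vals <- matrix(stats::rnorm(m * 20L), m, 20L,
                 dimnames = list(NULL, aaindex_residues()))
  n_na <- round(m * na_fraction)
  if (n_na > 0L) {
    rows <- sample.int(m, n_na)
    cols <- sample.int(20L, n_na, replace = TRUE)
    vals[cbind(rows, cols)] <- NA_real_
  }
  acc <- sprintf("SYN%07d", seq_len(m))
  aaindex_table(acc, paste("Synthetic amino-acid index", seq_len(m)), vals,
                source = sprintf("synthetic (m=%d, na_fraction=%g, seed=%d)",
                                 m, na_fraction, seed))
}

#' Generate labeled peptides with a planted class signal
#'
#' Negative peptides sample residues uniformly; positive peptides sample
#' residues from `softmax(delta * s)`, where `s` is the per-residue mean
#' of the standardized values of the planted index entries. The expected
#' class difference of the encoded features is therefore non-zero exactly
#' along the planted entries (and entries residue-correlated with them,
#' as in real index libraries), and `delta = 0` makes the classes
#' exchangeable. Lengths are uniform on `length_range`.
#'
#' @param table An [aaindex_table()] (planted entries must be NA-free).
#' @param planted Character vector of accessions carrying the signal
#'   (empty for a pure-null set).
#' @param delta Effect size `>= 0`: log-odds tilt of positive-class
#'   residue sampling.
#' @param n_pos,n_neg Positive / negative sample counts.
#' @param length_range Integer `c(Lmin, Lmax)`, `Lmin >= 2`; default 5-50,
#'   the typical benchmark peptide length range.
#' @param seed RNG seed.
#' @return List: `records` (data.frame `id`, `sequence`, `length`) and
#'   `labels` (0/1 vector), positives first.
#' @export
make_labeled_peptides <- function(table, planted = character(), delta = 0,
                                  n_pos = 200, n_neg = 200,
                                  length_range = c(5L, 50L), seed = 1) {
  stopifnot(inherits(table, "aaindex_table"), delta >= 0,
            n_pos >= 1, n_neg >= 1, length(length_range) == 2L,
            length_range[1L] >= 2L, length_range[1L] <= length_range[2L])
  missing <- setdiff(planted, table$accession)
  if (length(missing)) {
    stop("planted accession absent from table: ", paste(missing, collapse = ", "))
  }
  res <- aaindex_residues()
  if (length(planted) && delta > 0) {
    v <- table$values[planted, , drop = FALSE]
    if (anyNA(v)) stop("planted entries must be NA-free")
    z <- t(apply(v, 1L, function(row) (row - mean(row)) / stats::sd(row)))
    s <- colMeans(z)
    w <- exp(delta * s)
    p_pos <- w / sum(w)
  } else {
    p_pos <- rep(1 / 20, 20L)
  }
  p_neg <- rep(1 / 20, 20L)
  set.seed(seed)
  n <- n_pos + n_neg
  lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  seqs <- vapply(seq_len(n), function(i) {
    p <- if (labels[i] == 1L) p_pos else p_neg
    paste(sample(res, lens[i], replace = TRUE, prob = p), collapse = "")
  }, character(1))
  ids <- sprintf("%s%04d", ifelse(labels == 1L, "ACP", "NEG"),
                 unlist(lapply(c(n_pos, n_neg), seq_len)))
  list(records = data.frame(id = ids, sequence = seqs, length = lens,
                            stringsAsFactors = FALSE),
       labels = labels)
}

#' Write a train/test benchmark bundle to disk
#'
#' Mirrors the usual benchmark layout: `train_pos.fasta`,
#' `train_neg.fasta`, optional `test_pos.fasta` / `test_neg.fasta`, plus a
#' `manifest.json` recording counts and the observed length range.
#'
#' @param records,labels Training peptides (as from
#'   [make_labeled_peptides()]).
#' @param dir Output directory (created if needed).
#' @param test_records,test_labels Optional independent test split.
#' @return The manifest, invisibly (also written as JSON).
#' @export
write_benchmark_bundle <- function(records, labels, dir,
                                   test_records = NULL, test_labels = NULL) {
  stopifnot(is.data.frame(records), nrow(records) == length(labels))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  split_write <- function(recs, labs, prefix) {
    pos <- labs == 1L
    if (any(pos)) write_fasta(recs$id[pos], recs$sequence[pos],
                              file.path(dir, paste0(prefix, "_pos.fasta")))
    if (any(!pos)) write_fasta(recs$id[!pos], recs$sequence[!pos],
                               file.path(dir, paste0(prefix, "_neg.fasta")))
    c(pos = sum(pos), neg = sum(!pos))
  }
  train_counts <- split_write(records, labels, "train")
  test_counts <- c(pos = 0L, neg = 0L)
  all_len <- nchar(records$sequence)
  if (!is.null(test_records)) {
    stopifnot(nrow(test_records) == length(test_labels))
    test_counts <- split_write(test_records, test_labels, "test")
    all_len <- c(all_len, nchar(test_records$sequence))
  }
  manifest <- list(
    train_acp = unname(train_counts["pos"]),
    train_non_acp = unname(train_counts["neg"]),
    test_acp = unname(test_counts["pos"]),
    test_non_acp = unname(test_counts["neg"]),
    length_min = min(all_len), length_max = max(all_len)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate several synthetic benchmark datasets sharing one planted set
#'
#' Convenience wrapper for pipeline validation: builds one index table
#' and `n_datasets` independently sampled labeled peptide sets that share
#' the same planted signal, each already encoded as an `acp_features`.
#'
#' @inheritParams make_labeled_peptides
#' @param n_datasets Number of datasets.
#' @param m Index-table size.
#' @param n_planted Number of planted entries (taken as the first
#'   NA-free accessions).
#' @param na_fraction Passed to [make_index_table()].
#' @return List: `table`, `planted`, `datasets` (named list of
#'   `acp_features`).
#' @export
make_benchmark_suite <- function(n_datasets = 4, m = 60, n_planted = 3,
                                 delta = 1.5, n_pos = 200, n_neg = 200,
                                 length_range = c(5L, 50L),
                                 na_fraction = 0, seed = 1) {
  table <- make_index_table(m, na_fraction = na_fraction, seed = seed)
  ok <- table$accession[rowSums(is.na(table$values)) == 0L]
  stopifnot(length(ok) >= n_planted)
  planted <- ok[seq_len(n_planted)]
  datasets <- lapply(seq_len(n_datasets), function(i) {
    ds <- make_labeled_peptides(table, planted = planted, delta = delta,
                                n_pos = n_pos, n_neg = n_neg,
                                length_range = length_range,
                                seed = seed + 7919L * i)
    encode_dataset(ds$records, ds$labels, table)
  })
  names(datasets) <- paste0("synth", seq_len(n_datasets))
  list(table = table, planted = planted, datasets = datasets)
}
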