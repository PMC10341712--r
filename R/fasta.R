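#' Read peptide sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]: sequences are
#' uppercased, line wrapping is removed, and record order is preserved.
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path Path to a plain FASTA file.
#' @return A data.frame with columns `id`, `sequence` and `length`, one row
#'   per record in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence under header '", ids[!nzchar(seqs)][1L], "'")
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             length = nchar(unname(seqs)), stringsAsFactors = FALSE)
}

#' Write peptide sequences to a FASTA file
#'
#' @param ids Character vector of record identifiers.
#' @param sequences Character vector of amino-acid sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  set <- Biostrings::AAStringSet(sequences)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Canonicalize and validate a peptide sequence
#'
#' Uppercases the input and checks it against the 20-letter standard
#' amino-acid alphabet. Under `strict` any non-standard residue (B, J, O,
#' U, X, Z, gaps, ...) is an error naming its position; under
#' `drop_nonstandard` such residues are removed with a warning. Residue
#' dropping changes the average-pooled encoding, so `strict` is the
#' default.
#'
#' @param raw Non-empty sequence string.
#' @param policy `"strict"` or `"drop_nonstandard"`.
#' @return The canonical (uppercase, standard-alphabet) sequence.
#' @export
validate_sequence <- function(raw, policy = c("strict", "drop_nonstandard")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    stop("sequence must be a single non-empty string")
  }
  s <- toupper(raw)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% aaindex_residues())
  if (!any(bad)) return(s)
  if (policy == "strict") {
    stop("non-standard residue '", chars[bad][1L], "' at position ",
         which(bad)[1L])
  }
  warning("dropped ", sum(bad), " non-standard residue(s)")
  out <- paste(chars[!bad], collapse = "")
  if (!nzchar(out)) stop("sequence empty after dropping non-standard residues")
  out
}
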