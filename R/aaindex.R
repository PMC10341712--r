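#' Canonical AAindex1 residue order
#'
#' The fixed residue order of the two numeric rows following an AAindex1
#' `I` line: A R N D C Q E G H I on the first row, L K M F P S T W Y V on
#' the second.
#'
#' @return Character vector of the 20 standard one-letter residue codes.
#' @export
aaindex_residues <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Construct an amino-acid index table
#'
#' An index table holds one row per amino-acid index entry: an accession,
#' a free-text description, and a numeric value per standard residue
#' (possibly `NA`, as in the public AAindex1 release).
#'
#' @param accession Character vector of unique, non-empty accessions.
#' @param description Character vector of descriptions (recycled if length 1).
#' @param values Numeric matrix, one row per entry, 20 columns named by
#'   [aaindex_residues()] (any column order is accepted and canonicalized).
#' @param extras Optional list (one element per entry) of character vectors
#'   holding the other record lines (R/A/T/J/C ...) carried as opaque text.
#' @param source Provenance string recorded on the table.
#'
#' @return An object of class `aaindex_table`.
#' @export
aaindex_table <- function(accession, description, values,
                          extras = NULL, source = "constructed") {
  accession <- as.character(accession)
  if (length(accession) == 0L) stop("index table must contain at least one entry")
  if (anyNA(accession) || any(!nzchar(accession))) {
    stop("accessions must be non-empty strings")
  }
  if (anyDuplicated(accession)) {
    stop("duplicate accession: ", accession[duplicated(accession)][1L])
  }
  values <- as.matrix(values)
  if (ncol(values) != 20L) stop("values must have 20 residue columns")
  if (is.null(colnames(values))) {
    colnames(values) <- aaindex_residues()
  } else {
    if (!setequal(colnames(values), aaindex_residues())) {
      stop("values columns must be the 20 standard residues")
    }
    values <- values[, aaindex_residues(), drop = FALSE]
  }
  if (nrow(values) != length(accession)) {
    stop("values must have one row per accession")
  }
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) stop("index values must be finite or NA")
  rownames(values) <- accession
  description <- rep_len(as.character(description), length(accession))
  if (is.null(extras)) extras <- rep(list(character()), length(accession))
  structure(
    list(accession = accession, description = description,
         values = values, extras = extras, source = source),
    class = "aaindex_table"
  )
}

#' @export
length.aaindex_table <- function(x) length(x$accession)

#' @export
print.aaindex_table <- function(x, ...) {
  n_na <- sum(rowSums(is.na(x$values)) > 0L)
  cat("aaindex_table:", length(x), "entries (", n_na, "with NA values )\n")
  cat("  source:", x$source, "\n")
  show <- utils::head(x$accession, 5L)
  cat("  ", paste(show, collapse = ", "),
      if (length(x) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read an AAindex1 flat file
#'
#' Parses the standard multi-record AAindex1 text format: records are
#' terminated by `//`; within a record, `H` carries the accession, `D` the
#' description, and the `I` line is followed by two rows of ten values in
#' the canonical residue order ([aaindex_residues()]). `NA` tokens are kept
#' as missing values. All other line types (R, A, T, J, C, ...) are carried
#' through as opaque text.
#'
#' @param path Path to an AAindex1-format file, or a character vector of
#'   lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#'
#' @return An [aaindex_table()] whose `source` records the path and the
#'   entry count.
#' @export
read_aaindex <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply either `path` or `text`")
    text <- readLines(path, warn = FALSE)
    src <- path
  } else {
    src <- "text"
  }
  # strip trailing whitespace; tolerate missing final newline / blank tail
  text <- sub("[ \t\r]+$", "", text)
  ends <- which(text == "//")
  if (length(ends) == 0L) stop("no AAindex1 records found (missing '//' terminators)")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  acc <- character(length(ends))
  descr <- character(length(ends))
  vals <- matrix(NA_real_, length(ends), 20L,
                 dimnames = list(NULL, aaindex_residues()))
  extras <- vector("list", length(ends))
  for (r in seq_along(ends)) {
    rec <- text[starts[r]:(ends[r] - 1L)]
    rec <- rec[nzchar(rec)]
    tags <- substr(rec, 1L, 1L)
    h <- which(tags == "H")
    i <- which(tags == "I")
    if (length(h) != 1L) stop("record ", r, ": missing or duplicated H line")
    if (length(i) != 1L) stop("record ", r, ": missing or duplicated I line")
    acc[r] <- trimws(substring(rec[h], 2L))
    if (!nzchar(acc[r])) stop("record ", r, ": empty accession on H line")
    d <- which(tags == "D")
    if (length(d) >= 1L) {
      # description may continue on indented lines directly after D
      dl <- d[1L]
      dtxt <- trimws(substring(rec[dl], 2L))
      j <- dl + 1L
      while (j <= length(rec) && tags[j] == " ") {
        dtxt <- paste(dtxt, trimws(rec[j]))
        j <- j + 1L
      }
      descr[r] <- dtxt
    }
    if (i + 2L > length(rec)) stop("record ", r, ": I line not followed by two value rows")
    tok <- unlist(strsplit(trimws(rec[c(i + 1L, i + 2L)]), "[ \t]+"))
    tok <- tok[nzchar(tok)]
    if (length(tok) != 20L) {
      stop("record ", r, " (", acc[r], "): expected 20 values after I line, got ",
           length(tok))
    }
    v <- suppressWarnings(as.numeric(ifelse(tok == "NA", NA, tok)))
    bad <- is.na(v) & tok != "NA"
    if (any(bad)) {
      stop("record ", r, " (", acc[r], "): non-numeric value '", tok[bad][1L], "'")
    }
    vals[r, ] <- v
    keep <- setdiff(seq_along(rec), c(h, i, i + 1L, i + 2L,
                                      if (length(d)) seq(d[1L], by = 1L,
                                                         length.out = 1L)))
    # description continuation lines were folded into descr; drop them too
    if (length(d)) {
      j <- d[1L] + 1L
      while (j <= length(rec) && tags[j] == " " && !(j %in% c(i, i + 1L, i + 2L))) {
        keep <- setdiff(keep, j)
        j <- j + 1L
      }
    }
    extras[[r]] <- rec[sort(keep)]
  }
  if (anyDuplicated(acc)) {
    stop("duplicate accession: ", acc[duplicated(acc)][1L])
  }
  aaindex_table(acc, descr, vals, extras,
                source = sprintf("%s (%d entries)", src, length(acc)))
}

#' Write an index table in AAindex1 layout
#'
#' Emits H/D lines, carried-through extra lines, the `I` header and two
#' ten-value rows per entry, and the `//` terminator. Values are printed
#' with 17 significant digits so a write/read round trip is lossless.
#'
#' @param table An [aaindex_table()].
#' @param path Output file path; omit to return the lines invisibly only.
#' @return Invisibly, the character vector of lines written.
#' @export
write_aaindex <- function(table, path = NULL) {
  stopifnot(inherits(table, "aaindex_table"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- character(0)
  for (r in seq_along(table$accession)) {
    v <- table$values[r, ]
    out <- c(out,
             paste("H", table$accession[r]),
             paste("D", table$description[r]),
             table$extras[[r]],
             "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
             paste0("     ", paste(fmt(v[1:10]), collapse = "  ")),
             paste0("     ", paste(fmt(v[11:20]), collapse = "  ")),
             "//")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
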