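# Hand-written two-record AAindex1-format fixture: first entry is a real
# hydrophobicity-style layout, second carries an NA for tryptophan.
aaindex_fixture_lines <- function() {
  c("H TEST000001",
    "D Synthetic hydropathy-like index for parser tests",
    "R PMID:0000000",
    "A Nobody, A.",
    "T A test record",
    "J None 0:0 (0)",
    "C TEST000002    0.5",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5",
    "     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2",
    "//",
    "H TEST000002",
    "D Second record with one missing residue value",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     0.1     0.2     0.3     0.4     0.5     0.6     0.7     0.8     0.9     1.0",
    "     1.1     1.2     1.3     1.4     1.5     1.6     1.7      NA     1.9     2.0",
    "//")
}

# minimal labeled matrix for scorer unit tests
tiny_fm <- function(x, y) {
  feature_matrix(x, y)
}

# random peptide over the standard alphabet
random_peptide <- function(len) {
  paste(sample(aaindex_residues(), len, replace = TRUE), collapse = "")
}
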