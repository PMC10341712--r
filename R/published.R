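#' The 19 consensus physicochemical key features
#'
#' The packaged result of the two-round cross-dataset consensus selection
#' run on the four public ACP benchmark datasets (ACPred-Fuse, ACPred-FL,
#' ACP20Alt, ACP20main) against the 566-entry AAindex1 library: the 19
#' amino-acid index accessions that survived the `>= 3`-dataset per-method
#' intersection, the union merge, the second gradient-boosting round and
#' the all-dataset Gini-importance filter at 0.01. Shipping them lets
#' prediction restrict a full AAindex1 encoding without re-running
#' selection.
#'
#' @return data.frame with columns `accession` and `property`.
#' @export
acp_key_features <- function() {
  data.frame(
    accession = c(
      "QIAN880113", "QIAN880126", "BROC820102", "RACS820101", "SNEP660103",
      "OOBM850104", "SNEP660104", "FINA910103", "OOBM850101", "RICJ880110",
      "RICJ880112", "CHAM830102", "ZASB820101", "KLEP840101", "FINA910101",
      "MEEJ800101", "WOLS870103", "AURR980112", "KARP850103"
    ),
    property = c(
      "Weights for alpha-helix at the window position of 6",
      "Weights for beta-sheet at the window position of 6",
      "Retention coefficient in HFBA",
      "Average relative fractional occurrence in A0(i)",
      "Principal component III",
      "Optimized average non-bonded energy per atom",
      "Principal component IV",
      "Helix termination parameter at position j-2, j-1, j",
      "Optimized beta-structure-coil equilibrium constant",
      "Relative preference value at C5",
      "Relative preference value at C3",
      paste("A parameter defined from the residuals obtained from the best",
            "correlation of the Chou-Fasman parameter of beta-sheet"),
      "Dependence of partition coefficient on ionic strength",
      "Net charge",
      "Helix initiation parameter at position i-1",
      "Retention coefficient in HPLC, pH 7.4",
      "Principal property value z3",
      "Normalized positional residue frequency at helix termini C4",
      "Flexibility parameter for two rigid neighbors"
    ),
    stringsAsFactors = FALSE
  )
}

#' Published per-dataset benchmark results
#'
#' The printed per-dataset evaluation results used for the averaged
#' model comparison: `"literature"` rows are the best previously
#' published predictor results per benchmark dataset; `"rf105"` and
#' `"rf19"` rows are the AAindex random-forest models on the 105-feature
#' merged pool and the final 19-feature consensus set. AUC cells not
#' reported in the original comparisons are `NA`. These are inputs for
#' [average_metrics()] / [compare_models()], not values the package
#' recomputes.
#'
#' @return A [metric_table()] with models `literature`, `rf105`, `rf19`
#'   over the four benchmark datasets and both protocols.
#' @export
published_benchmarks <- function() {
  ds <- c("ACPred-Fuse", "ACPred-FL", "ACP20Alt", "ACP20main")
  rows <- rbind(
    data.frame(model_id = "literature", dataset_id = ds, protocol = "cv",
               acc = c(82.4, 89.0, 93.0, 76.7),
               mcc = c(0.652, 0.783, 0.861, 0.536),
               sn = c(77.2, 84.8, 89.7, 72.2),
               sp = c(87.6, 93.2, 96.3, 81.1),
               auc = c(0.882, 0.940, 0.978, 0.841)),
    data.frame(model_id = "literature", dataset_id = ds,
               protocol = "independent",
               acc = c(89.0, 87.8, 92.5, 73.4),
               mcc = c(0.320, 0.758, 0.852, 0.468),
               sn = c(72.0, 84.1, 88.6, 76.0),
               sp = c(89.5, 91.5, 96.4, 70.8),
               auc = c(0.868, 0.960, NA, NA)),
    data.frame(model_id = "rf105", dataset_id = ds, protocol = "cv",
               acc = c(80.2, 80.0, 89.7, 74.2),
               mcc = c(0.612, 0.601, 0.794, 0.489),
               sn = c(88.4, 83.2, 89.2, 67.2),
               sp = c(72.0, 76.8, 90.2, 81.2),
               auc = c(0.858, 0.863, 0.960, 0.800)),
    data.frame(model_id = "rf105", dataset_id = ds, protocol = "independent",
               acc = c(92.9, 76.2, 90.9, 69.3),
               mcc = c(0.457, 0.528, 0.819, 0.386),
               sn = c(93.9, 81.7, 89.1, 67.3),
               sp = c(70.7, 70.7, 92.7, 71.3),
               auc = c(0.897, 0.856, 0.960, 0.792)),
    data.frame(model_id = "rf19", dataset_id = ds, protocol = "cv",
               acc = c(78.6, 80.6, 89.3, 71.9),
               mcc = c(0.576, 0.616, 0.786, 0.440),
               sn = c(84.8, 86.0, 89.3, 66.7),
               sp = c(72.4, 75.2, 89.3, 77.0),
               auc = c(0.854, 0.860, 0.958, 0.797)),
    data.frame(model_id = "rf19", dataset_id = ds, protocol = "independent",
               acc = c(93.0, 79.9, 89.4, 70.5),
               mcc = c(0.447, 0.601, 0.791, 0.410),
               sn = c(94.1, 85.4, 85.0, 68.4),
               sp = c(68.3, 74.4, 93.8, 72.5),
               auc = c(0.900, 0.846, 0.952, 0.789))
  )
  metric_table(rows)
}

#' Second-round subset sizes published for the benchmark datasets
#'
#' The per-dataset best subset sizes found by the gradient-boosting sweep
#' on the 105-feature merged pool (ACPred-Fuse 58, ACPred-FL 33,
#' ACP20Alt 61, ACP20main 80), recorded for reference alongside
#' [published_benchmarks()].
#'
#' @return Named integer vector.
#' @export
published_second_round_sizes <- function() {
  c("ACPred-Fuse" = 58L, "ACPred-FL" = 33L, "ACP20Alt" = 61L,
    "ACP20main" = 80L)
}
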