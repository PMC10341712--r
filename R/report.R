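#' Construct a metric table
#'
#' Long-format container for evaluation results: one row per
#' (model, dataset, protocol) with the five metrics as columns. `auc` may
#' be `NA` (published comparisons sometimes omit it).
#'
#' @param df data.frame with columns `model_id`, `dataset_id`, `protocol`
#'   (`"cv"` or `"independent"`), `acc`, `mcc`, `sn`, `sp`, `auc`.
#' @return The validated data.frame with class `metric_table`.
#' @export
metric_table <- function(df) {
  need <- c("model_id", "dataset_id", "protocol", "acc", "mcc", "sn", "sp", "auc")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (!all(df$protocol %in% c("cv", "independent"))) {
    stop("protocol must be 'cv' or 'independent'")
  }
  key <- paste(df$model_id, df$dataset_id, df$protocol)
  if (anyDuplicated(key)) stop("duplicate (model, dataset, protocol) row")
  for (col in c("acc", "sn", "sp")) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) stop(col, " must lie in [0, 100]")
  }
  if (any(!is.na(df$mcc) & abs(df$mcc) > 1)) stop("mcc must lie in [-1, 1]")
  structure(as.data.frame(df[need]), class = c("metric_table", "data.frame"))
}

#' Append a metric-set row to a metric table
#'
#' @param table A `metric_table` (or `NULL` to start one).
#' @param model_id,dataset_id,protocol Row key.
#' @param metrics A `metric_set`.
#' @return The extended `metric_table`.
#' @export
add_metric_row <- function(table, model_id, dataset_id, protocol, metrics) {
  stopifnot(inherits(metrics, "metric_set"))
  row <- data.frame(model_id = model_id, dataset_id = dataset_id,
                    protocol = protocol, acc = metrics$acc, mcc = metrics$mcc,
                    sn = metrics$sn, sp = metrics$sp, auc = metrics$auc,
                    stringsAsFactors = FALSE)
  if (is.null(table)) metric_table(row)
  else metric_table(rbind(as.data.frame(table), row))
}

#' Average a model's metrics across datasets
#'
#' Arithmetic mean of each metric over the model's datasets under one
#' protocol; missing cells (e.g. unreported AUC values) are skipped. Full
#' precision is kept — rounding is a display concern only.
#'
#' @param table A `metric_table`.
#' @param model_id Model to average.
#' @param protocol `"cv"` or `"independent"`.
#' @return A `metric_set` of per-metric means (`auc` is `NA` when no
#'   dataset reports it).
#' @export
average_metrics <- function(table, model_id, protocol) {
  stopifnot(inherits(table, "metric_table"))
  rows <- table[table$model_id == model_id & table$protocol == protocol, ]
  if (nrow(rows) == 0L) stop("no rows for model '", model_id,
                             "' under protocol '", protocol, "'")
  avg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(list(acc = avg(rows$acc), mcc = avg(rows$mcc),
                 sn = avg(rows$sn), sp = avg(rows$sp), auc = avg(rows$auc)),
            class = "metric_set")
}

#' Paired significance test between two models across datasets
#'
#' For each metric, the two models' per-dataset values are paired on
#' shared datasets and compared two-sidedly: a paired t-test by default,
#' or the Wilcoxon signed-rank test. Degenerate pairings (all differences
#' zero, e.g. a model against itself) return p = 1.
#'
#' @param table A `metric_table`.
#' @param model_a,model_b Models to compare.
#' @param protocol `"cv"` or `"independent"`.
#' @param alpha Significance level for the `significant` flags.
#' @param method `"t.test"` (paired) or `"wilcoxon"` (signed-rank).
#' @return data.frame: `metric`, `p_value`, `significant`, `test`, `n`.
#' @export
compare_models <- function(table, model_a, model_b, protocol = "cv",
                           alpha = 0.05, method = c("t.test", "wilcoxon")) {
  stopifnot(inherits(table, "metric_table"))
  method <- match.arg(method)
  a <- table[table$model_id == model_a & table$protocol == protocol, ]
  b <- table[table$model_id == model_b & table$protocol == protocol, ]
  shared <- intersect(a$dataset_id, b$dataset_id)
  out <- do.call(rbind, lapply(c("acc", "mcc", "sn", "sp", "auc"), function(met) {
    va <- a[[met]][match(shared, a$dataset_id)]
    vb <- b[[met]][match(shared, b$dataset_id)]
    ok <- !is.na(va) & !is.na(vb)
    va <- va[ok]; vb <- vb[ok]
    if (length(va) < 2L) {
      stop("fewer than 2 paired observations for metric '", met, "'")
    }
    d <- va - vb
    p <- if (all(abs(d) < .Machine$double.eps^0.5)) {
      1
    } else if (method == "t.test") {
      stats::t.test(va, vb, paired = TRUE)$p.value
    } else {
      stats::wilcox.test(va, vb, paired = TRUE, exact = FALSE)$p.value
    }
    data.frame(metric = met, p_value = p, significant = p < alpha,
               test = if (method == "t.test") "paired t-test"
                      else "Wilcoxon signed-rank",
               n = length(va), stringsAsFactors = FALSE)
  }))
  out
}

# half-up rounding to match the usual printed-table convention
round_half_up <- function(x, digits) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Render a metric table as fixed-width text
#'
#' Column layout mirrors the usual benchmark tables: ACC (%), MCC,
#' Sn (%), Sp (%), AUC, grouped by protocol; missing AUC cells print as
#' `-`. Percentages display with 1 decimal, MCC/AUC with 3 (half-up);
#' the underlying table keeps full precision.
#'
#' @param table A `metric_table`.
#' @return Character vector of lines.
#' @export
render_metric_text <- function(table) {
  stopifnot(inherits(table, "metric_table"))
  fmt_pct <- function(v) ifelse(is.na(v), "-",
                                sprintf("%.1f", round_half_up(v, 1)))
  fmt_3 <- function(v) ifelse(is.na(v), "-",
                              sprintf("%.3f", round_half_up(v, 3)))
  lines <- character(0)
  for (proto in unique(table$protocol)) {
    sub <- table[table$protocol == proto, ]
    lines <- c(lines,
               sprintf("== %s ==", switch(proto, cv = "5-Fold Cross-Validation",
                                          independent = "Independent Test")),
               sprintf("%-18s %-14s %7s %7s %7s %7s %7s",
                       "Model", "Dataset", "ACC(%)", "MCC", "Sn(%)", "Sp(%)", "AUC"))
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, sprintf("%-18s %-14s %7s %7s %7s %7s %7s",
                                sub$model_id[i], sub$dataset_id[i],
                                fmt_pct(sub$acc[i]), fmt_3(sub$mcc[i]),
                                fmt_pct(sub$sn[i]), fmt_pct(sub$sp[i]),
                                fmt_3(sub$auc[i])))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Serialize a metric table to JSON (losslessly round-trippable)
#'
#' @param table A `metric_table`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
metric_table_to_json <- function(table, path = NULL) {
  stopifnot(inherits(table, "metric_table"))
  j <- jsonlite::toJSON(as.data.frame(table), dataframe = "rows",
                        auto_unbox = TRUE, digits = NA, na = "null",
                        pretty = TRUE)
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}

#' @rdname metric_table_to_json
#' @export
metric_table_from_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  for (col in c("acc", "mcc", "sn", "sp", "auc")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  metric_table(df)
}
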