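#' Mean-ratio fold change between two replicate groups
#'
#' FC = (mean(target) + pseudocount) / (mean(baseline) + pseudocount),
#' on the linear abundance scale. The pseudocount (default 0.01, in the
#' same FPKM-like units as the data) guards against division by zero for
#' genes silent at the baseline without distorting expressed genes.
#'
#' @param baseline_values,target_values Non-negative replicate vectors.
#' @param pseudocount Non-negative real added to both means.
#' @return Positive fold change.
#' @export
#' @examples
#' compute_fold_change(c(2, 2), c(4, 4), pseudocount = 0)
compute_fold_change <- function(baseline_values, target_values,
                                pseudocount = 0.01) {
  if (!length(baseline_values) || !length(target_values)) {
    stop("replicate vectors must be non-empty")
  }
  if (any(baseline_values < 0) || any(target_values < 0) ||
      any(!is.finite(c(baseline_values, target_values)))) {
    stop("abundances must be finite and >= 0")
  }
  if (pseudocount < 0) {
    stop("pseudocount must be >= 0")
  }
  mb <- mean(baseline_values) + pseudocount
  mt <- mean(target_values) + pseudocount
  if (mb == 0 && mt == 0) {
    stop("fold change undefined: both group means are zero with pseudocount 0")
  }
  if (mb == 0) {
    stop("fold change undefined: baseline mean is zero with pseudocount 0")
  }
  mt / mb
}

#' Welch-test p-value between two replicate groups
#'
#' Two-sided Welch (unequal-variance) t-test on `log2(x + 1)`-transformed
#' abundances, with two degenerate rules applied before the test: fewer
#' than two replicates in either group gives p = 1 (flagged with
#' attribute `degenerate = "insufficient_replicates"`), and zero variance
#' in both groups gives p = 1 when the group means are identical and
#' p = 0 when they differ (the noise-free limit, where any difference in
#' means is unambiguous).
#'
#' @param baseline_values,target_values Non-negative replicate vectors.
#' @param log_transform Test on `log2(x + 1)` (default) rather than the
#'   linear scale.
#' @return p-value in \[0, 1\].
#' @export
compute_p_value <- function(baseline_values, target_values,
                            log_transform = TRUE) {
  if (any(baseline_values < 0) || any(target_values < 0) ||
      any(!is.finite(c(baseline_values, target_values)))) {
    stop("abundances must be finite and >= 0")
  }
  if (length(baseline_values) < 2L || length(target_values) < 2L) {
    return(structure(1, degenerate = "insufficient_replicates"))
  }
  x <- if (log_transform) log2(baseline_values + 1) else baseline_values
  y <- if (log_transform) log2(target_values + 1) else target_values
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Wrap an externally computed DE table as a comparison result
#'
#' Pass-through mode: DE tables produced by any external engine (e.g.
#' the study's published per-gene FC/p tables) enter the stratifier
#' through this constructor without recomputation.
#'
#' @param table DE table data.frame (see [validate_de_table()]).
#' @param model Cell-model label (e.g. `"hESC"`).
#' @param target Target timepoint label (e.g. `"D20"`).
#' @param baseline Baseline timepoint label.
#' @return List of class `"comparison_result"` with elements `model`,
#'   `target`, `baseline`, `table`.
#' @export
as_comparison_result <- function(table, model, target, baseline = "D0") {
  structure(list(model = as.character(model), target = as.character(target),
                 baseline = as.character(baseline),
                 table = validate_de_table(table)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("DE contrast %s: %s vs %s, %d genes\n",
              x$model, x$target, x$baseline, nrow(x$table)))
  invisible(x)
}

#' Run all timepoint-vs-baseline contrasts
#'
#' For every cell model in the sample sheet and every target timepoint,
#' computes the per-gene mean-ratio fold change and Welch p-value of the
#' target replicates against the model's baseline replicates.
#'
#' @param mat Expression matrix (genes x samples).
#' @param sheet Sample sheet data.frame covering all matrix columns.
#' @param baseline Baseline timepoint label (default `"D0"`).
#' @param targets Target timepoint labels (default `c("D20", "D35")`).
#' @param pseudocount Passed to [compute_fold_change()].
#' @param log_transform Passed to [compute_p_value()].
#' @return Named list (`"<model>_<target>"`) of `"comparison_result"`
#'   objects, one per (model, target) pair.
#' @export
run_contrasts <- function(mat, sheet, baseline = "D0",
                          targets = c("D20", "D35"),
                          pseudocount = 0.01, log_transform = TRUE) {
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing)) {
    stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (m in unique(sheet$model)) {
    base_samples <- sheet$sample_id[sheet$model == m &
                                    sheet$timepoint == baseline]
    base_samples <- intersect(base_samples, colnames(mat))
    if (!length(base_samples)) {
      stop(sprintf("model '%s' has no %s baseline samples", m, baseline))
    }
    base_mat <- mat[, base_samples, drop = FALSE]
    for (tp in targets) {
      tgt_samples <- sheet$sample_id[sheet$model == m &
                                     sheet$timepoint == tp]
      tgt_samples <- intersect(tgt_samples, colnames(mat))
      if (!length(tgt_samples)) {
        stop(sprintf("model '%s' has no %s samples", m, tp))
      }
      tgt_mat <- mat[, tgt_samples, drop = FALSE]
      fc <- numeric(nrow(mat))
      p <- numeric(nrow(mat))
      for (i in seq_len(nrow(mat))) {
        fc[i] <- compute_fold_change(base_mat[i, ], tgt_mat[i, ], pseudocount)
        p[i] <- compute_p_value(base_mat[i, ], tgt_mat[i, ], log_transform)
      }
      tbl <- data.frame(gene_id = rownames(mat), fold_change = fc,
                        p_value = p, stringsAsFactors = FALSE)
      out[[paste(m, tp, sep = "_")]] <-
        as_comparison_result(tbl, model = m, target = tp, baseline = baseline)
    }
  }
  out
}
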