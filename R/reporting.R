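#' Order a category's genes for heatmap display
#'
#' Two sorting rules mirror the study's figure conventions: the
#' `"mean_fpkm"` rule sorts genes by their mean abundance over all D20
#' and D35 samples of every model, largest first (used for the four
#' single-stage categories and for genes down at both stages); the
#' `"delta_d35_d20"` rule sorts by the difference between the mean D35
#' and mean D20 abundance — largest increase first for increasing
#' categories (`direction = "increase"`), largest decrease first for
#' decreasing ones (`direction = "decrease"`). Ties break
#' lexicographically by symbol.
#'
#' @param genes Character vector: the category's gene list; all must be
#'   rows of `mat`.
#' @param mat Expression matrix (genes x samples).
#' @param sheet Sample sheet covering the matrix columns.
#' @param rule `"mean_fpkm"` or `"delta_d35_d20"`.
#' @param direction For the delta rule: is the category increasing or
#'   decreasing from D20 to D35?
#' @param top_n Size of the highlighted prefix (e.g. the top-20 panels);
#'   `Inf` keeps everything.
#' @param timepoints Timepoints averaged by the `"mean_fpkm"` rule.
#' @return List of class `"heatmap_order"`: `genes` (full ordering),
#'   `top` (prefix of length <= `top_n`), `sort_key` (named numeric),
#'   `rule`, `direction`.
#' @export
order_heatmap <- function(genes, mat, sheet,
                          rule = c("mean_fpkm", "delta_d35_d20"),
                          direction = c("increase", "decrease"),
                          top_n = Inf, timepoints = c("D20", "D35")) {
  rule <- match.arg(rule)
  direction <- match.arg(direction)
  sheet <- validate_sample_sheet(sheet)
  genes <- normalize_symbols(genes)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing)) {
    stop("gene(s) absent from the expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (top_n < 0) stop("top_n must be >= 0")
  sub <- mat[genes, , drop = FALSE]
  sample_at <- function(tps) {
    ids <- sheet$sample_id[sheet$timepoint %in% tps]
    ids <- intersect(colnames(mat), ids)
    if (!length(ids)) {
      stop("no samples at timepoint(s): ", paste(tps, collapse = ", "))
    }
    ids
  }
  if (rule == "mean_fpkm") {
    key <- rowMeans(sub[, sample_at(timepoints), drop = FALSE])
    ord <- order(-key, genes)
  } else {
    key <- rowMeans(sub[, sample_at("D35"), drop = FALSE]) -
      rowMeans(sub[, sample_at("D20"), drop = FALSE])
    ord <- if (direction == "increase") order(-key, genes) else order(key, genes)
  }
  ordered <- genes[ord]
  structure(list(genes = ordered,
                 top = utils::head(ordered, top_n),
                 sort_key = stats::setNames(key, genes)[ordered],
                 rule = rule, direction = direction),
            class = "heatmap_order")
}

#' @export
print.heatmap_order <- function(x, ...) {
  cat(sprintf("Heatmap order (%s%s): %d genes, top %d highlighted\n",
              x$rule,
              if (x$rule == "delta_d35_d20") paste0(", ", x$direction) else "",
              length(x$genes), length(x$top)))
  invisible(x)
}

#' Render an ordered heatmap (optional)
#'
#' Draws a `log2(x + 1)` heatmap of the ordered genes with pheatmap,
#' rows in heatmap order, columns grouped by model and timepoint.
#' Requires the pheatmap package.
#'
#' @param order A [order_heatmap()] result.
#' @param mat Expression matrix.
#' @param sheet Sample sheet.
#' @param filename Optional output file passed to pheatmap.
#' @param ... Further arguments to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_heatmap <- function(order, mat, sheet, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_heatmap needs the pheatmap package")
  }
  sheet <- validate_sample_sheet(sheet)
  ord_samples <- sheet$sample_id[order(sheet$model, sheet$timepoint,
                                       sheet$replicate)]
  ord_samples <- intersect(ord_samples, colnames(mat))
  m <- log2(mat[order$genes, ord_samples, drop = FALSE] + 1)
  ann <- data.frame(model = sheet$model[match(ord_samples, sheet$sample_id)],
                    timepoint = sheet$timepoint[match(ord_samples,
                                                      sheet$sample_id)],
                    row.names = ord_samples)
  invisible(pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                               annotation_col = ann, filename = filename, ...))
}

#' Knockdown intersection filter across shRNA conditions
#'
#' Applies the hairpin-robustness filter used to define a knockdown
#' target set: within each shRNA-vs-scrambled DE table, a gene is
#' called down when `p_adjusted < p_adj_max` and log2 fold change
#' `< -abs_log2fc_min`, and up when `p_adjusted < p_adj_max` and log2
#' fold change `> abs_log2fc_min` (strict inequalities); the common
#' lists are the genes so called in at least `n_conditions_required`
#' conditions (default: all of them).
#'
#' Fold-change scale: a `log2_fold_change` column is used directly when
#' present; otherwise the linear `fold_change` column is log2-
#' transformed. `linear_fc = TRUE` instead applies the magnitude cutoff
#' literally on the linear column (`|FC| > abs_log2fc_min`, up when
#' FC > 1, down when FC < 1) — a mode retained only to reproduce
#' filters stated on that scale, and documented as such because a
#' linear magnitude cutoff below 1 cannot exclude any upregulated gene.
#'
#' @param tables Named list of DE tables (data.frames with `gene_id`,
#'   `p_adjusted` and `fold_change` or `log2_fold_change`), one per
#'   shRNA condition.
#' @param p_adj_max Adjusted-p cutoff (default 0.05).
#' @param abs_log2fc_min Magnitude cutoff (default 0.5, log2 units).
#' @param n_conditions_required Number of conditions a gene must pass
#'   in; defaults to all supplied conditions.
#' @param linear_fc Apply the magnitude cutoff on the linear scale.
#' @return List with sorted character vectors `common_down` and
#'   `common_up`.
#' @export
knockdown_intersect <- function(tables, p_adj_max = 0.05,
                                abs_log2fc_min = 0.5,
                                n_conditions_required = NULL,
                                linear_fc = FALSE) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (!(p_adj_max > 0) || !(abs_log2fc_min > 0)) {
    stop("thresholds must be positive")
  }
  if (is.null(n_conditions_required)) {
    n_conditions_required <- length(tables)
  }
  if (n_conditions_required < 1L || n_conditions_required > length(tables)) {
    stop("n_conditions_required must lie in 1..number of conditions")
  }
  nms <- names(tables)
  if (is.null(nms)) nms <- paste0("condition", seq_along(tables))
  down_votes <- list()
  up_votes <- list()
  for (i in seq_along(tables)) {
    tbl <- tables[[i]]
    if (!"p_adjusted" %in% colnames(tbl)) {
      stop(sprintf("condition '%s' has no p_adjusted column", nms[i]))
    }
    genes <- normalize_symbols(tbl$gene_id)
    sig <- tbl$p_adjusted < p_adj_max
    if (linear_fc) {
      fc <- tbl$fold_change
      pass_mag <- abs(fc) > abs_log2fc_min
      down <- sig & pass_mag & fc < 1
      up <- sig & pass_mag & fc > 1
    } else {
      lfc <- if ("log2_fold_change" %in% colnames(tbl)) {
        tbl$log2_fold_change
      } else {
        log2(tbl$fold_change)
      }
      down <- sig & lfc < -abs_log2fc_min
      up <- sig & lfc > abs_log2fc_min
    }
    down_votes[[i]] <- genes[down]
    up_votes[[i]] <- genes[up]
  }
  tally <- function(votes) {
    counts <- table(unlist(votes, use.names = FALSE))
    sort(names(counts)[counts >= n_conditions_required])
  }
  list(common_down = tally(down_votes), common_up = tally(up_votes))
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' Per sample: dCt = Ct(target) - Ct(reference); ddCt = dCt minus the
#' mean dCt of the control condition; relative expression = 2^-ddCt.
#' The control condition's relative expression has geometric mean 1 by
#' construction.
#'
#' @param ct data.frame with columns `sample`, `condition`,
#'   `target_ct`, `reference_ct` (one row per sample).
#' @param control_condition Label of the calibrator condition.
#' @return The input with columns `delta_ct`, `delta_delta_ct` and
#'   `rel_expr` appended.
#' @export
#' @examples
#' ct <- data.frame(sample = c("s1", "s2", "s3", "s4"),
#'                  condition = c("ctrl", "ctrl", "kd", "kd"),
#'                  target_ct = c(20, 21, 24, 25),
#'                  reference_ct = c(15, 16, 15, 16))
#' ddct(ct, "ctrl")
ddct <- function(ct, control_condition) {
  required <- c("sample", "condition", "target_ct", "reference_ct")
  missing <- setdiff(required, colnames(ct))
  if (length(missing)) {
    stop("Ct table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$reference_ct))) {
    stop("Ct values must be finite")
  }
  if (!any(ct$condition == control_condition)) {
    stop(sprintf("control condition '%s' absent from Ct table",
                 control_condition))
  }
  ct$delta_ct <- ct$target_ct - ct$reference_ct
  control_mean <- mean(ct$delta_ct[ct$condition == control_condition])
  ct$delta_delta_ct <- ct$delta_ct - control_mean
  ct$rel_expr <- 2^(-ct$delta_delta_ct)
  ct
}
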