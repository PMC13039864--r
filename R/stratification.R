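#' The eight trajectory categories
#'
#' A gene's differential status versus the D0 baseline at the
#' endocrine-progenitor stage (D20) and the beta-like-cell stage (D35)
#' places it in one of eight trajectory categories. Genes upregulated at
#' both stages are further split by the change-in-FC ratio
#' r = FC(D35) / FC(D20) into increasing (r > 1.5), decreasing
#' (r < 0.5) and near-constant (0.5 <= r <= 1.5) expression.
#' Two bookkeeping labels complete the partition: `DISCORDANT` (up at
#' one stage, down at the other) and `UNCLASSIFIED` (neither stage
#' significant).
#'
#' @param include_bookkeeping Also return `DISCORDANT` and
#'   `UNCLASSIFIED`.
#' @return Character vector of category labels in the canonical report
#'   order.
#' @export
trajectory_categories <- function(include_bookkeeping = FALSE) {
  cats <- c("UP_D20_ONLY", "UP_D35_ONLY",
            "UP_BOTH_NEAR_CONSTANT", "UP_BOTH_INCREASING",
            "UP_BOTH_DECREASING",
            "DOWN_BOTH", "DOWN_D20_ONLY", "DOWN_D35_ONLY")
  if (include_bookkeeping) c(cats, "DISCORDANT", "UNCLASSIFIED") else cats
}

#' Stratification thresholds
#'
#' Default thresholds: upregulation FC > 2.0, downregulation FC < 0.5,
#' both additionally requiring p < 0.05; change-in-FC ratio bins at
#' 1.5 and 0.5 with boundaries belonging to the near-constant bin.
#' `strict_fc = TRUE` reads the FC cutoffs as strict inequalities
#' (FC exactly 2.0 is not significant); set it to `FALSE` for inclusive
#' cutoffs.
#'
#' @param fc_up Upregulation fold-change cutoff (> 1).
#' @param fc_down Downregulation fold-change cutoff (< 1).
#' @param p_max p-value cutoff applied to each contrast.
#' @param ratio_up Change-in-FC cutoff above which expression is
#'   increasing.
#' @param ratio_down Change-in-FC cutoff below which expression is
#'   decreasing.
#' @param strict_fc Use strict inequalities on the FC cutoffs.
#' @return List of class `"trajectory_thresholds"`.
#' @export
trajectory_thresholds <- function(fc_up = 2, fc_down = 0.5, p_max = 0.05,
                                  ratio_up = 1.5, ratio_down = 0.5,
                                  strict_fc = TRUE) {
  stopifnot(is.numeric(fc_up), is.numeric(fc_down), is.numeric(p_max),
            is.numeric(ratio_up), is.numeric(ratio_down))
  if (!(fc_down < 1 && 1 < fc_up)) {
    stop("need fc_down < 1 < fc_up")
  }
  if (!(ratio_down < 1 && 1 < ratio_up)) {
    stop("need ratio_down < 1 < ratio_up")
  }
  if (!(p_max > 0 && p_max <= 1)) {
    stop("need 0 < p_max <= 1")
  }
  structure(list(fc_up = fc_up, fc_down = fc_down, p_max = p_max,
                 ratio_up = ratio_up, ratio_down = ratio_down,
                 strict_fc = isTRUE(strict_fc)),
            class = "trajectory_thresholds")
}

#' Call per-timepoint differential status
#'
#' `UP` when the fold change exceeds `fc_up` and p < `p_max`; `DOWN`
#' when it falls below `fc_down` and p < `p_max`; `NS` otherwise.
#' Vectorized over `fc` and `p`.
#'
#' @param fc Positive fold change(s), linear scale versus baseline.
#' @param p p-value(s).
#' @param thresholds A [trajectory_thresholds()] object.
#' @return Character vector in `{"UP", "DOWN", "NS"}`.
#' @export
#' @examples
#' call_status(c(3, 2, 0.4), c(0.01, 0.01, 0.2), trajectory_thresholds())
call_status <- function(fc, p, thresholds = trajectory_thresholds()) {
  stopifnot(inherits(thresholds, "trajectory_thresholds"))
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    stop("fold changes must be finite and > 0")
  }
  up <- if (thresholds$strict_fc) fc > thresholds$fc_up else fc >= thresholds$fc_up
  down <- if (thresholds$strict_fc) fc < thresholds$fc_down else fc <= thresholds$fc_down
  sig <- p < thresholds$p_max
  ifelse(up & sig, "UP", ifelse(down & sig, "DOWN", "NS"))
}

#' Change-in-FC ratio
#'
#' The statistic used to sub-classify genes upregulated at both stages:
#' the D35-vs-D0 fold change divided by the D20-vs-D0 fold change. A
#' gene with FC 2 at D20 and FC 6 at D35 has r = 6 / 2 = 3.
#'
#' @param fc_d20 Fold change at the early stage (D20 vs D0).
#' @param fc_d35 Fold change at the late stage (D35 vs D0).
#' @return `fc_d35 / fc_d20`.
#' @export
change_in_fc <- function(fc_d20, fc_d35) {
  if (any(!is.finite(fc_d20)) || any(fc_d20 <= 0) ||
      any(!is.finite(fc_d35)) || any(fc_d35 <= 0)) {
    stop("fold changes must be finite and > 0")
  }
  fc_d35 / fc_d20
}

#' Bin a change-in-FC ratio
#'
#' r > `ratio_up` is `INCREASING`, r < `ratio_down` is `DECREASING`,
#' and the closed interval between them (boundaries included) is
#' `NEAR_CONSTANT`. Vectorized.
#'
#' @param r Positive change-in-FC ratio(s).
#' @param thresholds A [trajectory_thresholds()] object.
#' @return Character vector in
#'   `{"INCREASING", "DECREASING", "NEAR_CONSTANT"}`.
#' @export
#' @examples
#' bin_ratio(c(3, 1.5, 0.4))
bin_ratio <- function(r, thresholds = trajectory_thresholds()) {
  stopifnot(inherits(thresholds, "trajectory_thresholds"))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("change-in-FC ratio must be finite and > 0")
  }
  ifelse(r > thresholds$ratio_up, "INCREASING",
         ifelse(r < thresholds$ratio_down, "DECREASING", "NEAR_CONSTANT"))
}

#' Classify a gene from its (D20, D35) status pair
#'
#' Maps the 3x3 table of per-stage statuses onto the trajectory
#' categories; `(UP, UP)` genes are split by [bin_ratio()] applied to
#' `r`. `(UP, DOWN)` and `(DOWN, UP)` are labelled `DISCORDANT`,
#' `(NS, NS)` is `UNCLASSIFIED`. Vectorized; `r` is only consulted for
#' `(UP, UP)` pairs.
#'
#' @param status_d20,status_d35 Statuses from [call_status()].
#' @param r Change-in-FC ratio(s); may be `NA` for genes that are not
#'   up at both stages.
#' @param thresholds A [trajectory_thresholds()] object.
#' @return Character vector of category labels.
#' @export
classify_gene <- function(status_d20, status_d35, r = NA_real_,
                          thresholds = trajectory_thresholds()) {
  ok <- c("UP", "DOWN", "NS")
  if (!all(status_d20 %in% ok) || !all(status_d35 %in% ok)) {
    stop("statuses must be UP, DOWN or NS")
  }
  n <- max(length(status_d20), length(status_d35))
  status_d20 <- rep_len(status_d20, n)
  status_d35 <- rep_len(status_d35, n)
  r <- rep_len(r, n)
  out <- rep_len("UNCLASSIFIED", n)
  out[status_d20 == "UP" & status_d35 == "NS"] <- "UP_D20_ONLY"
  out[status_d20 == "NS" & status_d35 == "UP"] <- "UP_D35_ONLY"
  out[status_d20 == "DOWN" & status_d35 == "DOWN"] <- "DOWN_BOTH"
  out[status_d20 == "DOWN" & status_d35 == "NS"] <- "DOWN_D20_ONLY"
  out[status_d20 == "NS" & status_d35 == "DOWN"] <- "DOWN_D35_ONLY"
  out[(status_d20 == "UP" & status_d35 == "DOWN") |
      (status_d20 == "DOWN" & status_d35 == "UP")] <- "DISCORDANT"
  both_up <- status_d20 == "UP" & status_d35 == "UP"
  if (any(both_up)) {
    if (any(!is.finite(r[both_up]) | r[both_up] <= 0)) {
      stop("genes up at both stages need a positive change-in-FC ratio")
    }
    out[both_up] <- paste0("UP_BOTH_", bin_ratio(r[both_up], thresholds))
  }
  out
}

#' Stratify DE contrasts into trajectory categories
#'
#' The core procedure: for each cell model, combine its early
#' (D20-vs-D0) and late (D35-vs-D0) DE tables, call per-stage statuses,
#' compute the change-in-FC ratio, assign every gene a trajectory
#' category, and — when two or more models are supplied — intersect the
#' per-category gene sets across models so that only genes with the same
#' trajectory in every model are retained.
#'
#' @param comparisons List of comparison results from [run_contrasts()]
#'   or [as_comparison_result()] (pass-through mode).
#' @param thresholds A [trajectory_thresholds()] object.
#' @param early,late Target timepoint labels of the two contrasts.
#' @param count_discordant_in_only Also count `DISCORDANT` genes into
#'   the matching `*_ONLY` sets when building category gene sets (their
#'   per-gene label stays `DISCORDANT`).
#' @return List of class `"stratification_result"` with elements
#'   `per_model` (named list of per-gene assignment data.frames),
#'   `intersected` (named list: category -> sorted common gene vector;
#'   `NULL` for a single model), `thresholds`, `early`, `late`.
#' @export
stratify <- function(comparisons, thresholds = trajectory_thresholds(),
                     early = "D20", late = "D35",
                     count_discordant_in_only = FALSE) {
  stopifnot(length(comparisons) >= 1L)
  models <- unique(vapply(comparisons, `[[`, character(1L), "model"))
  per_model <- list()
  for (m in models) {
    mine <- Filter(function(cr) cr$model == m, comparisons)
    targets <- vapply(mine, `[[`, character(1L), "target")
    if (!(early %in% targets) || !(late %in% targets)) {
      stop(sprintf("model '%s' needs both %s and %s contrasts", m, early, late))
    }
    t20 <- mine[[match(early, targets)]]$table
    t35 <- mine[[match(late, targets)]]$table
    common <- intersect(t20$gene_id, t35$gene_id)
    i20 <- match(common, t20$gene_id)
    i35 <- match(common, t35$gene_id)
    df <- data.frame(gene_id = common,
                     fc_d20 = t20$fold_change[i20],
                     p_d20 = t20$p_value[i20],
                     fc_d35 = t35$fold_change[i35],
                     p_d35 = t35$p_value[i35],
                     stringsAsFactors = FALSE)
    df$status_d20 <- call_status(df$fc_d20, df$p_d20, thresholds)
    df$status_d35 <- call_status(df$fc_d35, df$p_d35, thresholds)
    df$ratio <- change_in_fc(df$fc_d20, df$fc_d35)
    df$category <- classify_gene(df$status_d20, df$status_d35, df$ratio,
                                 thresholds)
    per_model[[m]] <- df
  }
  intersected <- if (length(per_model) >= 2L) {
    intersect_models(per_model,
                     count_discordant_in_only = count_discordant_in_only)
  } else {
    NULL
  }
  structure(list(per_model = per_model, intersected = intersected,
                 thresholds = thresholds, early = early, late = late,
                 count_discordant_in_only = count_discordant_in_only),
            class = "stratification_result")
}

#' Per-category gene sets of one model's assignment
#'
#' @param assignment Per-gene assignment data.frame (an element of
#'   `stratify()$per_model`).
#' @param count_discordant_in_only Also place `DISCORDANT` genes into
#'   the two matching `*_ONLY` sets (UP at D20 / DOWN at D35 joins
#'   `UP_D20_ONLY` and `DOWN_D35_ONLY`, and symmetrically).
#' @return Named list: category label -> sorted gene vector (all ten
#'   labels present, possibly empty).
#' @export
category_sets <- function(assignment, count_discordant_in_only = FALSE) {
  labels <- trajectory_categories(include_bookkeeping = TRUE)
  sets <- lapply(labels, function(l) {
    sort(assignment$gene_id[assignment$category == l])
  })
  names(sets) <- labels
  if (count_discordant_in_only) {
    ud <- assignment$status_d20 == "UP" & assignment$status_d35 == "DOWN"
    du <- assignment$status_d20 == "DOWN" & assignment$status_d35 == "UP"
    sets$UP_D20_ONLY <- sort(union(sets$UP_D20_ONLY, assignment$gene_id[ud]))
    sets$DOWN_D35_ONLY <- sort(union(sets$DOWN_D35_ONLY, assignment$gene_id[ud]))
    sets$DOWN_D20_ONLY <- sort(union(sets$DOWN_D20_ONLY, assignment$gene_id[du]))
    sets$UP_D35_ONLY <- sort(union(sets$UP_D35_ONLY, assignment$gene_id[du]))
  }
  sets
}

#' Intersect per-model category assignments
#'
#' For each trajectory category, the genes assigned to that category in
#' every model. A gene up at both stages must fall in the same
#' change-in-FC bin in every model to survive.
#'
#' @param per_model Named list (>= 2 models) of per-gene assignment
#'   data.frames as produced by [stratify()].
#' @param count_discordant_in_only See [category_sets()].
#' @return Named list: category label -> lexicographically sorted
#'   common gene vector.
#' @export
intersect_models <- function(per_model, count_discordant_in_only = FALSE) {
  if (length(per_model) < 2L) {
    stop("intersection needs >= 2 models; use the per-model output instead")
  }
  all_sets <- lapply(per_model, category_sets,
                     count_discordant_in_only = count_discordant_in_only)
  labels <- trajectory_categories(include_bookkeeping = TRUE)
  out <- lapply(labels, function(l) {
    sort(Reduce(intersect, lapply(all_sets, `[[`, l)))
  })
  names(out) <- labels
  out
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("Trajectory stratification: %d model(s), contrasts %s/%s vs baseline\n",
              length(x$per_model), x$early, x$late))
  print(summary(x))
  invisible(x)
}

#' Category sizes of a stratification
#'
#' @param object A `"stratification_result"`.
#' @param ... Unused.
#' @return data.frame with one row per category label and one column
#'   per model plus (when present) the cross-model intersection.
#' @export
summary.stratification_result <- function(object, ...) {
  labels <- trajectory_categories(include_bookkeeping = TRUE)
  counts <- vapply(object$per_model, function(df) {
    vapply(labels, function(l) sum(df$category == l), integer(1L))
  }, integer(length(labels)))
  out <- data.frame(category = labels, counts, check.names = FALSE,
                    row.names = NULL)
  if (!is.null(object$intersected)) {
    out$intersected <- vapply(object$intersected[labels], length, integer(1L))
  }
  out
}
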