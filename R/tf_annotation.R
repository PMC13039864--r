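#' Overlay a transcription-factor registry onto category gene lists
#'
#' For each trajectory category, intersects the category's gene list
#' with the TF registry and reports the TF members, counts and the
#' percentage of the category made up of transcription factors.
#' Registry symbols that match no category gene are reported (attribute
#' `unmatched_registry`) rather than silently dropped, since symbol
#' drift between catalogues is the main failure mode of this overlay.
#'
#' @param x Either a `"stratification_result"` (the intersected sets
#'   are annotated when present, otherwise the single model's sets) or
#'   a named list of gene vectors (category -> genes).
#' @param registry Character vector of TF symbols (see
#'   [read_tf_registry()]); matched after [normalize_symbols()].
#' @return data.frame of class `"tf_report"` with columns `category`,
#'   `n_genes`, `n_tf`, `tf_percent`, plus attributes `tf_genes`
#'   (named list of sorted per-category TF vectors) and
#'   `unmatched_registry`.
#' @export
annotate_tfs <- function(x, registry) {
  registry <- unique(normalize_symbols(registry))
  registry <- registry[nzchar(registry)]
  if (!length(registry)) {
    stop("transcription-factor registry is empty")
  }
  sets <- if (inherits(x, "stratification_result")) {
    if (!is.null(x$intersected)) {
      x$intersected
    } else {
      category_sets(x$per_model[[1L]],
                    count_discordant_in_only = x$count_discordant_in_only)
    }
  } else if (is.list(x)) {
    lapply(x, normalize_symbols)
  } else {
    stop("x must be a stratification_result or a named list of gene vectors")
  }
  tf_genes <- lapply(sets, function(g) sort(intersect(g, registry)))
  n_genes <- vapply(sets, length, integer(1L))
  n_tf <- vapply(tf_genes, length, integer(1L))
  report <- data.frame(category = names(sets),
                       n_genes = n_genes,
                       n_tf = n_tf,
                       tf_percent = ifelse(n_genes == 0, 0,
                                           100 * n_tf / n_genes),
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "tf_genes") <- tf_genes
  attr(report, "unmatched_registry") <-
    sort(setdiff(registry, unique(unlist(sets, use.names = FALSE))))
  class(report) <- c("tf_report", "data.frame")
  report
}

#' @export
print.tf_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  unmatched <- attr(x, "unmatched_registry")
  cat(sprintf("(%d registry symbols matched no category gene)\n",
              length(unmatched)))
  invisible(x)
}
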