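#' Hypergeometric over-representation p-value
#'
#' The one-sided tail P\[X >= k\] where X ~ Hypergeometric(N, K, n):
#' the probability of drawing at least `k` members of a `K`-gene set in
#' a query of `n` genes from a background of `N`, computed with
#' `stats::phyper` for numerical stability.
#'
#' @param k Observed overlap between query and set.
#' @param K Set size within the background.
#' @param n Query size.
#' @param N Background (universe) size.
#' @return p-value in \[0, 1\].
#' @export
#' @examples
#' hypergeom_p(3, 5, 3, 10)  # C(5,3)/C(10,3) = 10/120
hypergeom_p <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0)) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (k > min(K, n) || K > N || n > N) {
    stop(sprintf(
      "inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N (got k=%d K=%d n=%d N=%d)",
      k, K, n, N))
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation of a query list
#'
#' Tests each set of a GMT collection for over-representation in a
#' query gene list against a background universe (the set of genes
#' detected in the experiment), using the one-sided hypergeometric test
#' and Benjamini-Hochberg FDR control across all tested sets. This is
#' the package's stand-in for web-service GO BP profiling; the BH
#' correction is a deliberate, documented substitution for service-
#' specific multiple-testing schemes.
#'
#' @param query Character vector of gene symbols.
#' @param collection A `"gene_set_collection"` (see [read_gmt()]).
#' @param background Character vector: the gene universe. Query genes
#'   absent from the background are dropped with a warning.
#' @return data.frame sorted by ascending p-value (ties by set name)
#'   with columns `set_name`, `set_size`, `query_size`, `overlap`,
#'   `background_size`, `p_value`, `q_value`, `overlap_genes`
#'   (comma-separated sorted symbols). Sets that do not intersect the
#'   background are omitted.
#' @export
enrich <- function(query, collection, background) {
  background <- unique(normalize_symbols(background))
  background <- background[nzchar(background)]
  if (!length(background)) {
    stop("background gene universe is empty")
  }
  query <- unique(normalize_symbols(query))
  query <- query[nzchar(query)]
  dropped <- setdiff(query, background)
  if (length(dropped)) {
    warning(sprintf("%d query gene(s) absent from the background were dropped",
                    length(dropped)))
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]]$genes, background)
    if (!length(members)) return(NULL)
    hits <- intersect(query, members)
    data.frame(set_name = nm,
               set_size = length(members),
               query_size = n,
               overlap = length(hits),
               background_size = N,
               p_value = hypergeom_p(length(hits), length(members), n, N),
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    stop("no gene set intersects the background")
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out[c("set_name", "set_size", "query_size", "overlap", "background_size",
        "p_value", "q_value", "overlap_genes")]
}
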