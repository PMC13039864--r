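#' Normalize gene symbols
#'
#' Gene identifiers throughout the package are HGNC-style symbols,
#' uppercased with surrounding whitespace stripped. Every reader applies
#' this normalization, so symbol matching between the expression matrix,
#' DE tables, the transcription-factor registry and gene-set collections
#' is case- and whitespace-insensitive. The operation is idempotent.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbols(c(" Ins ", "NKX6-1", "smad9"))
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated abundance table (FPKM-like units): first column
#' gene symbols, header row of sample identifiers, remaining cells
#' non-negative numbers. Symbols are normalized with
#' [normalize_symbols()]; rows that collapse to the same symbol are
#' resolved by `collapse`.
#'
#' @param path Path to a tab-separated text file.
#' @param collapse How to resolve duplicate symbols after normalization:
#'   `"max_mean"` (default) keeps the row with the largest mean
#'   abundance, `"first"` keeps the first occurrence, `"error"` fails.
#' @return Numeric matrix, rownames = gene symbols, colnames = sample
#'   identifiers. Row order is the file order of the surviving rows.
#' @export
read_expression_matrix <- function(path, collapse = c("max_mean", "first", "error")) {
  collapse <- match.arg(collapse)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) {
    stop("expression matrix needs a gene column plus at least one sample column")
  }
  samples <- colnames(df)[-1L]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample header(s): ", paste(dup_s, collapse = ", "))
  }
  genes <- normalize_symbols(df[[1L]])
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   df[[j + 1L]][bad[1L]], genes[bad[1L]], samples[j]))
    }
    vals[, j] <- v
  }
  if (any(vals < 0)) {
    stop("negative abundance values are not allowed")
  }
  rownames(vals) <- genes
  collapse_duplicate_genes(vals, collapse)
}

collapse_duplicate_genes <- function(mat, collapse) {
  genes <- rownames(mat)
  if (!anyDuplicated(genes)) {
    return(mat)
  }
  if (collapse == "error") {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene symbol(s) after normalization: ",
         paste(dup, collapse = ", "))
  }
  keep <- if (collapse == "first") {
    !duplicated(genes)
  } else {
    # max_mean: keep the row with the largest mean, first wins ties
    means <- rowMeans(mat)
    best <- tapply(seq_along(genes), genes, function(i) i[which.max(means[i])])
    seq_along(genes) %in% unlist(best)
  }
  mat[keep, , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix as returned by [read_expression_matrix()].
#' @param path Output path.
#' @param gene_column Header for the gene column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, gene_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet assigns each expression-matrix column to a cell model
#' (e.g. hESC, hiPSC), a differentiation timepoint (e.g. D0, D13, D20,
#' D35) and a replicate number. (model, timepoint, replicate) triples
#' must be unique.
#'
#' @param path TSV with columns `sample_id`, `model`, `timepoint`,
#'   `replicate`.
#' @return data.frame with those four columns, `replicate` integer.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data.frame
#'
#' @param df data.frame with columns `sample_id`, `model`, `timepoint`,
#'   `replicate`.
#' @return The validated data.frame (replicate coerced to integer).
#' @export
validate_sample_sheet <- function(df) {
  required <- c("sample_id", "model", "timepoint", "replicate")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$replicate) || any(df$replicate < 1L)) {
    stop("replicate must be a positive integer")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  key <- paste(df$model, df$timepoint, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(model, timepoint, replicate) triples must be unique")
  }
  df[required]
}

#' Write a sample sheet as TSV
#' @param sheet Sample sheet data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-contrast differential-expression table
#'
#' One row per gene: linear-scale fold change versus the baseline
#' timepoint, a p-value, and optionally an adjusted p-value (used by the
#' knockdown filter). This is also the pass-through entry point for DE
#' tables computed outside the package.
#'
#' @param path TSV with header `gene_id`, `fold_change`, `p_value` and
#'   optionally `p_adjusted`.
#' @return Validated data.frame (a DE table).
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_de_table(df)
}

#' Validate a differential-expression table
#'
#' Checks the DE-table contract: normalized unique gene symbols, finite
#' positive fold changes, p-values in \[0, 1\].
#'
#' @param df data.frame with columns `gene_id`, `fold_change`, `p_value`
#'   and optionally `p_adjusted`.
#' @return The validated data.frame.
#' @export
validate_de_table <- function(df) {
  required <- c("gene_id", "fold_change", "p_value")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$gene_id <- normalize_symbols(df$gene_id)
  if (anyDuplicated(df$gene_id)) {
    stop("DE table has more than one row for gene(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (any(!is.finite(df$fold_change)) || any(df$fold_change <= 0)) {
    stop("fold_change must be finite and > 0 (linear scale)")
  }
  pcols <- intersect(c("p_value", "p_adjusted"), colnames(df))
  for (pc in pcols) {
    if (any(!is.finite(df[[pc]])) || any(df[[pc]] < 0 | df[[pc]] > 1)) {
      stop(pc, " must lie in [0, 1]")
    }
  }
  df
}

#' Write a DE table as TSV
#' @param df DE table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor registry
#'
#' A plain-text catalogue of human transcription-factor gene symbols,
#' one per line (e.g. the Lambert catalogue). Symbols are normalized,
#' deduplicated and sorted; blank lines are skipped.
#'
#' @param path Path to the symbol list.
#' @param source_label Free-text provenance label stored as an attribute;
#'   defaults to the file name.
#' @return Sorted character vector of unique symbols with attribute
#'   `source_label`.
#' @export
read_tf_registry <- function(path, source_label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  symbols <- normalize_symbols(lines)
  symbols <- sort(unique(symbols[nzchar(symbols)]))
  if (!length(symbols)) {
    stop("transcription-factor registry is empty: ", path)
  }
  structure(symbols, source_label = source_label)
}

#' Write a transcription-factor registry
#' @param registry Character vector of symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tf_registry <- function(registry, path) {
  writeLines(as.character(registry), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT dialect: each line is
#' `set_name<TAB>description<TAB>member1<TAB>member2...`. Member symbols
#' are normalized and deduplicated within each set.
#'
#' @param path Path to a GMT file.
#' @return Named list; each element is `list(description =, genes =)`.
#'   Class `"gene_set_collection"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  names(sets) <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    genes <- unique(normalize_symbols(fields[-c(1L, 2L)]))
    genes <- genes[nzchar(genes)]
    if (length(fields) < 3L || !length(genes)) {
      stop(sprintf("GMT line %d: expected set name, description and at least one member", i))
    }
    names(sets)[i] <- trimws(fields[1L])
    sets[[i]] <- list(description = fields[2L], genes = genes)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection Object returned by [read_gmt()] or a named list of
#'   `list(description =, genes =)` elements.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), integer(1L))
  cat(sprintf("Gene-set collection: %d sets (sizes %d-%d)\n",
              length(x), if (length(x)) min(sizes) else 0L,
              if (length(x)) max(sizes) else 0L))
  invisible(x)
}
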