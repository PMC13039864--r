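# Shared fixture builders (all data generated in code at test time)

small_counts <- function(n_planted = 20L, n_background = 100L) {
  c(stats::setNames(rep(n_planted, 8L), trajectory_categories()),
    UNCLASSIFIED = n_background)
}

# Category assigned to each gene by the cross-model intersection
# (NA when the gene falls in no intersected category)
assigned_categories <- function(strat, gene_ids) {
  assigned <- rep(NA_character_, length(gene_ids))
  names(assigned) <- gene_ids
  for (l in names(strat$intersected)) {
    assigned[strat$intersected[[l]]] <- l
  }
  assigned
}

# Fraction of planted (non-background) genes whose intersected category
# equals the planted truth
recovery_fraction <- function(sim, strat) {
  assigned <- assigned_categories(strat, sim$truth$gene_id)
  planted <- sim$truth$category != "UNCLASSIFIED"
  mean(!is.na(assigned[planted]) &
         assigned[planted] == sim$truth$category[planted])
}

# Random per-gene assignment table over the full label set
random_assignment <- function(genes, seed_categories) {
  data.frame(gene_id = genes,
             status_d20 = "NS", status_d35 = "NS",
             category = seed_categories,
             stringsAsFactors = FALSE)
}

random_de_table <- function(genes, with_padj = TRUE) {
  tbl <- data.frame(gene_id = genes,
                    fold_change = 2^stats::runif(length(genes), -3, 3),
                    p_value = stats::runif(length(genes)),
                    stringsAsFactors = FALSE)
  if (with_padj) tbl$p_adjusted <- stats::runif(length(genes))
  tbl
}
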