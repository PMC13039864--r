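#' Default planted fold changes per trajectory category
#'
#' Planted (D20, D35) fold changes versus baseline for each trajectory
#' category, chosen to satisfy the category's defining inequalities with
#' at least the default 1.5x safety margin beyond every threshold so
#' that classes remain recoverable under replicate noise. Background
#' (`UNCLASSIFIED`) genes are flat at FC 1.
#'
#' @return Named list: category -> `c(d20 =, d35 =)`.
#' @export
default_planted_fc <- function() {
  list(
    UP_D20_ONLY           = c(d20 = 3,    d35 = 1),
    UP_D35_ONLY           = c(d20 = 1,    d35 = 3),
    UP_BOTH_NEAR_CONSTANT = c(d20 = 3,    d35 = 3),
    UP_BOTH_INCREASING    = c(d20 = 3,    d35 = 9),
    UP_BOTH_DECREASING    = c(d20 = 10,   d35 = 3),
    DOWN_BOTH             = c(d20 = 0.25, d35 = 0.25),
    DOWN_D20_ONLY         = c(d20 = 0.25, d35 = 1),
    DOWN_D35_ONLY         = c(d20 = 1,    d35 = 0.25),
    UNCLASSIFIED          = c(d20 = 1,    d35 = 1)
  )
}

#' Build and validate a simulation configuration
#'
#' Defines the synthetic study: two cell models, three replicates at
#' each of four timepoints (D0 baseline, D13, D20, D35), 50 genes
#' planted in each of the eight trajectory categories plus 200 flat
#' background genes, log-normal replicate noise on the linear FPKM
#' scale, and a transcription-factor flag on a fixed fraction of each
#' category. Planted fold changes are rejected unless they satisfy
#' their category's defining inequalities with margin `safety_factor`
#' beyond every threshold.
#'
#' @param n_genes_per_category Named integer vector, category -> gene
#'   count; the `UNCLASSIFIED` entry is the flat background.
#' @param baseline_mean Mean abundance (FPKM-like) at the baseline.
#' @param planted_fc Named list, category -> `c(d20 =, d35 =)`; see
#'   [default_planted_fc()].
#' @param noise_sd SD of the Normal log2 replicate noise (0 = noise
#'   free).
#' @param n_replicates Replicates per (model, timepoint).
#' @param models Cell-model labels.
#' @param timepoints Timepoint labels; must contain `baseline`, `"D20"`
#'   and `"D35"`; a `"D13"` timepoint, when present, follows the
#'   geometric midpoint between baseline and D20.
#' @param baseline Baseline timepoint label.
#' @param tf_fraction Fraction of each category flagged as
#'   transcription factors.
#' @param discordance_fraction Fraction of planted genes whose
#'   trajectory is flattened in every model after the first, to emulate
#'   model disagreement and exercise intersection loss.
#' @param safety_factor Required margin (>= 1) between each planted FC
#'   or ratio and the threshold it must clear.
#' @param thresholds A [trajectory_thresholds()] object the planted FCs
#'   are validated against.
#' @param seed Integer RNG seed; identical configs give bit-identical
#'   simulations.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes_per_category = NULL,
                              baseline_mean = 10,
                              planted_fc = default_planted_fc(),
                              noise_sd = 0.25,
                              n_replicates = 3,
                              models = c("hESC", "hiPSC"),
                              timepoints = c("D0", "D13", "D20", "D35"),
                              baseline = "D0",
                              tf_fraction = 0.1,
                              discordance_fraction = 0,
                              safety_factor = 1.5,
                              thresholds = trajectory_thresholds(),
                              seed = 1L) {
  if (is.null(n_genes_per_category)) {
    n_genes_per_category <- c(stats::setNames(rep(50L, 8L),
                                              trajectory_categories()),
                              UNCLASSIFIED = 200L)
  }
  known <- c(trajectory_categories(), "UNCLASSIFIED")
  bad <- setdiff(names(n_genes_per_category), known)
  if (length(bad)) {
    stop("unknown categor(ies): ", paste(bad, collapse = ", "))
  }
  if (any(n_genes_per_category < 0)) {
    stop("gene counts must be >= 0")
  }
  stopifnot(baseline_mean > 0, noise_sd >= 0, n_replicates >= 1,
            safety_factor >= 1, length(models) >= 1)
  if (!(tf_fraction >= 0 && tf_fraction <= 1)) {
    stop("tf_fraction must lie in [0, 1]")
  }
  if (!(discordance_fraction >= 0 && discordance_fraction <= 1)) {
    stop("discordance_fraction must lie in [0, 1]")
  }
  need <- c(baseline, "D20", "D35")
  if (!all(need %in% timepoints)) {
    stop("timepoints must include ", paste(need, collapse = ", "))
  }
  for (cat in names(n_genes_per_category)) {
    if (n_genes_per_category[[cat]] > 0L) {
      validate_planted_fc(cat, planted_fc[[cat]], thresholds, safety_factor)
    }
  }
  structure(list(n_genes_per_category = n_genes_per_category,
                 baseline_mean = baseline_mean, planted_fc = planted_fc,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 models = models, timepoints = timepoints,
                 baseline = baseline, tf_fraction = tf_fraction,
                 discordance_fraction = discordance_fraction,
                 safety_factor = safety_factor, thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# A planted (d20, d35) FC pair must clear every inequality its category
# imposes by at least the safety factor; the UP_BOTH ratio bins apply the
# same margin to r = d35/d20.
validate_planted_fc <- function(category, fc, thresholds, safety_factor) {
  if (is.null(fc) || !all(c("d20", "d35") %in% names(fc))) {
    stop(sprintf("category %s needs planted FCs named d20 and d35", category))
  }
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    stop(sprintf("category %s: planted FCs must be finite and > 0", category))
  }
  th <- thresholds
  sf <- safety_factor
  up_ok <- function(v) v >= th$fc_up * sf
  down_ok <- function(v) v <= th$fc_down / sf
  ns_ok <- function(v) v >= th$fc_down * sf && v <= th$fc_up / sf
  r <- fc[["d35"]] / fc[["d20"]]
  ok <- switch(category,
    UP_D20_ONLY = up_ok(fc[["d20"]]) && ns_ok(fc[["d35"]]),
    UP_D35_ONLY = ns_ok(fc[["d20"]]) && up_ok(fc[["d35"]]),
    UP_BOTH_NEAR_CONSTANT = up_ok(fc[["d20"]]) && up_ok(fc[["d35"]]) &&
      r >= th$ratio_down * sf && r <= th$ratio_up / sf,
    UP_BOTH_INCREASING = up_ok(fc[["d20"]]) && up_ok(fc[["d35"]]) &&
      r >= th$ratio_up * sf,
    UP_BOTH_DECREASING = up_ok(fc[["d20"]]) && up_ok(fc[["d35"]]) &&
      r <= th$ratio_down / sf,
    DOWN_BOTH = down_ok(fc[["d20"]]) && down_ok(fc[["d35"]]),
    DOWN_D20_ONLY = down_ok(fc[["d20"]]) && ns_ok(fc[["d35"]]),
    DOWN_D35_ONLY = ns_ok(fc[["d20"]]) && down_ok(fc[["d35"]]),
    UNCLASSIFIED = ns_ok(fc[["d20"]]) && ns_ok(fc[["d35"]]),
    stop("unknown category: ", category))
  if (!ok) {
    stop(sprintf(
      "category %s: planted FCs (d20 = %g, d35 = %g) do not satisfy the category's inequalities with safety factor %g",
      category, fc[["d20"]], fc[["d35"]], sf))
  }
  invisible(TRUE)
}

planted_fc_at <- function(fc, timepoint, baseline) {
  if (timepoint == baseline) return(1)
  switch(timepoint,
         D20 = fc[["d20"]],
         D35 = fc[["d35"]],
         # intermediate timepoints (D13) ride the geometric midpoint of
         # the baseline-to-D20 leg
         sqrt(fc[["d20"]]))
}

#' Simulate an expression matrix with planted trajectory classes
#'
#' Generates gene-by-sample abundances for every (model, timepoint,
#' replicate): the gene's mean at a timepoint is
#' `baseline_mean * planted_fc(timepoint)` and each replicate draws
#' `mean * 2^eps` with `eps ~ Normal(0, noise_sd)` (log-normal noise on
#' the linear scale). The ground truth — category, TF flag and planted
#' FCs per gene — is returned alongside, so downstream stages can be
#' scored against it.
#'
#' @param config A [simulation_config()].
#' @return List of class `"simulation"` with elements `matrix`
#'   (genes x samples), `sheet` (sample sheet data.frame) and `truth`
#'   (data.frame `gene_id`, `category`, `is_tf`, `planted_fc_d20`,
#'   `planted_fc_d35`, `discordant`).
#' @export
simulate_expression <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  counts <- config$n_genes_per_category
  counts <- counts[counts > 0L]
  n_genes <- sum(counts)
  truth <- data.frame(
    gene_id = sprintf("SIMG%05d", seq_len(n_genes)),
    category = rep(names(counts), counts),
    stringsAsFactors = FALSE)
  # deterministic TF flag: the first ceiling(fraction * n) genes of each
  # category, so the flag does not depend on the noise stream
  truth$is_tf <- unlist(lapply(counts, function(n) {
    k <- ceiling(config$tf_fraction * n)
    seq_len(n) <= k
  }), use.names = FALSE)
  truth$planted_fc_d20 <- vapply(truth$category,
                                 function(cat) config$planted_fc[[cat]][["d20"]],
                                 numeric(1L))
  truth$planted_fc_d35 <- vapply(truth$category,
                                 function(cat) config$planted_fc[[cat]][["d35"]],
                                 numeric(1L))
  planted <- which(truth$category != "UNCLASSIFIED")
  n_disc <- floor(config$discordance_fraction * length(planted))
  disc_idx <- if (n_disc > 0L) {
    planted[sample.int(length(planted), n_disc)]
  } else {
    integer(0L)
  }
  truth$discordant <- seq_len(n_genes) %in% disc_idx

  sheet <- expand.grid(replicate = seq_len(config$n_replicates),
                       timepoint = config$timepoints,
                       model = config$models,
                       stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("%s_%s_R%d", sheet$model, sheet$timepoint,
                             sheet$replicate)
  sheet <- sheet[c("sample_id", "model", "timepoint", "replicate")]

  mat <- matrix(0, nrow = n_genes, ncol = nrow(sheet),
                dimnames = list(truth$gene_id, sheet$sample_id))
  flat <- c(d20 = 1, d35 = 1)
  for (j in seq_len(nrow(sheet))) {
    m <- sheet$model[j]
    tp <- sheet$timepoint[j]
    # discordant genes keep their trajectory only in the first model
    fc <- vapply(seq_len(n_genes), function(i) {
      pf <- if (truth$discordant[i] && m != config$models[1L]) {
        flat
      } else {
        c(d20 = truth$planted_fc_d20[i], d35 = truth$planted_fc_d35[i])
      }
      planted_fc_at(pf, tp, config$baseline)
    }, numeric(1L))
    eps <- if (config$noise_sd > 0) {
      stats::rnorm(n_genes, 0, config$noise_sd)
    } else {
      numeric(n_genes)
    }
    mat[, j] <- config$baseline_mean * fc * 2^eps
  }
  structure(list(matrix = mat, sheet = sheet, truth = truth,
                 config = config),
            class = "simulation")
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf("Simulated experiment: %d genes x %d samples (%d models, %d timepoints, %d replicates)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$config$models),
              length(x$config$timepoints), x$config$n_replicates))
  invisible(x)
}

#' Transcription-factor registry implied by a simulation truth
#'
#' @param truth Truth data.frame from [simulate_expression()].
#' @return Sorted symbol vector with attribute `source_label`.
#' @export
tf_registry_from_truth <- function(truth) {
  symbols <- sort(truth$gene_id[truth$is_tf])
  if (!length(symbols)) {
    stop("truth table flags no transcription factors")
  }
  structure(symbols, source_label = "simulated")
}

#' Plant enriched gene sets from a simulation truth
#'
#' Emits one gene set per non-empty trajectory category, containing a
#' fraction of that category's genes plus randomly drawn background
#' genes from outside the category. Each set is over-represented in its
#' own category by construction, giving the enrichment stage a positive
#' control.
#'
#' @param truth Truth data.frame from [simulate_expression()].
#' @param fraction Fraction of each category's genes included in its
#'   set, in (0, 1].
#' @param n_background Number of out-of-category genes added to each
#'   set.
#' @param seed Optional RNG seed for the sampling.
#' @return A `"gene_set_collection"` (one set per non-empty category,
#'   named `<CATEGORY>_SET`).
#' @export
plant_enriched_sets <- function(truth, fraction = 0.8, n_background = 25,
                                seed = NULL) {
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  sets <- list()
  for (cat in trajectory_categories()) {
    members <- truth$gene_id[truth$category == cat]
    if (!length(members)) next
    k <- max(1L, round(fraction * length(members)))
    core <- if (k >= length(members)) members else sample(members, k)
    pool <- setdiff(truth$gene_id, members)
    bg <- if (n_background > 0L && length(pool)) {
      sample(pool, min(n_background, length(pool)))
    } else {
      character(0L)
    }
    sets[[paste0(cat, "_SET")]] <-
      list(description = paste("planted set enriched in", cat),
           genes = c(sort(core), sort(bg)))
  }
  structure(sets, class = "gene_set_collection")
}

#' Write the simulation truth table as TSV
#' @param truth Truth data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
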