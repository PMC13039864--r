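# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the Welch test is recomputed from the textbook
# formulas, the hypergeometric tail by exhaustive subset enumeration, BH by
# the step-up definition, and set operations by explicit double loops.

# Textbook Welch statistic + Welch-Satterthwaite df on log2(x + 1)
welch_p_oracle <- function(a, b) {
  x <- log2(a + 1)
  y <- log2(b + 1)
  nx <- length(x)
  ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Hand-enumerated category truth table (nested conditionals, written
# directly from the category definitions, independent of classify_gene)
oracle_classify <- function(s20, s35, r) {
  if (s20 == "UP" && s35 == "UP") {
    if (r > 1.5) "UP_BOTH_INCREASING"
    else if (r < 0.5) "UP_BOTH_DECREASING"
    else "UP_BOTH_NEAR_CONSTANT"
  } else if (s20 == "UP" && s35 == "NS") "UP_D20_ONLY"
  else if (s20 == "NS" && s35 == "UP") "UP_D35_ONLY"
  else if (s20 == "DOWN" && s35 == "DOWN") "DOWN_BOTH"
  else if (s20 == "DOWN" && s35 == "NS") "DOWN_D20_ONLY"
  else if (s20 == "NS" && s35 == "DOWN") "DOWN_D35_ONLY"
  else if (s20 == "NS" && s35 == "NS") "UNCLASSIFIED"
  else "DISCORDANT"
}

# P[X >= k] for Hypergeometric(N, K, n) by enumerating every n-subset of
# 1..N against the marked set 1..K
hypergeom_tail_by_enumeration <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k <= 0L))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Benjamini-Hochberg step-up from its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Per-category intersection across models by explicit double loop
brute_intersect <- function(assignments) {
  labels <- unique(unlist(lapply(assignments, function(a) a$category)))
  out <- list()
  for (l in labels) {
    genes <- assignments[[1]]$gene_id[assignments[[1]]$category == l]
    keep <- character(0)
    for (g in genes) {
      in_all <- TRUE
      for (a in assignments[-1]) {
        hit <- a$category[a$gene_id == g]
        if (length(hit) != 1L || hit != l) in_all <- FALSE
      }
      if (in_all) keep <- c(keep, g)
    }
    out[[l]] <- sort(keep)
  }
  out
}

# Cross-condition knockdown intersection by explicit loops (log2 scale)
brute_knockdown <- function(tables, p_max = 0.05, lfc_min = 0.5) {
  per_cond <- lapply(tables, function(tbl) {
    lfc <- log2(tbl$fold_change)
    list(down = tbl$gene_id[tbl$p_adjusted < p_max & lfc < -lfc_min],
         up = tbl$gene_id[tbl$p_adjusted < p_max & lfc > lfc_min])
  })
  pick <- function(which) {
    first <- per_cond[[1]][[which]]
    keep <- character(0)
    for (g in first) {
      if (all(vapply(per_cond[-1], function(pc) g %in% pc[[which]],
                     logical(1)))) {
        keep <- c(keep, g)
      }
    }
    sort(keep)
  }
  list(common_down = pick("down"), common_up = pick("up"))
}
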