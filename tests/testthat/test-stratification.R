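test_that("status calls respect FC and p cutoffs, with boundary strictness", {
  th <- trajectory_thresholds()
  expect_equal(call_status(3, 0.01, th), "UP")
  expect_equal(call_status(0.4, 0.01, th), "DOWN")
  expect_equal(call_status(0.4, 0.2, th), "NS")   # fails p
  expect_equal(call_status(1.2, 0.001, th), "NS") # fails FC
  # FC exactly at the cutoff: excluded under the strict reading,
  # included under the inclusive flag
  expect_equal(call_status(2, 0.01, th), "NS")
  expect_equal(call_status(0.5, 0.01, th), "NS")
  inclusive <- trajectory_thresholds(strict_fc = FALSE)
  expect_equal(call_status(2, 0.01, inclusive), "UP")
  expect_equal(call_status(0.5, 0.01, inclusive), "DOWN")
})

test_that("change-in-FC ratio bins use inclusive near-constant boundaries", {
  expect_equal(change_in_fc(2, 6), 3)
  expect_equal(bin_ratio(3), "INCREASING")
  expect_equal(bin_ratio(1.5), "NEAR_CONSTANT")
  expect_equal(bin_ratio(0.5), "NEAR_CONSTANT")
  expect_equal(bin_ratio(0.4), "DECREASING")
  expect_equal(bin_ratio(1), "NEAR_CONSTANT")
  expect_error(bin_ratio(0), "> 0")
  expect_error(bin_ratio(-2), "> 0")
  expect_error(change_in_fc(0, 3), "> 0")
})

test_that("classification matches the hand-enumerated 3x3 truth table", {
  statuses <- c("UP", "DOWN", "NS")
  for (s20 in statuses) {
    for (s35 in statuses) {
      for (r in c(3, 1, 0.3)) {
        expect_equal(classify_gene(s20, s35, r),
                     oracle_classify(s20, s35, r),
                     info = sprintf("(%s, %s, r=%g)", s20, s35, r))
      }
    }
  }
  expect_error(classify_gene("UP", "MAYBE", 1), "UP, DOWN or NS")
  # (UP, UP) without a usable ratio is an error, not a silent NA
  expect_error(classify_gene("UP", "UP", NA_real_), "ratio")
})

test_that("model intersection equals a brute-force double loop", {
  set.seed(41)
  labels <- trajectory_categories(include_bookkeeping = TRUE)
  genes <- sprintf("G%03d", 1:200)
  a1 <- random_assignment(genes, sample(labels, 200, replace = TRUE))
  a2 <- random_assignment(genes, sample(labels, 200, replace = TRUE))
  got <- intersect_models(list(m1 = a1, m2 = a2))
  want <- brute_intersect(list(a1, a2))
  for (l in labels) {
    expect_equal(got[[l]], if (is.null(want[[l]])) character(0) else want[[l]],
                 info = l)
  }
})

test_that("intersection demands agreement including the up-both bin", {
  a1 <- random_assignment("G001", "UP_BOTH_INCREASING")
  a2 <- random_assignment("G001", "UP_BOTH_NEAR_CONSTANT")
  got <- intersect_models(list(m1 = a1, m2 = a2))
  expect_true(all(vapply(got, length, integer(1)) == 0L))
  # identical assignments intersect to themselves
  same <- intersect_models(list(m1 = a1, m2 = a1))
  expect_equal(same$UP_BOTH_INCREASING, "G001")
  expect_error(intersect_models(list(m1 = a1)), "per-model")
})

test_that("stratify is complete, deterministic, and correct end-to-end", {
  sim <- simulate_expression(simulation_config(
    n_genes_per_category = small_counts(5L, 15L), noise_sd = 0, seed = 12L))
  cr <- run_contrasts(sim$matrix, sim$sheet)
  st <- stratify(cr)
  for (m in names(st$per_model)) {
    df <- st$per_model[[m]]
    expect_setequal(df$gene_id, rownames(sim$matrix))
    expect_true(all(df$category %in%
                      trajectory_categories(include_bookkeeping = TRUE)))
  }
  expect_identical(stratify(cr)$per_model, st$per_model)
  expect_equal(recovery_fraction(sim, st), 1)
  # the three up-both sets partition the up-both genes
  df <- st$per_model[[1]]
  upboth <- df$gene_id[df$status_d20 == "UP" & df$status_d35 == "UP"]
  bins <- df$category[match(upboth, df$gene_id)]
  expect_true(all(startsWith(bins, "UP_BOTH_")))
  expect_equal(sort(unlist(st$intersected[c("UP_BOTH_NEAR_CONSTANT",
                                            "UP_BOTH_INCREASING",
                                            "UP_BOTH_DECREASING")],
                           use.names = FALSE)),
               sort(intersect(upboth,
                              st$per_model[[2]]$gene_id[
                                st$per_model[[2]]$status_d20 == "UP" &
                                st$per_model[[2]]$status_d35 == "UP"])))
})

test_that("threshold changes move gene sets monotonically", {
  set.seed(51)
  n <- 400
  fc <- 2^stats::runif(n, -3, 3)
  p <- stats::runif(n)
  base <- trajectory_thresholds()
  s0 <- call_status(fc, p, base)
  # raising fc_up can only shrink the UP set
  s1 <- call_status(fc, p, trajectory_thresholds(fc_up = 3))
  expect_true(all(which(s1 == "UP") %in% which(s0 == "UP")))
  # lowering p_max can only shrink both UP and DOWN sets
  s2 <- call_status(fc, p, trajectory_thresholds(p_max = 0.01))
  expect_true(all(which(s2 == "UP") %in% which(s0 == "UP")))
  expect_true(all(which(s2 == "DOWN") %in% which(s0 == "DOWN")))
})

test_that("discordant genes can optionally join the matching only-sets", {
  df <- data.frame(gene_id = c("A1", "B2"),
                   fc_d20 = c(3, 0.2), p_d20 = c(0.01, 0.01),
                   fc_d35 = c(0.2, 3), p_d35 = c(0.01, 0.01),
                   stringsAsFactors = FALSE)
  th <- trajectory_thresholds()
  df$status_d20 <- call_status(df$fc_d20, df$p_d20, th)
  df$status_d35 <- call_status(df$fc_d35, df$p_d35, th)
  df$ratio <- change_in_fc(df$fc_d20, df$fc_d35)
  df$category <- classify_gene(df$status_d20, df$status_d35, df$ratio, th)
  expect_equal(df$category, c("DISCORDANT", "DISCORDANT"))
  plain <- category_sets(df)
  expect_equal(plain$DISCORDANT, c("A1", "B2"))
  expect_length(plain$UP_D20_ONLY, 0L)
  counted <- category_sets(df, count_discordant_in_only = TRUE)
  expect_equal(counted$UP_D20_ONLY, "A1")
  expect_equal(counted$DOWN_D35_ONLY, "A1")
  expect_equal(counted$DOWN_D20_ONLY, "B2")
  expect_equal(counted$UP_D35_ONLY, "B2")
  expect_equal(counted$DISCORDANT, c("A1", "B2"))
})
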