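make_report_fixture <- function(n_genes = 6L, seed = 81L) {
  set.seed(seed)
  sheet <- expand.grid(replicate = 1:2, timepoint = c("D0", "D20", "D35"),
                       model = c("hESC", "hiPSC"), stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("%s_%s_R%d", sheet$model, sheet$timepoint,
                             sheet$replicate)
  sheet <- sheet[c("sample_id", "model", "timepoint", "replicate")]
  genes <- sprintf("G%02d", seq_len(n_genes))
  mat <- matrix(stats::runif(n_genes * nrow(sheet), 0, 50),
                nrow = n_genes, dimnames = list(genes, sheet$sample_id))
  list(mat = mat, sheet = sheet, genes = genes)
}

test_that("mean-FPKM ordering puts the most abundant genes first", {
  fx <- make_report_fixture(2L)
  fx$mat["G01", ] <- 5
  fx$mat["G02", ] <- 10
  ord <- order_heatmap(c("G01", "G02"), fx$mat, fx$sheet, rule = "mean_fpkm")
  expect_equal(ord$genes, c("G02", "G01"))
  # top_n larger than the category returns the full list
  expect_equal(ord$top, ord$genes)
  ord3 <- order_heatmap(c("G01", "G02"), fx$mat, fx$sheet, top_n = 1)
  expect_equal(ord3$top, "G02")
})

test_that("heatmap ordering equals an independent sort oracle", {
  fx <- make_report_fixture(50L, seed = 82L)
  d20 <- fx$sheet$sample_id[fx$sheet$timepoint == "D20"]
  d35 <- fx$sheet$sample_id[fx$sheet$timepoint == "D35"]
  # oracle: plain data.frame sort on independently computed keys
  mean_key <- rowMeans(fx$mat[, c(d20, d35)])
  delta_key <- rowMeans(fx$mat[, d35]) - rowMeans(fx$mat[, d20])
  want_mean <- fx$genes[order(-mean_key, fx$genes)]
  want_up <- fx$genes[order(-delta_key, fx$genes)]
  want_down <- fx$genes[order(delta_key, fx$genes)]
  expect_equal(order_heatmap(fx$genes, fx$mat, fx$sheet,
                             rule = "mean_fpkm")$genes, want_mean)
  expect_equal(order_heatmap(fx$genes, fx$mat, fx$sheet,
                             rule = "delta_d35_d20",
                             direction = "increase")$genes, want_up)
  expect_equal(order_heatmap(fx$genes, fx$mat, fx$sheet,
                             rule = "delta_d35_d20",
                             direction = "decrease")$genes, want_down)
})

test_that("ordering is a permutation, breaks ties by symbol, and validates", {
  fx <- make_report_fixture(8L, seed = 83L)
  fx$mat[] <- 7  # all-tied keys
  ord <- order_heatmap(fx$genes, fx$mat, fx$sheet)
  expect_equal(ord$genes, sort(fx$genes))
  ord2 <- order_heatmap(rev(fx$genes), fx$mat, fx$sheet)
  expect_setequal(ord2$genes, fx$genes)
  expect_error(order_heatmap(c("G01", "NOPE"), fx$mat, fx$sheet), "absent")
  expect_error(order_heatmap(fx$genes, fx$mat, fx$sheet, rule = "banana"))
})

test_that("knockdown filter enforces both cutoffs with strict boundaries", {
  tbl <- data.frame(
    gene_id = c("A1", "B2", "C3", "D4"),
    fold_change = c(2^-1, 2^-0.5, 2^1, 2^0.4),  # log2 FC -1, -0.5, 1, 0.4
    p_value = 0.001,
    p_adjusted = c(0.01, 0.01, 0.5, 0.01),
    stringsAsFactors = FALSE)
  got <- knockdown_intersect(list(sh1 = tbl))
  expect_equal(got$common_down, "A1")     # B2 sits exactly at |log2FC| = 0.5
  expect_length(got$common_up, 0L)        # C3 fails adjusted p, D4 fails FC
  expect_error(knockdown_intersect(list(sh1 = tbl[, -4])), "p_adjusted")
})

test_that("three-condition intersection equals the brute-force oracle", {
  set.seed(91)
  genes <- sprintf("G%03d", 1:100)
  tables <- lapply(1:3, function(i) random_de_table(genes))
  names(tables) <- sprintf("sh%d", 1:3)
  got <- knockdown_intersect(tables)
  want <- brute_knockdown(tables)
  expect_equal(got$common_down, want$common_down)
  expect_equal(got$common_up, want$common_up)
})

test_that("adding a knockdown condition can only shrink the common lists", {
  set.seed(92)
  genes <- sprintf("G%03d", 1:150)
  tables <- lapply(1:3, function(i) random_de_table(genes))
  two <- knockdown_intersect(tables[1:2])
  three <- knockdown_intersect(tables)
  expect_true(all(three$common_down %in% two$common_down))
  expect_true(all(three$common_up %in% two$common_up))
  # relaxing the quorum recovers at least the strict intersection
  loose <- knockdown_intersect(tables, n_conditions_required = 2)
  expect_true(all(three$common_down %in% loose$common_down))
})

test_that("a log2_fold_change column takes precedence over linear FC", {
  tbl <- data.frame(gene_id = c("A1", "B2"),
                    fold_change = c(1, 1),
                    log2_fold_change = c(-2, 2),
                    p_value = 0.001, p_adjusted = 0.001,
                    stringsAsFactors = FALSE)
  got <- knockdown_intersect(list(sh1 = tbl))
  expect_equal(got$common_down, "A1")
  expect_equal(got$common_up, "B2")
})

test_that("ddct follows the closed-form identities", {
  ct <- data.frame(sample = sprintf("s%d", 1:4),
                   condition = c("ctrl", "ctrl", "kd", "kd"),
                   target_ct = c(20, 22, 24, 26),
                   reference_ct = c(15, 17, 15, 17),
                   stringsAsFactors = FALSE)
  out <- ddct(ct, "ctrl")
  # control samples sit at the control mean dCt = 5 -> expression 1
  expect_equal(out$rel_expr[1:2], c(1, 1))
  # ddCt of 4 (kd samples) -> 2^-4
  expect_equal(out$delta_delta_ct[3:4], c(4, 4))
  expect_equal(out$rel_expr[3:4], c(2^-4, 2^-4))
  expect_error(ddct(ct, "missing"), "absent")
  expect_error(ddct(ct[, -3], "ctrl"), "missing column")
})

test_that("ddct matches independent spreadsheet arithmetic and calibrates", {
  set.seed(93)
  ct <- data.frame(sample = sprintf("s%d", 1:9),
                   condition = rep(c("ctrl", "shA", "shB"), each = 3),
                   target_ct = stats::runif(9, 18, 30),
                   reference_ct = stats::runif(9, 14, 18),
                   stringsAsFactors = FALSE)
  out <- ddct(ct, "ctrl")
  # independent arithmetic, spelled out step by step
  dct <- ct$target_ct - ct$reference_ct
  cal <- sum(dct[1:3]) / 3
  expect_equal(out$rel_expr, 2^(-(dct - cal)), tolerance = 1e-12)
  # geometric mean of the control condition is exactly 1
  expect_equal(exp(mean(log(out$rel_expr[out$condition == "ctrl"]))), 1,
               tolerance = 1e-12)
})
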