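# QC boundary behavior, Wilcoxon DE statistics, entropy specificity and
# signature-gene selection rules.

test_that("qc_filter applies the printed boundaries exactly", {
  counts <- matrix(5, 10, 5)
  expr <- make_expr(counts, n_detected = c(100, 200, 1000, 4000, 5000))
  kept <- qc_filter(expr, min_cells_per_gene = 0)
  expect_equal(kept$cell_meta$n_detected_genes, c(200, 1000, 4000))

  # mito exactly at the bound is removed (strictly less than)
  expr2 <- make_expr(matrix(5, 4, 3), mito = c(0.0999, 0.10, 0.101),
                     n_detected = rep(1000L, 3))
  expect_identical(qc_filter(expr2, min_cells_per_gene = 0)$cell_meta$cell_id, "c001")

  # gene detected in exactly min_cells_per_gene cells is removed (strict >)
  m <- rbind(g_in3 = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
             g_in4 = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
             g_all = rep(1, 10))
  expr3 <- make_expr(m, n_detected = rep(1000L, 10))
  expect_identical(rownames(qc_filter(expr3)$counts), c("g_in4", "g_all"))
})

test_that("qc_filter is idempotent and warns instead of failing when empty", {
  sc <- simulate_sc(sc_sim_config(n_types = 2, cells_per_type = 80,
                                  n_genes = 300, seed = 3))
  once <- qc_filter(sc, min_genes = 100, max_genes = 250, max_mito = 0.06)
  twice <- qc_filter(once, min_genes = 100, max_genes = 250, max_mito = 0.06)
  expect_identical(once$counts, twice$counts)
  expect_identical(once$cell_meta, twice$cell_meta)

  expect_warning(empty <- qc_filter(sc, min_genes = 1e6), "all")
  expect_identical(ncol(empty$counts), 0L)
})

test_that("Wilcoxon statistic matches brute-force pair counting and wilcox.test", {
  x <- c(3.1, 0.2, 5.5, 2.2, 9.0, 1.1)
  y <- c(0.0, 2.2, 4.4, 0.7, 0.2, 3.3)
  mat <- matrix(c(x, y), nrow = 1)
  w <- cldimmune:::row_wilcox(mat, c(rep(TRUE, 6), rep(FALSE, 6)))
  expect_equal(unname(w$statistic), oracle_rank_sum_u(x, y))
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(unname(w$statistic), unname(ref$statistic))
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
})

test_that("de_stats: constant genes are null, planted markers are found", {
  counts <- rbind(flat = rep(4L, 12),
                  up = c(rep(10L, 6), rep(1L, 6)))
  # equal library sizes so normalization keeps 'flat' constant
  counts <- rbind(counts, filler = 20L - colSums(counts))
  expr <- make_expr(counts, type = rep(c("A", "B"), each = 6))
  tab <- de_stats(expr)
  flat <- tab[tab$gene == "flat", ]
  expect_true(all(flat$avg_log2FC == 0))
  expect_true(all(flat$p_adj == 1))

  # planted marker recovery across seeds: adjusted p < 0.01 and log2FC in [2,4]
  hits <- sapply(1:20, function(s) {
    sc <- simulate_sc(sc_sim_config(n_types = 4, cells_per_type = 200,
                                    n_genes = 400, markers_per_type = 5,
                                    marker_log2fc = 3, seed = s))
    tab <- de_stats(sc)
    truth <- attr(sc, "truth")$markers
    sub <- tab[tab$cluster == "type1" & tab$gene %in% truth$type1, ]
    all(sub$p_adj < 0.01 & sub$avg_log2FC >= 2 & sub$avg_log2FC <= 4)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("entropy specificity: analytic limits, scale invariance, majorization", {
  expect_equal(entropy_specificity(c(1, 0, 0, 0)), 2, tolerance = 1e-6)
  expect_equal(entropy_specificity(c(3, 3, 3, 3)), 0, tolerance = 1e-12)
  expect_equal(entropy_specificity(c(5, 5, 0, 0)), 1, tolerance = 1e-6)
  expect_equal(entropy_specificity(c(0, 0, 0, 0)), 0)
  expect_error(entropy_specificity(c(-1, 1)), "non-negative")

  # invariant to scaling all means by a positive constant
  v <- c(4, 1, 0.5, 0.01)
  expect_equal(entropy_specificity(v), entropy_specificity(137 * v), tolerance = 1e-9)

  # strictly decreases as mass spreads (each vector majorizes the next)
  chain <- list(c(8, 0, 0, 0), c(5, 3, 0, 0), c(4, 2, 2, 0), c(2, 2, 2, 2))
  d <- vapply(chain, entropy_specificity, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("select_signatures enforces the class-specific rules", {
  tab <- data.frame(
    cluster = "m1",
    gene = c("good", "pct2bad", "weakfc", "ALB"),
    avg_log2FC = c(2, 2, 0.7, 3),
    pct1 = c(0.8, 0.6, 0.9, 0.9),
    pct2 = c(0.2, 0.6, 0.1, 0.1),
    p_adj = c(1e-5, 1e-5, 1e-5, 1e-9),
    entropy_diff = c(1, 2, 3, 4), stringsAsFactors = FALSE)

  mac <- suppressWarnings(select_signatures(tab, "macrophage"))
  expect_identical(mac$m1, "good")            # pct2 rule rejects, ALB excluded

  tc <- select_signatures(tab, "tcell")
  expect_setequal(tc$m1, c("good", "pct2bad", "weakfc"))  # no pct rule for T cells
  # ranked by decreasing entropy difference
  expect_identical(tc$m1, c("weakfc", "pct2bad", "good"))
  expect_identical(select_signatures(tab, "tcell", top_n_by_entropy = 1)$m1, "weakfc")
})

test_that("planted markers are recovered with high sensitivity and precision", {
  sc <- simulate_sc(sc_sim_config(n_types = 3, cells_per_type = 200,
                                  n_genes = 1000, markers_per_type = 10,
                                  marker_log2fc = 3, seed = 21))
  sel <- unlist(select_signatures(de_stats(sc), "macrophage"))
  tru <- unlist(attr(sc, "truth")$markers)
  expect_gte(mean(tru %in% sel), 0.9)   # sensitivity
  expect_gte(mean(sel %in% tru), 0.9)   # precision
})
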