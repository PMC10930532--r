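log2p1_matrix <- function(v) expression_matrix(v, "log2p1")

test_that("marker grouping uses inclusive mean +/- k*SD thresholds", {
  vals <- c(-2, -1, -0.99, 0, 0.99, 1, 2)
  vals <- (vals - mean(vals)) / sd(vals) * 1 + 0          # mean 0, SD 1
  vals <- c(vals, -vals)                                  # keep mean 0, SD ~1
  vals <- vals / sd(vals)
  v <- rbind(M = vals + 5, OTHER = seq_along(vals))
  colnames(v) <- sprintf("S%02d", seq_along(vals))
  g <- assign_groups(log2p1_matrix(v), "M")
  expect_equal(unname(g$groups[vals >= 1]), rep("high", sum(vals >= 1)))
  expect_equal(unname(g$groups[abs(vals) < 1]),
               rep("neither", sum(abs(vals) < 1)))
  expect_true(all(g$groups[vals <= -1] == "low"))
  const <- matrix(2, 1, 10, dimnames = list("M", sprintf("S%02d", 1:10)))
  expect_error(assign_groups(log2p1_matrix(const), "M"), "degenerate")

  # standard normal marker: high fraction approaches Phi(-1)
  set.seed(101)
  n <- 10000
  v2 <- rbind(M = rnorm(n) + 8, X = rnorm(n))
  colnames(v2) <- sprintf("S%05d", 1:n)
  g2 <- assign_groups(log2p1_matrix(v2), "M")
  expect_lt(abs(mean(g2$groups == "high") - pnorm(-1)), 0.01)
  expect_lt(abs(mean(g2$groups == "low") - pnorm(-1)), 0.01)
})

test_that("group comparison is a label-symmetric Mann-Whitney with BH", {
  set.seed(55)
  n <- 60
  marker <- c(rnorm(10, 10, 0.1), rnorm(40, 5, 0.5), rnorm(10, 0, 0.1))
  genes <- matrix(rnorm(5 * n, 4), 5,
                  dimnames = list(sprintf("G%d", 1:5), NULL))
  genes[1, ] <- genes[1, ] + 2 * (marker > 8)  # shifted in the high group
  v <- rbind(M = marker, genes)
  colnames(v) <- sprintf("S%02d", 1:n)
  x <- log2p1_matrix(pmax(v, 0))
  grouping <- assign_groups(x, "M")
  res <- group_compare(x, grouping)
  expect_lt(res$fdr[res$gene == "G1"], 0.05)
  expect_equal(res$gene[which.min(res$p)], "G1")  # planted gene dominates
  expect_gt(res$median_high[res$gene == "G1"],
            res$median_low[res$gene == "G1"])

  # swapping group labels leaves the two-sided p unchanged
  swapped <- grouping
  swapped$groups[grouping$groups == "high"] <- "low"
  swapped$groups[grouping$groups == "low"] <- "high"
  expect_equal(group_compare(x, swapped)$p, res$p, tolerance = 1e-12)
  expect_error(group_compare(x, local({
    g <- grouping; g$groups[g$groups == "high"] <- "neither"; g
  })), ">=3")
})

test_that("planted expression shifts are detected with high power", {
  set.seed(66)
  n_planted <- 40
  marker <- c(rnorm(30, 9, 0.2), rnorm(30, 1, 0.2))
  planted <- matrix(rnorm(n_planted * 60, 4), n_planted)
  planted[, marker > 5] <- planted[, marker > 5] + 2  # 2 SD shift
  v <- rbind(M = marker, planted)
  rownames(v) <- c("M", sprintf("P%02d", 1:n_planted))
  colnames(v) <- sprintf("S%02d", 1:60)
  x <- log2p1_matrix(pmax(v, 0))
  res <- group_compare(x, assign_groups(x, "M", k = 0.9))
  expect_gte(mean(res$fdr < 0.05), 0.95)
})

test_that("Spearman against the marker handles monotone and constant genes", {
  v <- rbind(M = 1:10, UP = (1:10)^3, DOWN = -(exp(1:10)), FLAT = rep(2, 10))
  colnames(v) <- sprintf("S%02d", 1:10)
  rep <- spearman_vs_marker(log2p1_matrix(v), "M", nperm = 100, seed = 4)
  expect_equal(rep$spearman_r[rep$gene == "UP"], 1)
  expect_equal(rep$spearman_r[rep$gene == "DOWN"], -1)
  expect_true(is.na(rep$spearman_r[rep$gene == "FLAT"]))
  expect_true(rep$flagged[rep$gene == "FLAT"])
  expect_equal(rep$permutation_p[rep$gene == "FLAT"], 1)
  expect_equal(rep$bin[match(c("UP", "DOWN", "FLAT"), rep$gene)],
               c("strong", "weak", "weak"))
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(202)
  n <- 50; n_genes <- 200
  v <- matrix(rnorm((n_genes + 1) * n), n_genes + 1,
              dimnames = list(c("M", sprintf("G%03d", 1:n_genes)),
                              sprintf("S%02d", 1:n)))
  rep <- spearman_vs_marker(log2p1_matrix(v), "M", nperm = 500, seed = 7)
  hits <- sum(rep$permutation_p < 0.05)
  ci <- qbinom(c(0.005, 0.995), n_genes, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("correlation bins split at 0.3 and 0.4 inclusively", {
  expect_equal(correlation_bin(c(0.4, 0.39, 0.3, 0.299, -1, NA)),
               c("strong", "moderate", "moderate", "weak", "weak", "weak"))
})

test_that("similarity matrix is a sorted, symmetric rank-then-Pearson table", {
  set.seed(9)
  v <- matrix(rnorm(5 * 20), 5,
              dimnames = list(c("M", "A", "B", "C", "D"),
                              sprintf("S%02d", 1:20)))
  x <- log2p1_matrix(pmax(v + 5, 0))
  m <- similarity_matrix(x, c("A", "B", "C", "D"), "M")
  expect_equal(unname(diag(m)), rep(1, 5))
  expect_equal(m, t(m))
  # rank-then-Pearson oracle for one pair
  expect_equal(m["A", "B"],
               cor(rank(x$values["A", ]), rank(x$values["B", ])),
               tolerance = 1e-12)
  # sorted by anchor correlation, anchor first (r = 1 with itself)
  anchor_r <- attr(m, "anchor_r")
  expect_equal(rownames(m)[1], "M")
  expect_equal(anchor_r, sort(anchor_r, decreasing = TRUE))
  # anchor row reproduces spearman_vs_marker r exactly
  rep <- spearman_vs_marker(x, "M", c("A", "B", "C", "D"), nperm = 50, seed = 1)
  expect_equal(unname(m["M", rep$gene]), rep$spearman_r, tolerance = 1e-12)
})

test_that("Spearman r is invariant under monotone per-gene transforms", {
  set.seed(14)
  v <- matrix(rnorm(3 * 30, 5), 3,
              dimnames = list(c("M", "A", "B"), sprintf("S%02d", 1:30)))
  x1 <- log2p1_matrix(pmax(v, 0))
  v2 <- v; v2["A", ] <- exp(v2["A", ])
  x2 <- log2p1_matrix(pmax(v2, 0))
  r1 <- spearman_vs_marker(x1, "M", nperm = 50, seed = 3)
  r2 <- spearman_vs_marker(x2, "M", nperm = 50, seed = 3)
  expect_equal(r1$spearman_r, r2$spearman_r, tolerance = 1e-12)
})

test_that("the strong-correlation venn counts match brute-force sets", {
  ra <- data.frame(gene = c("A", "B", "C", "D"),
                   spearman_r = c(0.5, 0.2, 0.4, 0.45))
  rb <- data.frame(gene = c("A", "B", "C", "D"),
                   spearman_r = c(0.2, 0.6, 0.4, 0.41))
  v <- strong_correlation_venn(ra, rb)
  expect_equal(v$only_a, 1L)  # A
  expect_equal(v$only_b, 1L)  # B
  expect_equal(v$both, 2L)    # C (inclusive >= 0.4 in both), D
  expect_equal(sort(v$genes_both), c("C", "D"))
  expect_error(strong_correlation_venn(ra, rb[1:3, ]), "universes")

  set.seed(30)
  ra2 <- data.frame(gene = sprintf("G%02d", 1:50), spearman_r = runif(50, -1, 1))
  rb2 <- data.frame(gene = sprintf("G%02d", 1:50), spearman_r = runif(50, -1, 1))
  v2 <- strong_correlation_venn(ra2, rb2)
  sa <- ra2$gene[ra2$spearman_r >= 0.4]; sb <- rb2$gene[rb2$spearman_r >= 0.4]
  expect_equal(v2$only_a, length(setdiff(sa, sb)))
  expect_equal(v2$only_b, length(setdiff(sb, sa)))
  expect_equal(v2$both, length(intersect(sa, sb)))
})
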