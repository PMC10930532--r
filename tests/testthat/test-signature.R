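test_that("stand-in DE matches closed-form Welch t and known BH values", {
  x <- toy_expression(seed = 5)
  de <- standin_de(x, paste0("S", 1:3), paste0("S", 4:6))
  # closed-form Welch t on log2(1+TPM) for one gene
  g <- "G007"
  a <- log2(1 + x$values[g, 1:3]); b <- log2(1 + x$values[g, 4:6])
  tt <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(de$p[de$gene == g], 2 * pt(-abs(tt), df), tolerance = 1e-12)
  expect_equal(de$p[de$gene == g],
               t.test(a, b)$p.value, tolerance = 1e-12)
  # identical groups give log2fc 0 everywhere
  de0 <- standin_de(x, paste0("S", 1:3), paste0("S", 1:3))
  expect_true(all(de0$log2fc == 0))
  # BH step-up by hand: p = (.01,.02,.03,.04), m = 4 -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_error(standin_de(x, "S1", paste0("S", 4:6)), ">=2")
})

test_that("orient flips depletion contrasts once and only once", {
  de <- de_table(c("A", "B"), c(-1.5, 2), c(0.01, 0.01), c(0.01, 0.01),
                 orientation = "depletion")
  o <- orient(de)
  expect_equal(o$log2fc, c(1.5, -2))
  expect_error(orient(o), "already oriented")
  act <- orient(de_table("A", 2, 0.01, 0.01, orientation = "activation"))
  expect_equal(act$log2fc, 2)
})

test_that("regulated calls use strict fold-change and FDR cutoffs", {
  de <- orient(de_table(
    c("PASS", "ATBOUND", "ATFDR", "DOWN", "UNDET"),
    log2fc = c(1.1, 1.0, 1.5, -1.2, 3),
    p = rep(0.001, 5),
    fdr = c(0.01, 0.01, 0.05, 0.01, 0.001),
    detected = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  calls <- call_regulated(de)
  expect_equal(calls$up, "PASS")           # 2^1.1 > 2; boundary and FDR=0.05 excluded
  expect_equal(calls$down, "DOWN")
  expect_error(call_regulated(de, fc_threshold = 1), "exceed 1")
})

test_that("consensus requires the anchor plus min_support agreeing supports", {
  mk <- function(id, up = character(), down = character(),
                 undetected = character()) {
    genes <- c("U1", "U2", "U3", "D1", "D2", "BG")
    lfc <- ifelse(genes %in% up, 2, ifelse(genes %in% down, -2, 0))
    fdr <- ifelse(genes %in% c(up, down), 0.001, 0.9)
    orient(de_table(genes, lfc, fdr, fdr, detected = !(genes %in% undetected),
                    contrast_id = id))
  }
  anchor <- mk("anchor", up = c("U1", "U2", "U3"), down = c("D1", "D2"))
  s1 <- mk("s1", up = c("U1", "U2"), down = "D1")
  s2 <- mk("s2", up = c("U1", "U3"), down = c("D1", "D2"))
  s3 <- mk("s3", down = "U2")  # direction conflict for U2
  sig <- derive_consensus(anchor, list(s1, s2, s3), min_support = 2)
  # U1: anchor + s1 + s2 -> in. U2: 1 support + conflict -> out.
  # U3: only one support -> out. D1: two supports -> in. D2: one -> out.
  expect_equal(sig$up$genes, "U1")
  expect_equal(sig$down$genes, "D1")
  expect_equal(sig$provenance$n_support[sig$provenance$gene == "U1"], 2L)

  # up in supports but not in the anchor is never included
  anchor2 <- mk("anchor", up = "U1")
  sig2 <- derive_consensus(anchor2, list(s1, s2, s3), min_support = 2)
  expect_null(sig2$down)
  expect_equal(sig2$up$genes, "U1")

  # a gene not detected in a support counts as non-supporting, not opposing:
  # U1 is up in s1 but undetected in s_nd -> only 1 support -> excluded,
  # while U2 (up and detected in both) stays in
  s_nd <- mk("snd", up = c("U1", "U2"), undetected = "U1")
  sig3 <- derive_consensus(anchor, list(s1, s_nd), min_support = 2)
  expect_equal(sig3$up$genes, "U2")
  expect_error(derive_consensus(anchor, list(s1), min_support = 2),
               "min_support")
})

test_that("tightening thresholds never adds signature genes", {
  suite <- simulate_contrast_suite(n_genes = 300, n_up = 20, n_down = 10,
                                   noise_sd = 0.6, seed = 21)
  anchor <- orient(suite$anchor)
  sups <- lapply(suite$supports, orient)
  base <- derive_consensus(anchor, sups, fc_threshold = 2, fdr_threshold = 0.05)
  for (fc in c(2.5, 3, 4)) {
    tight <- derive_consensus(anchor, sups, fc_threshold = fc,
                              fdr_threshold = 0.05)
    expect_true(all((tight$up$genes %||% character()) %in%
                      (base$up$genes %||% character())))
    expect_true(all((tight$down$genes %||% character()) %in%
                      (base$down$genes %||% character())))
  }
  tight <- derive_consensus(anchor, sups, fdr_threshold = 0.001)
  expect_true(all((tight$up$genes %||% character()) %in%
                    (base$up$genes %||% character())))
})

test_that("depletion orientation equals swapping groups in an activation DE", {
  x <- toy_expression(seed = 13)
  act <- orient(standin_de(x, paste0("S", 1:3), paste0("S", 4:6),
                           orientation = "activation"))
  # same data, groups swapped, declared as a knockdown-style contrast
  dep_raw <- standin_de(x, paste0("S", 4:6), paste0("S", 1:3),
                        orientation = "depletion")
  dep <- orient(dep_raw)
  expect_equal(dep$log2fc, -(-act$log2fc))  # flip of the swapped contrast
  expect_equal(dep$log2fc, act$log2fc, tolerance = 1e-12)
  expect_equal(dep$p, act$p, tolerance = 1e-12)
})

test_that("venn regions partition the union", {
  v <- venn_counts(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(unname(v[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  v2 <- venn_counts(list(A = "a", B = "b", C = "c"))
  expect_equal(unname(v2[c("A&B", "A&C", "B&C", "A&B&C")]), rep(0L, 4))

  set.seed(8)
  sets <- lapply(1:3, function(i) sample(letters, 10))
  names(sets) <- c("A", "B", "C")
  v3 <- venn_counts(sets)
  expect_equal(sum(v3), length(unique(unlist(sets))))
  # brute-force membership enumeration
  uni <- unique(unlist(sets))
  brute <- table(vapply(uni, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, NA)], collapse = "&"),
    ""))
  expect_equal(unname(v3[names(brute)]), unname(as.integer(brute)))
  expect_error(venn_counts(list(A = "a")), "2-4")
})

test_that("signature round-trips through GMT output", {
  suite <- simulate_contrast_suite(n_genes = 200, n_up = 10, n_down = 5,
                                   inclusion_probs = 1, noise_sd = 0, seed = 2)
  sig <- derive_consensus(orient(suite$anchor), lapply(suite$supports, orient))
  f <- tempfile(fileext = ".gmt")
  write_signature(sig, f)
  back <- read_gmt(f)
  expect_equal(back$YAP_TAZ_UP$genes, sig$up$genes)
  expect_equal(back$YAP_TAZ_DOWN$genes, sig$down$genes)
  expect_length(intersect(sig$up$genes, sig$down$genes), 0)
})
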