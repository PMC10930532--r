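# Three-gene toy model: A (+) with promoter near 10000, B (-) downstream of A,
# C on another chromosome.
toy_model <- function() {
  gene_model(
    gene_id = c("A", "B", "C"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(10000L, 30000L, 5000L),
    end = c(20000L, 44000L, 9000L),
    exon_starts = list(c(10000L, 15000L), c(30000L, 40000L), 5000L),
    exon_ends = list(c(11000L, 16000L), c(31000L, 44000L), 9000L))
}

test_that("the priority cascade assigns exactly one category per peak", {
  model <- toy_model()
  peaks <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(9500L, 15010L, 12000L, 20500L, 100000L, 43990L),
    end   = c(9600L, 15050L, 12100L, 20600L, 100200L, 44100L))
  peaks$chrom[6] <- "chr1"
  ann <- annotate_peaks(peaks, model)
  # [tss-500, tss-400) on the + strand gene: inside the +/-1 kb window
  expect_equal(ann$category[1], "Promoter"); expect_equal(ann$gene_id[1], "A")
  # inside an exon of A, no promoter overlap
  expect_equal(ann$category[2], "Exon"); expect_equal(ann$gene_id[2], "A")
  # inside A's body between exons
  expect_equal(ann$category[3], "Intron")
  # past A's 3' end within 3 kb
  expect_equal(ann$category[4], "Downstream"); expect_equal(ann$gene_id[4], "A")
  # far from everything
  expect_equal(ann$category[5], "Intergenic")
  expect_true(is.na(ann$gene_id[5]))
  expect_equal(ann$nearest_gene[5], "B")  # context only
  # overlaps B's promoter (TSS at 43999, - strand): promoter wins
  expect_equal(ann$category[6], "Promoter"); expect_equal(ann$gene_id[6], "B")
  # every peak got exactly one category and counts sum to the peak count
  expect_equal(sum(table(ann$category)), nrow(peaks))
})

test_that("promoter windows are strand-aware and beat gene-body categories", {
  model <- toy_model()
  # on the - strand gene B (TSS 43999), a peak "upstream" in transcription
  # direction sits at larger genomic coordinates
  p <- data.frame(chrom = "chr1", start = 43999L + 200L, end = 43999L + 300L)
  ann <- annotate_peaks(p, model)
  expect_equal(ann$category, "Promoter")
  expect_equal(ann$gene_id, "B")
  # distance is signed downstream-positive along transcription: negative here
  expect_lt(ann$distance_to_tss, 0)

  # a peak overlapping gene A's promoter AND an exon of a hypothetical gene
  # in between: promoter priority beats distance. Construct overlapping pair.
  m2 <- gene_model(gene_id = c("P", "Q"), chrom = c("chr1", "chr1"),
                   strand = c("+", "+"), start = c(10000L, 8000L),
                   end = c(20000L, 9800L),
                   exon_starts = list(10000L, 9000L),
                   exon_ends = list(20000L, 9800L))
  # peak inside Q's exon but also within P's promoter window
  a2 <- annotate_peaks(data.frame(chrom = "chr1", start = 9100L, end = 9200L), m2)
  expect_equal(a2$category, "Promoter")
  expect_equal(a2$gene_id, "P")
})

test_that("overlapping promoters resolve by TSS distance then gene id", {
  m <- gene_model(gene_id = c("NEAR", "FAR"), chrom = c("chr1", "chr1"),
                  strand = c("+", "+"), start = c(10000L, 10800L),
                  end = c(10500L, 12000L))
  a <- annotate_peaks(data.frame(chrom = "chr1", start = 10050L, end = 10150L), m)
  expect_equal(a$gene_id, "NEAR")  # |d| = 99.5 vs 700.5
  # exact tie: equidistant promoters -> lexicographic gene id
  m2 <- gene_model(gene_id = c("BBB", "AAA"), chrom = c("chr1", "chr1"),
                   strand = c("+", "+"), start = c(10000L, 11000L),
                   end = c(10400L, 12000L))
  a2 <- annotate_peaks(data.frame(chrom = "chr1", start = 10450L, end = 10551L), m2)
  expect_equal(a2$gene_id, "AAA")
})

test_that("annotation is invariant under a constant coordinate shift", {
  model <- toy_model()
  set.seed(44)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                      start = sample(1000:50000, 30))
  peaks$end <- peaks$start + sample(200:600, 30, TRUE)
  off <- 12345L
  shifted_model <- gene_model(model$gene_id, model$chrom, model$strand,
                              model$start + off, model$end + off,
                              lapply(model$exon_starts, `+`, off),
                              lapply(model$exon_ends, `+`, off))
  shifted_peaks <- transform(peaks, start = start + off, end = end + off)
  a1 <- annotate_peaks(peaks, model)
  a2 <- annotate_peaks(shifted_peaks, shifted_model)
  expect_equal(a2$category, a1$category)
  expect_equal(a2$gene_id, a1$gene_id)
  expect_equal(a2$distance_to_tss, a1$distance_to_tss)
})

test_that("unknown chromosomes warn and fall through to Intergenic", {
  expect_warning(
    a <- annotate_peaks(data.frame(chrom = "chrUn", start = 1L, end = 100L),
                        toy_model()),
    "absent from the model")
  expect_equal(a$category, "Intergenic")
  expect_true(is.na(a$gene_id))
})

test_that("the gene x dataset matrix thresholds at >=1 assigned peak", {
  model <- toy_model()
  d1 <- annotate_peaks(data.frame(chrom = rep("chr1", 3),
                                  start = c(9500L, 9700L, 9900L),
                                  end = c(9600L, 9800L, 10000L)), model)
  d2 <- annotate_peaks(data.frame(chrom = "chr1",
                                  start = 100000L, end = 100100L), model)
  m <- gene_peak_matrix(list(ds1 = d1, ds2 = d2), c("A", "B", "C"), model)
  expect_equal(unname(m["A", ]), c(1L, 0L))    # 3 promoter peaks -> still 1
  expect_equal(unname(m["B", ]), c(0L, 0L))    # intergenic-nearest only -> 0
  expect_equal(unname(m["C", ]), c(0L, 0L))
  expect_warning(gene_peak_matrix(list(ds1 = d1), c("A", "NOPE"), model),
                 "absent")

  # brute-force recount on a random fixture
  set.seed(3)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                      start = sample(3000:46000, 40))
  peaks$end <- peaks$start + 300L
  ann <- annotate_peaks(peaks, model)
  mm <- gene_peak_matrix(list(a = ann), c("A", "B", "C"), model)
  for (g in c("A", "B", "C"))
    expect_equal(mm[g, "a"],
                 as.integer(any(!is.na(ann$gene_id) & ann$gene_id == g)))
})

test_that("BED and gene-model files round-trip", {
  model <- toy_model()
  f <- tempfile(fileext = ".tsv")
  write_gene_model(model, f)
  back <- read_gene_model(f)
  expect_equal(back$gene_id, model$gene_id)
  expect_equal(back$tss, model$tss)
  expect_equal(back$exon_starts, model$exon_starts)

  peaks <- data.frame(chrom = "chr1", start = 1L, end = 200L, name = "p1")
  b <- tempfile(fileext = ".bed")
  write_bed(peaks, b)
  expect_equal(read_bed(b)$end, 200L)
  expect_error(gene_model("X", "chr1", "+", 100L, 50L), "start < end")
})
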