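# Transcriptomic classification: window/peak intersection, fold changes,
# the logFC-ratio estimator, z-scores, clustering and qPCR NRQs.

test_that("promoter windows extend upstream by strand", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      start = 5000L, end = 8000L, strand = c("+", "-"))
  peaks <- data.frame(chrom = "chr1", start = 3500L, end = 3600L)
  hit <- promoter_peak_intersect(genes, peaks)
  expect_equal(hit$gene_id, "a")          # minus-strand window is [5000,10000)
  down <- data.frame(chrom = "chr1", start = 9500L, end = 9600L)
  expect_equal(promoter_peak_intersect(genes, down)$gene_id, "b")
  expect_error(promoter_peak_intersect(transform(genes, strand = "*"),
                                       peaks), "strand")
  # negative window coordinates are clipped to zero
  near0 <- data.frame(gene_id = "c", chrom = "chr1", start = 100L,
                      end = 900L, strand = "+")
  pk0 <- data.frame(chrom = "chr1", start = 0L, end = 10L)
  expect_equal(nrow(promoter_peak_intersect(near0, pk0)), 1L)
})

test_that("intersection equals a brute-force all-pairs scan", {
  set.seed(71)
  for (rep in 1:3) {
    ng <- 300
    genes <- data.frame(gene_id = sprintf("g%03d", 1:ng),
                        chrom = sample(c("chr1", "chr2"), ng, TRUE),
                        start = sample.int(5e5, ng),
                        strand = sample(c("+", "-"), ng, TRUE))
    genes$end <- genes$start + sample(500:5000, ng, TRUE)
    np <- 150
    peaks <- data.frame(chrom = sample(c("chr1", "chr2"), np, TRUE),
                        start = sample.int(5e5, np))
    peaks$end <- peaks$start + sample(50:400, np, TRUE)
    expect_setequal(promoter_peak_intersect(genes, peaks)$gene_id,
                    oracle_overlap(genes, peaks))
  }
})

test_that("BED round trips preserve coordinates and strand", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(100L, 5000L), end = c(900L, 5600L),
                      strand = c("+", "-"))
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                     genes$end, genes$gene_id, genes$strand), bed)
  back <- read_genes_bed(bed)
  expect_equal(back[, c("gene_id", "chrom", "start", "end", "strand")],
               genes[, c("gene_id", "chrom", "start", "end", "strand")])
  pk <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t60", pk)
  expect_equal(read_peaks_bed(pk), data.frame(chrom = "chr1", start = 10L,
                                              end = 60L))
})

test_that("fold changes against the reference behave as ratios", {
  counts <- cbind(NT_1 = c(100, 200, 400), NT_2 = c(100, 200, 400),
                  M_1 = c(100, 200, 400))
  rownames(counts) <- c("g1", "g2", "g3")
  fc <- log2fc_vs_reference(counts, c("NT", "NT", "M"))
  expect_true(all(fc == 0))
  # one gene doubled at compensated library size: log2FC ~ 1
  counts2 <- cbind(NT_1 = c(10000, 5000, 85000),
                   M_1 = c(20000, 5000, 75000))
  rownames(counts2) <- c("g1", "g2", "g3")
  fc2 <- log2fc_vs_reference(counts2, c("NT", "M"))
  expect_equal(fc2["g1", "M"], 1, tolerance = 0.01)
  expect_error(log2fc_vs_reference(counts, c("A", "A", "B")), "reference")
  expect_error(log2fc_vs_reference(cbind(a = c(0, 0), b = c(1, 1)),
                                   c("NT", "M")), "library")
})

test_that("the logFC-ratio classifier is exact on shifted tables", {
  set.seed(72)
  wt <- setNames(rnorm(215, 1, 0.8), sprintf("g%03d", 1:215))
  same <- classify_mutant(wt, wt)
  expect_equal(same$median_log2fc_ratio, 0)
  expect_equal(same$pearson_r, 1)
  loss <- classify_mutant(wt - 0.47, wt)
  expect_equal(loss$median_log2fc_ratio, -0.47, tolerance = 1e-12)
  expect_equal(loss$call, "loss")
  gain <- classify_mutant(wt + 0.28, wt)
  expect_equal(gain$median_log2fc_ratio, 0.28, tolerance = 1e-12)
  expect_equal(gain$call, "gain")
  expect_true(all(gain$direction == "up"))
})

test_that("the classifier is antisymmetric under swapping arguments", {
  set.seed(73)
  g <- sprintf("g%02d", 1:99)
  a <- setNames(rnorm(99), g)
  b <- setNames(rnorm(99), g)
  ab <- classify_mutant(a, b)
  ba <- classify_mutant(b, a)
  expect_equal(ab$median_log2fc_ratio, -ba$median_log2fc_ratio,
               tolerance = 1e-12)
  expect_equal(ab$pearson_r, ba$pearson_r, tolerance = 1e-12)
  expect_error(classify_mutant(a, b, character()), "empty")
})

test_that("row standardization gives exact zero mean and unit SD", {
  expect_equal(zscore_rows(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(74)
  m <- matrix(rnorm(600), 30)
  z <- zscore_rows(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  mc <- m
  mc[7, ] <- 2
  rownames(mc) <- sprintf("r%02d", 1:30)
  expect_error(zscore_rows(mc), "r07")
})

test_that("clustering places identical columns on adjacent leaves", {
  set.seed(75)
  m <- matrix(rnorm(80), 20, 4)
  m <- cbind(m, m[, 2])  # duplicate column
  colnames(m) <- c("a", "b", "c", "d", "b2")
  cl <- cluster_rows_cols(zscore_rows(m))
  pos <- match(c(2, 5), cl$col_order)
  expect_equal(abs(diff(pos)), 1L)
  # under 2 rows/cols: identity order
  expect_equal(cluster_rows_cols(matrix(1:3, 1))$row_order, 1L)
})

test_that("2x2 clustering reproduces the only possible pairing", {
  m <- matrix(c(0, 0, 3, 3), 2, 2)
  cl <- cluster_rows_cols(m)
  expect_setequal(cl$row_order, 1:2)
  expect_setequal(cl$col_order, 1:2)
})

test_that("a column built to correlate with another co-clusters with it", {
  set.seed(76)
  base <- matrix(rnorm(300), 100, 3)
  colnames(base) <- c("WT", "M1", "M2")
  kkrr <- base[, "WT"] + rnorm(100, 0, 0.2)   # planted structure
  m <- cbind(base, KKRR = kkrr)
  tree <- cluster_rows_cols(zscore_rows(m))$col_tree
  merge1 <- tree$merge[1, ]
  expect_setequal(-merge1, c(1, 4))   # WT and KKRR merge first
})

test_that("NRQ transformation matches hand-computed arithmetic", {
  ct <- expand.grid(sample = c("cal", "s1", "s2"),
                    gene = c("tgt", "ref1", "ref2"),
                    stringsAsFactors = FALSE)
  ct$ct <- c(20, 19, 22,   18, 18, 18.5,   22, 22, 21.5)
  nrq <- nrq_from_ct(ct, c("ref1", "ref2"), "cal")
  # hand-computed: RQ(s, g) = 2^(Ct(cal, g) - Ct(s, g))
  rq <- function(s, g) {
    2^(ct$ct[ct$sample == "cal" & ct$gene == g] -
         ct$ct[ct$sample == s & ct$gene == g])
  }
  for (s in c("cal", "s1", "s2")) {
    norm <- sqrt(rq(s, "ref1") * rq(s, "ref2"))
    for (g in c("tgt", "ref1", "ref2")) {
      expect_equal(nrq[s, g], rq(s, g) / norm, tolerance = 1e-12)
    }
  }
  # all-equal Ct: NRQ is identically 1
  ct1 <- transform(ct, ct = 20)
  expect_true(all(abs(nrq_from_ct(ct1, c("ref1", "ref2"), "cal") - 1) <
                    1e-12))
})

test_that("NRQ special cases and invariances hold", {
  ct <- expand.grid(sample = c("cal", "s1"), gene = c("tgt", "ref"),
                    stringsAsFactors = FALSE)
  ct$ct <- c(20, 19, 20, 20)   # target one cycle earlier in s1
  nrq <- nrq_from_ct(ct, "ref", "cal")
  expect_equal(nrq["s1", "tgt"], 2, tolerance = 1e-12)
  # a constant added to every Ct of one sample cancels
  ct2 <- ct
  ct2$ct[ct2$sample == "s1"] <- ct2$ct[ct2$sample == "s1"] + 1.7
  expect_equal(nrq_from_ct(ct2, "ref", "cal")["s1", "tgt"], 2,
               tolerance = 1e-12)
  # missing Ct drops the sample with a warning
  ct3 <- rbind(ct, data.frame(sample = "s2", gene = "tgt", ct = 21))
  expect_warning(nrq3 <- nrq_from_ct(ct3, "ref", "cal"), "s2")
  expect_false("s2" %in% rownames(nrq3))
})
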