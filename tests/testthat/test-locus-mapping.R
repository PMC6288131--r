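make_ss <- function(snp, bp, p, chr = "1") {
  data.table::data.table(SNP = snp, CHR = chr, BP = bp, P = p)
}

test_that("no genome-wide significant variant gives zero loci", {
  ss <- make_ss(paste0("v", 1:5), 1:5 * 1000L, rep(1e-6, 5))
  ld <- data.frame(SNP_A = "v1", SNP_B = "v2", R2 = 0.9)
  expect_equal(nrow(define_loci(ss, ld)), 0L)
})

test_that("isolated significant variant yields a single-variant locus", {
  ss <- make_ss(c("lead", "far"), c(50000L, 90000L), c(1e-9, 0.5))
  ld <- data.frame(SNP_A = "lead", SNP_B = "far", R2 = 0.1)
  loci <- define_loci(ss, ld)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$lead_variant, "lead")
  expect_equal(loci$start, 50000L)
  expect_equal(loci$end, 50000L)
  expect_equal(loci$members[[1]], "lead")
})

test_that("a planted LD cluster spans exactly its qualifying members", {
  # lead at 1e-9 with five partners below 1e-4 at r2 = 0.5, flanked by
  # null variants and one partner above the membership threshold
  snp <- c("lead", paste0("m", 1:5), "weak", paste0("null", 1:3))
  bp <- c(5000L, 1000L, 2000L, 3000L, 7000L, 9000L, 6000L,
          20000L, 30000L, 40000L)
  p <- c(1e-9, rep(5e-5, 5), 1e-3, 0.3, 0.6, 0.9)
  ss <- make_ss(snp, bp, p)
  ld <- data.frame(SNP_A = "lead",
                   SNP_B = c(paste0("m", 1:5), "weak"),
                   R2 = 0.5)
  loci <- define_loci(ss, ld)
  expect_equal(nrow(loci), 1L)
  expect_setequal(loci$members[[1]], c("lead", paste0("m", 1:5)))
  expect_equal(loci$start, 1000L)
  expect_equal(loci$end, 9000L)
})

test_that("define_loci is invariant to row order with disjoint members", {
  set.seed(21)
  n <- 60
  ss <- make_ss(paste0("v", 1:n), sort(sample.int(1e6, n)),
                10^-runif(n, 0, 10))
  ld <- data.frame(SNP_A = paste0("v", sample(n, 40, replace = TRUE)),
                   SNP_B = paste0("v", sample(n, 40, replace = TRUE)),
                   R2 = runif(40))
  ld <- ld[ld$SNP_A != ld$SNP_B, ]
  a <- define_loci(ss, ld)
  b <- define_loci(ss[sample(n)], ld[sample(nrow(ld)), ])
  expect_identical(a, b)
  members <- unlist(a$members)
  expect_equal(anyDuplicated(members), 0L)
})

test_that("overlapping loci merge keeping the best lead", {
  # two leads whose member spans intersect on one chromosome
  ss <- make_ss(c("leadA", "a1", "leadB", "b1"),
                c(10000L, 30000L, 40000L, 25000L),
                c(1e-12, 5e-5, 1e-9, 5e-5))
  ld <- data.frame(SNP_A = c("leadA", "leadB"),
                   SNP_B = c("a1", "b1"),
                   R2 = c(0.5, 0.5))
  loci <- define_loci(ss, ld)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$lead_variant, "leadA")
  expect_equal(loci$start, 10000L)
  expect_equal(loci$end, 40000L)
  expect_setequal(loci$members[[1]], c("leadA", "a1", "leadB", "b1"))
})

test_that("positional mapping honours the 250 kb window boundary", {
  loci <- data.table::data.table(locus_id = "L1", chrom = "1",
                                 start = 1000000L, end = 1100000L)
  genes <- data.table::data.table(
    chrom = "1",
    start = c(1020000L, 1100000L + 250000L, 1100000L + 250001L) - 1L,
    end = c(1030000L, 1400000L, 1500000L),
    gene_id = c("inside", "at_edge", "beyond"))
  genes[, start := as.integer(start)]
  m <- positional_map(loci, genes)
  expect_true("inside" %in% m$gene_id)
  expect_true("at_edge" %in% m$gene_id)   # last bp inside the window
  expect_false("beyond" %in% m$gene_id)   # starts window + 1 beyond end
})

test_that("positional mapping matches a brute-force interval oracle", {
  set.seed(31)
  loci <- data.table::data.table(locus_id = "L1", chrom = "1",
                                 start = 2000000L, end = 2050000L)
  gs <- sort(sample.int(4000000L, 20))
  genes <- data.table::data.table(chrom = "1", start = gs,
                                  end = gs + sample.int(200000L, 20),
                                  gene_id = paste0("g", 1:20))
  w <- 250000L
  mapped <- positional_map(loci, genes, window_bp = w)$gene_id
  oracle <- genes$gene_id[mapply(interval_overlaps, genes$start,
                                 genes$end,
                                 MoreArgs = list(ws = loci$start - w,
                                                 we = loci$end + w))]
  expect_setequal(mapped, oracle)
  # monotonicity: shrinking the window never adds genes
  for (w2 in c(100000L, 10000L, 0L)) {
    expect_true(all(positional_map(loci, genes, w2)$gene_id %in% mapped))
    mapped <- positional_map(loci, genes, w2)$gene_id
  }
})

test_that("chromatin mapping applies a strict interaction FDR cutoff", {
  loci <- data.table::data.table(locus_id = "L1", chrom = "1",
                                 start = 500000L, end = 600000L)
  ia <- data.table::data.table(
    anchor_chrom = "1",
    anchor_start = c(520000L, 530000L, 540000L, 900000L),
    anchor_end = c(525000L, 535000L, 545000L, 910000L),
    gene_id = c("gA", "gB", "gC", "gFar"),
    fdr = c(1e-7, 1e-5, 1e-9, 1e-9))
  m <- chromatin_map(loci, ia)
  expect_setequal(m$gene_id, c("gA", "gC")) # 1e-5 fails, gFar no overlap
  exact <- data.table::copy(ia)[1, fdr := 1e-6]
  expect_false("gA" %in% chromatin_map(loci, exact)$gene_id)
})

test_that("combined mapping records union evidence", {
  loci <- data.table::data.table(locus_id = "L1", chrom = "1",
                                 start = 100000L, end = 200000L)
  genes <- data.table::data.table(chrom = "1", start = 120000L,
                                  end = 130000L, gene_id = "gBoth")
  ia <- data.table::data.table(anchor_chrom = "1", anchor_start = 150000L,
                               anchor_end = 160000L,
                               gene_id = c("gBoth", "gDistal"),
                               fdr = 1e-8)
  m <- map_genes(loci, genes, ia)
  expect_equal(m[m$gene_id == "gBoth", ]$evidence, "both")
  expect_equal(m[m$gene_id == "gDistal", ]$evidence, "chromatin")
  expect_setequal(pooled_gene_list(m), c("gBoth", "gDistal"))
})
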