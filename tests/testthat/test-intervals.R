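test_that("BED peaks round-trip through read_peaks/write_peaks", {
  cs <- toy_cistrome(c(100, 500, 900), c(300, 800, 1500),
                     scores = c(600, 700, 3100),
                     fes = c(22, 25, 42.11))
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks(cs, path)
  back <- read_peaks(path, "bed6+")
  expect_equal(n_peaks(back), 3L)
  expect_equal(back$start, cs$start)
  expect_equal(back$end, cs$end)
  expect_equal(back$score, cs$score)
  expect_equal(back$fold_enrichment, cs$fold_enrichment)
  expect_equal(back$summit, cs$summit)
})

test_that("a validated qPCR region reads back with its printed fields", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr19\t51353679\t51354605\tsite1\t3100\t.\t42.11\t463",
             path)
  cs <- read_peaks(path, "bed6+")
  expect_equal(cs$chrom, "chr19")
  expect_equal(cs$start, 51353679L)
  expect_equal(cs$end, 51354605L)
  expect_equal(cs$score, 3100)
  expect_equal(cs$fold_enrichment, 42.11)
})

test_that("empty and malformed peak files are handled", {
  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_warning(cs <- read_peaks(empty), "empty")
  expect_equal(n_peaks(cs), 0L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\toops"), bad)
  expect_error(read_peaks(bad), "line 2")
})

test_that("MACS-style 1-based coordinates are converted on read", {
  path <- withr::local_tempfile(fileext = ".xls")
  writeLines(c("chr\tstart\tend\tsummit\tscore\tfold_enrichment",
               "chr1\t101\t200\t150\t800\t25"), path)
  cs <- read_peaks(path, "macs-xls")
  expect_equal(cs$start, 100L)
  expect_equal(cs$end, 200L)
  expect_equal(cs$summit, 149L)
})

test_that("peak validation enforces invariants", {
  expect_error(cistrome_set(data.frame(chrom = "chr1", start = -5,
                                       end = 10)), "start")
  expect_error(cistrome_set(data.frame(chrom = "chr1", start = 10,
                                       end = 10)), "end")
  expect_error(cistrome_set(data.frame(chrom = "chr1", start = 0, end = 10,
                                       summit = 10)), "summit")
  expect_error(cistrome_set(data.frame(chrom = "chr1", start = 0,
                                       end = c(10, 20), id = c("a", "a"))),
               "unique")
})

test_that("overlap requires at least one shared base", {
  a <- toy_cistrome(100, 200)
  expect_equal(overlap_sets(a, toy_cistrome(199, 300))$n_shared_a, 1L)
  expect_equal(overlap_sets(a, toy_cistrome(200, 300))$n_shared_a, 0L)
  expect_equal(overlap_sets(a, toy_cistrome(100, 200,
                                            chrom = "chr2"))$n_shared_a,
               0L)
})

test_that("overlap is reflexive and symmetric", {
  set.seed(42)
  starts <- sort(sample(0:5000, 30)) * 10
  a <- toy_cistrome(starts, starts + sample(50:400, 30, TRUE))
  self <- overlap_sets(a, a)
  expect_equal(self$n_shared_a, n_peaks(a))
  b <- toy_cistrome(starts + sample(-300:300, 30), starts + 400)
  ab <- overlap_sets(a, b); ba <- overlap_sets(b, a)
  expect_equal(nrow(ab$pairs), nrow(ba$pairs))
  expect_setequal(paste(ab$pairs$a_id, ab$pairs$b_id),
                  paste(ba$pairs$b_id, ba$pairs$a_id))
})

test_that("TSS association window is inclusive at the boundary", {
  genes <- gene_models(data.frame(gene = "G1", chrom = "chr1",
                                  strand = "+", tss = 100000))
  near <- function(offset) {
    cs <- cistrome_set(data.frame(chrom = "chr1",
                                  start = 100000 + offset - 50,
                                  end = 100000 + offset + 50,
                                  summit = 100000 + offset))
    nrow(map_to_tss(cs, genes))
  }
  expect_equal(near(24999), 1L)
  expect_equal(near(25000), 1L)
  expect_equal(near(25001), 0L)
  expect_equal(near(-25000), 1L)
})

test_that("TSS association matches a brute-force all-pairs scan", {
  set.seed(7)
  n_p <- 80; n_g <- 60
  cs <- cistrome_set(data.frame(
    chrom = sample(c("chr1", "chr2"), n_p, TRUE),
    start = (s <- sample(0:2e6, n_p)), end = s + 200))
  genes <- gene_models(data.frame(
    gene = sprintf("G%03d", 1:n_g),
    chrom = sample(c("chr1", "chr2"), n_g, TRUE),
    strand = sample(c("+", "-"), n_g, TRUE),
    tss = sample(0:2e6, n_g)))
  got <- map_to_tss(cs, genes, max_dist = 25000)
  brute <- do.call(rbind, lapply(1:n_g, function(gi) {
    hits <- which(cs$chrom == genes$chrom[gi] &
                    abs(cs$summit - genes$tss[gi]) <= 25000)
    if (!length(hits)) return(NULL)
    data.frame(gene = genes$gene[gi], peak_id = cs$id[hits],
               distance = abs(cs$summit[hits] - genes$tss[gi]))
  }))
  key <- function(d) sort(paste(d$gene, d$peak_id, d$distance))
  expect_equal(key(got), key(brute))
  # distance is strand-independent
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  expect_equal(key(map_to_tss(cs, flipped)), key(got))
})

test_that("genes with unknown chromosome are skipped with a warning", {
  genes <- gene_models(data.frame(gene = c("G1", "G2"),
                                  chrom = c("chr1", ""),
                                  strand = "+", tss = c(1000, 2000)))
  cs <- toy_cistrome(900, 1100)
  expect_warning(out <- map_to_tss(cs, genes), "skipped")
  expect_equal(out$gene, "G1")
})

test_that("annotation categories are exhaustive, exclusive and ordered", {
  genes <- gene_models(data.frame(
    gene = "G1", chrom = "chr1", strand = "+", tss = 10000,
    tx_start = 10000, tx_end = 20000,
    exon_starts = "10000,15000", exon_ends = "10500,15500"))
  cs <- cistrome_set(data.frame(
    chrom = "chr1",
    start = c(9500, 10050, 12000, 50000),
    end = c(10100, 10600, 12500, 50400)))
  out <- classify_annotation(cs, genes, chrom_sizes = c(chr1 = 100000))
  expect_equal(sum(out$counts), n_peaks(cs))
  # first peak spans promoter; second overlaps promoter AND exon ->
  # promoter wins by precedence; third intronic; fourth intergenic
  expect_equal(unname(out$counts),
               c(promoter = 2L, exonic = 0L, intronic = 1L,
                 intergenic = 1L), ignore_attr = TRUE)
})

test_that("annotation enrichment is observed over background fraction", {
  # gene-desert peaks: all intergenic
  genes <- gene_models(data.frame(gene = "G1", chrom = "chr1",
                                  strand = "+", tss = 1000,
                                  tx_start = 1000, tx_end = 2000,
                                  exon_starts = "", exon_ends = ""))
  cs <- toy_cistrome(c(50000, 60000), c(50400, 60400))
  out <- classify_annotation(cs, genes, chrom_sizes = c(chr1 = 100000))
  expect_equal(unname(out$counts[["intergenic"]]), 2L)
  expect_equal(sum(out$counts), 2L)
  # fold over-representation arithmetic: fraction / background
  expect_equal(unname(out$enrichment[["intergenic"]]),
               1 / unname(out$background[["intergenic"]]))
})
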