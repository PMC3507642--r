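mk_de <- function(probe_id, gene, fc, q, d = NULL) {
  de_table(data.frame(probe_id = probe_id, gene = gene, fold_change = fc,
                      d_score = d %||% sign(fc) * 3, q_value = q))
}

test_that("significance needs both FDR and fold-change cuts", {
  tab <- mk_de(c("p1", "p2", "p3", "p4"),
               c("G1", "G2", "G3", "G4"),
               c(1.6, 1.4, -2.0, 2.0),
               c(0.04, 0.01, 0.02, 0.2))
  sig <- de_significant(tab)
  expect_equal(sig$up, "G1")          # p2 fails |FC|, p4 fails FDR
  expect_equal(sig$down, "G3")
})

test_that("genes with opposite-direction probes are excluded", {
  tab <- mk_de(c("p1", "p2", "p3"), c("G1", "G1", "G2"),
               c(2.0, -1.8, 1.9), c(0.01, 0.02, 0.01))
  sig <- de_significant(tab)
  expect_equal(sig$discordant, "G1")
  expect_false("G1" %in% c(sig$up, sig$down))
  expect_equal(sig$up, "G2")
})

test_that("loosening the cuts never removes significant genes", {
  set.seed(19)
  tab <- mk_de(sprintf("p%03d", 1:200), sprintf("G%03d", 1:200),
               sample(c(-1, 1), 200, TRUE) * runif(200, 1, 4),
               runif(200))
  strict <- de_significant(tab, fdr = 0.05, fc_cut = 2)
  loose_fdr <- de_significant(tab, fdr = 0.2, fc_cut = 2)
  loose_fc <- de_significant(tab, fdr = 0.05, fc_cut = 1.2)
  expect_true(all(strict$up %in% loose_fdr$up))
  expect_true(all(strict$down %in% loose_fdr$down))
  expect_true(all(strict$up %in% c(loose_fc$up, loose_fc$discordant)))
  expect_true(all(strict$down %in% c(loose_fc$down, loose_fc$discordant)))
})

test_that("profile concordance is 1 on identity and -1 on sign flip", {
  set.seed(29)
  n <- 100
  l2 <- rnorm(n)
  tab <- mk_de(sprintf("p%03d", 1:n), sprintf("G%03d", 1:n),
               sign(l2) * 2^abs(l2), runif(n), d = rnorm(n, l2 * 3))
  same <- profile_concordance(tab, tab)
  expect_equal(same$r_fc, 1)
  expect_equal(same$r_d, 1)
  flip <- tab
  flip$fold_change <- -flip$fold_change
  flip$d_score <- -flip$d_score
  opp <- profile_concordance(tab, flip)
  expect_equal(opp$r_fc, -1)
  expect_equal(opp$r_d, -1)
  expect_error(profile_concordance(tab[1:2, ], tab[1:2, ]), "3")
})

test_that("a planted correlation of 0.6 is recovered genome-wide", {
  set.seed(37)
  n <- 10000
  rho <- 0.6
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  ta <- mk_de(sprintf("p%05d", 1:n), sprintf("G%05d", 1:n),
              sign(x) * 2^abs(x), runif(n), d = x * 4)
  tb <- mk_de(sprintf("p%05d", 1:n), sprintf("G%05d", 1:n),
              sign(y) * 2^abs(y), runif(n), d = y * 4)
  res <- profile_concordance(ta, tb)
  expect_equal(res$r_fc, 0.6, tolerance = 0.035)
  expect_equal(res$r_d, 0.6, tolerance = 0.035)
})

test_that("direct targets pair impacted binding with expression direction", {
  impacted <- data.frame(gene = c("G1", "G2", "G3"),
                         peak_id = c("pk1", "pk2", "pk3"),
                         distance = c(1200, 800, 4000))
  tg <- classify_direct_targets(impacted, up_genes = "G2",
                                down_genes = "G1")
  expect_equal(tg$mode[tg$gene == "G1"], "activation")
  expect_equal(tg$mode[tg$gene == "G2"], "repression")
  expect_false("G3" %in% tg$gene)     # impacted but not DE
  expect_error(classify_direct_targets(impacted, up_genes = "G1",
                                       down_genes = "G1"), "both")
})

test_that("activation and repression target lists stay disjoint subsets", {
  set.seed(41)
  genes <- sprintf("G%03d", 1:60)
  impacted <- data.frame(gene = sample(genes, 40),
                         peak_id = sprintf("pk%02d", 1:40),
                         distance = sample(100:20000, 40))
  up <- sample(genes, 15)
  down <- sample(setdiff(genes, up), 15)
  tg <- classify_direct_targets(impacted, up, down)
  act <- tg$gene[tg$mode == "activation"]
  rep_ <- tg$gene[tg$mode == "repression"]
  expect_length(intersect(act, rep_), 0)
  expect_true(all(tg$gene %in% impacted$gene))
})

test_that("qPCR concordance behaves on constructed data", {
  lin <- data.frame(binding_score = c(500, 800, 1200, 2000),
                    fold_enrichment_qpcr = c(5, 8, 12, 20))
  expect_equal(qpcr_concordance(lin)$r, 1)
  # residual-orthogonal pair: r = 0 by construction
  x <- c(1, 2, 3, 4)
  y <- c(1, -1, -1, 1)
  orth <- data.frame(binding_score = x, fold_enrichment_qpcr = y + 10)
  expect_equal(qpcr_concordance(orth)$r, 0)
  expect_error(qpcr_concordance(lin[1:2, ]), "3")
})

test_that("the packaged qPCR fixture has 12 regions, 11 with scores", {
  tab <- ar_qpcr_sites()
  expect_equal(nrow(tab), 12L)
  expect_equal(sum(!is.na(tab$binding_score)), 11L)
  expect_equal(min(tab$fold_enrichment_qpcr), 3.10)
  # concordance is invariant to row order
  set.seed(43)
  r1 <- qpcr_concordance(tab)$r
  r2 <- qpcr_concordance(tab[sample(nrow(tab)), ])$r
  expect_identical(r1, r2)
})

test_that("the fold filter counts strictly above threshold", {
  tab <- ar_qpcr_sites()
  expect_equal(qpcr_fold_filter(tab, 3), 12L)
  expect_equal(qpcr_fold_filter(tab, 4), 10L)  # 3.48 and 3.10 fail
  expect_equal(qpcr_fold_filter(tab[0, ]), 0L)
})
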