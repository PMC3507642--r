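# small-genome config used throughout this file; study-scale defaults are
# exercised in the acceptance suite
small_cfg <- function(...) synthetic_config(
  seed = 101, n_chroms = 2, chrom_length = 1e6, n_sites = 300,
  n_genes = 200, ...)

test_that("truth generation is reproducible and respects the config", {
  tr1 <- generate_truth(small_cfg())
  tr2 <- generate_truth(small_cfg())
  expect_identical(tr1$sites, tr2$sites)
  expect_identical(tr1$occupancy, tr2$occupancy)
  expect_identical(tr1$genes, tr2$genes)
  expect_equal(nrow(tr1$sites), 300L)
  expect_true(all(tr1$sites$start >= 0 & tr1$sites$end <= 1e6))
  expect_error(synthetic_config(conditions = c(a = 0.5, b = 0.1)),
               "increasing stringency")
  expect_error(synthetic_config(occupancy_noise = 0.7), "occupancy_noise")
})

test_that("noise-free occupancy is strictly nested along the dose series", {
  tr <- generate_truth(small_cfg(occupancy_noise = 0))
  occ <- tr$occupancy
  conds <- colnames(occ)
  for (i in seq_len(ncol(occ) - 1)) {
    expect_true(all(occ[occ[, conds[i + 1]], conds[i]]))   # subset
    expect_lt(sum(occ[, conds[i + 1]]), sum(occ[, conds[i]]))
  }
})

test_that("a threshold at the affinity median plants ~50% impact", {
  tr <- generate_truth(synthetic_config(
    seed = 5, n_chroms = 2, chrom_length = 1e6, n_sites = 1000,
    n_genes = 100, occupancy_noise = 0,
    conditions = c(reference = 0, half = 0.5, minimum = 0.9)))
  expect_equal(truth_impact(tr, "half"), 100 * 0.5 / 0.9,
               tolerance = 0.02)
})

test_that("background regions have Poisson-rate tag density", {
  cfg <- small_cfg()
  tr <- generate_truth(cfg)
  em <- emit_condition(tr, "R1881minus")
  # bins at least 1 kb away from any site
  v <- em$track$counts$chr1
  bins <- seq_along(v) - 1L
  pos <- bins * 32
  sites <- tr$sites[tr$sites$chrom == "chr1", ]
  near <- vapply(pos, function(p) any(abs(p - sites$summit) < 1500),
                 logical(1))
  bg <- v[!near]
  se <- sqrt(cfg$background_rate / length(bg))
  expect_lt(abs(mean(bg) - cfg$background_rate), 3 * se + 0.01)
})

test_that("the strongest site has the highest emitted score without noise", {
  tr <- generate_truth(small_cfg(score_sd = 0, fe_sd = 0))
  em <- emit_condition(tr, "R1881plus")
  top <- sort_by_strength(em$positive)[1, ]
  expect_equal(top$id, tr$sites$id[which.max(tr$sites$affinity)])
})

test_that("auto-calibrated filtering excludes all negative peaks", {
  tr <- generate_truth(small_cfg())
  for (cond in c("R1881plus", "antag_10uM")) {
    em <- emit_condition(tr, cond)
    hc <- filter_high_confidence(em$positive, em$negative, "auto")
    expect_equal(n_peaks(filter_high_confidence(em$negative, em$negative,
                                                "auto")), 0L)
    # the true sites all survive
    expect_equal(n_peaks(hc), n_peaks(em$positive))
  }
})

test_that("conserved elements sit on occupied summits", {
  tr <- generate_truth(small_cfg())
  em <- emit_condition(tr, "antag_1uM")
  occ_summits <- tr$sites$summit[tr$occupancy[, "antag_1uM"]]
  mid <- (em$conserved$start + em$conserved$end) / 2
  expect_equal(sort(mid), sort(occ_summits))
})

test_that("expression responds only to lost linked sites", {
  tr <- generate_truth(small_cfg())
  de <- emit_expression(tr, "antag_10uM")
  resp <- attr(de, "responders")
  g <- tr$genes
  # activation-mode responders are down-regulated below -1.5 on average
  act <- resp[g$mode[match(resp, g$gene)] == "activation"]
  fc_act <- de$fold_change[match(act, de$gene)]
  expect_true(all(fc_act < 0))
  expect_lt(mean(fc_act), -1.5)
  rep_ <- resp[g$mode[match(resp, g$gene)] == "repression"]
  fc_rep <- de$fold_change[match(rep_, de$gene)]
  expect_true(all(fc_rep > 0))
  expect_gt(mean(fc_rep), 1.5)
  # in the reference condition nothing is lost, so no responders
  de_ref <- emit_expression(tr, "R1881plus")
  expect_length(attr(de_ref, "responders"), 0)
})

test_that("unlinked genes carry uniform p-values", {
  tr <- generate_truth(synthetic_config(
    seed = 7, n_chroms = 2, chrom_length = 2e6, n_sites = 400,
    n_genes = 5000, frac_linked = 0.05))
  de <- emit_expression(tr, "antag_10uM")
  null_genes <- tr$genes$gene[!tr$genes$linked]
  d <- de$d_score[match(null_genes, de$gene)]
  p <- 2 * pnorm(-abs(d))
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted motifs appear in occupied-site sequences", {
  cfg <- synthetic_config(seed = 13, n_chroms = 2, chrom_length = 4e5,
                          n_sites = 120, n_genes = 50, site_width = 200)
  tr <- generate_truth(cfg, sequences = TRUE)
  em <- emit_condition(tr, "R1881plus", sequences = TRUE)
  expect_equal(length(em$sequences), n_peaks(em$positive))
  hits <- scan_pwm(em$sequences, cfg$are_pwm)
  expect_gt(length(unique(hits$seq_id)), 0.8 * length(em$sequences))
  expect_error(emit_condition(generate_truth(cfg), "R1881plus",
                              sequences = TRUE), "genome")
})
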