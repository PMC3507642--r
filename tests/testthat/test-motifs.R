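make_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("the consensus attains the maximal score where planted", {
  p <- pwm_from_consensus("ACGTACGT", fidelity = 0.9)
  s <- paste0(substr(make_seq(10, 2), 1, 10), "ACGTACGT",
              substr(make_seq(10, 3), 1, 10))
  hits <- scan_pwm(setNames(s, "s1"), p, threshold = -Inf,
                   background = rep(0.25, 4))
  best <- hits[which.max(hits$score), ]
  expect_equal(best$position, 10L)
  expect_equal(best$score, max_score(p), tolerance = 1e-9)
  # no window can out-score the consensus
  expect_true(all(hits$score <= max_score(p) + 1e-9))
})

test_that("a uniform PWM over a uniform background scores zero everywhere", {
  p <- pwm(matrix(0.25, 4, 6), pseudocount = 0)
  hits <- scan_pwm(setNames(make_seq(60, 4), "s"), p, threshold = -Inf,
                   background = rep(0.25, 4))
  expect_true(all(abs(hits$score) < 1e-12))
})

test_that("palindromic PWMs hit both strands at equal positions and scores", {
  p <- default_are_pwm()
  expect_true(is_palindromic(p))
  set.seed(6)
  for (i in 1:5) {
    s <- setNames(make_seq(300, i + 10), "s")
    hits <- scan_pwm(s, p, threshold = -Inf, background = rep(0.25, 4))
    fwd <- hits[hits$strand == "+", ]
    rev <- hits[hits$strand == "-", ]
    expect_equal(sort(fwd$position), sort(rev$position))
    expect_equal(fwd$score[order(fwd$position)],
                 rev$score[order(rev$position)], tolerance = 1e-9)
  }
})

test_that("scanning the reverse complement mirrors strands and positions", {
  p <- pwm_from_consensus("TGTTTAC")
  s <- make_seq(200, 33)
  rc <- paste(rev(chartr("ACGT", "TGCA",
                         strsplit(s, "")[[1]])), collapse = "")
  h1 <- scan_pwm(setNames(s, "x"), p, threshold = -5,
                 background = rep(0.25, 4))
  h2 <- scan_pwm(setNames(rc, "x"), p, threshold = -5,
                 background = rep(0.25, 4))
  # a + hit at position q corresponds to a - hit at L - w - q
  L <- nchar(s); w <- p$width
  key <- function(h) sort(paste(h$strand, h$position, round(h$score, 6)))
  mirrored <- data.frame(strand = ifelse(h2$strand == "+", "-", "+"),
                         position = L - w - h2$position,
                         score = h2$score)
  expect_equal(key(h1), key(mirrored))
})

test_that("palindrome detection distinguishes symmetric matrices", {
  expect_true(is_palindromic(default_are_pwm()))
  expect_false(is_palindromic(pwm_from_consensus("AAAAAA")))
  # width-1 matrix with A = T and C = G is its own reverse complement
  p1 <- pwm(matrix(c(0.4, 0.1, 0.1, 0.4), 4), pseudocount = 0)
  expect_true(is_palindromic(p1))
})

test_that("motif Z-score separates planted from background sequences", {
  set.seed(17)
  genome <- setNames(vapply(1:2, function(i) make_seq(20000, 40 + i),
                            character(1)), c("chr1", "chr2"))
  p <- default_are_pwm()
  cons <- consensus(p)
  planted <- vapply(1:30, function(i) {
    s <- make_seq(120, 60 + i)
    paste0(substr(s, 1, 50), cons, substr(s, 66, 120))
  }, character(1))
  chroms <- rep(c("chr1", "chr2"), 15)
  # a permissive cutoff keeps the background hit rate non-degenerate so
  # the random-group variance is informative
  z_planted <- motif_zscore(planted, p, genome, chroms = chroms,
                            threshold = 8, background = rep(0.25, 4),
                            background_groups = 40, seed = 5)
  expect_gt(z_planted$z, 3)
  # matched background sequences should not look enriched
  set.seed(99)
  bg_seqs <- vapply(1:30, function(i) {
    s0 <- sample(nchar(genome[chroms[i]]) - 120, 1)
    substr(genome[chroms[i]], s0, s0 + 119)
  }, character(1))
  z_bg <- motif_zscore(bg_seqs, p, genome, chroms = chroms,
                       threshold = 8, background = rep(0.25, 4),
                       background_groups = 40, seed = 5)
  expect_lt(abs(z_bg$z), 3)
  # bit-for-bit reproducibility given the seed
  z_again <- motif_zscore(planted, p, genome, chroms = chroms,
                          threshold = 8, background = rep(0.25, 4),
                          background_groups = 40, seed = 5)
  expect_identical(z_planted$z, z_again$z)
  expect_identical(z_planted$random_counts, z_again$random_counts)
})

test_that("pair spacing recovers a planted preference and rejects out-of-range", {
  a <- pwm_from_consensus("AGAACANNNTGTTCT")
  b <- pwm_from_consensus("TGTTTAC")
  hits_a <- data.frame(seq_id = sprintf("s%d", 1:50), position = 20,
                       strand = "+", score = 10)
  hits_b <- data.frame(seq_id = sprintf("s%d", 1:50),
                       position = 20 + 15 + (a$width - b$width) / 2,
                       strand = "+", score = 8)
  ps <- pair_spacing(hits_a, hits_b, a$width, b$width)
  expect_equal(ps$mode, 15)
  expect_equal(sum(ps$counts), 50)

  far <- transform(hits_b, position = position + 45)  # 60 bp apart
  ps2 <- pair_spacing(hits_a, far, a$width, b$width)
  expect_equal(sum(ps2$counts), 0)
  expect_true(is.na(ps2$mode))
})

test_that("uniform random spacing gives an approximately flat histogram", {
  set.seed(23)
  n <- 4000
  ids <- sprintf("s%d", 1:n)
  hits_a <- data.frame(seq_id = ids, position = 0, strand = "+", score = 1)
  hits_b <- data.frame(seq_id = ids, position = sample(10:50, n, TRUE),
                       strand = "+", score = 1)
  ps <- pair_spacing(hits_a, hits_b, 0, 0)  # zero-width: distance = offset
  chi <- stats::chisq.test(ps$counts)
  expect_gt(chi$p.value, 0.01)
})

test_that("motif/mode association matches fixed-margin enumeration", {
  res <- motif_mode_association(rep(c(TRUE, FALSE), each = 10),
                                rep(c("activation", "repression"),
                                    each = 10))
  expect_equal(res$p, 2 / choose(20, 10))
  expect_equal(res$p, fisher_enum(res$table))
  flat <- motif_mode_association(rep(c(TRUE, FALSE), 10),
                                 rep(c("activation", "repression"),
                                     each = 10))
  expect_equal(flat$p, 1)
  expect_error(motif_mode_association(c(TRUE, FALSE),
                                      c("activation", "activation")),
               "both")
  # random small tables against the enumeration oracle
  set.seed(13)
  for (i in 1:15) {
    cnt <- sample(1:6, 4, TRUE)
    presence <- rep(c(TRUE, FALSE, TRUE, FALSE), cnt)
    mode <- rep(c("activation", "activation", "repression", "repression"),
                cnt)
    res <- motif_mode_association(presence, mode)
    expect_equal(res$p, fisher_enum(res$table), tolerance = 1e-9)
  }
})

test_that("score/motif-strength association delegates to the rank-sum test", {
  set.seed(31)
  a <- rnorm(30, 10); b <- rnorm(30, 8)
  expect_identical(score_strength_association(a, b),
                   compare_strength_groups(a, b))
  eq <- score_strength_association(1:20, 1:20)
  expect_gt(eq$p, 0.9)
})

test_that("PWM text formats round-trip", {
  p <- default_are_pwm()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pwm_tsv(p, tsv)
  expect_equal(read_pwm_tsv(tsv)$probs, p$probs, tolerance = 1e-6)
  meme <- withr::local_tempfile(fileext = ".txt")
  write_meme_minimal(p, meme)
  expect_equal(read_meme_minimal(meme)$probs, p$probs, tolerance = 1e-5)
})

test_that("summit sequence extraction trims long sites around the summit", {
  genome <- c(chr1 = make_seq(5000, 77))
  cs <- cistrome_set(data.frame(chrom = "chr1",
                                start = c(1000, 3000),
                                end = c(2200, 3100),
                                summit = c(1600, 3050),
                                score = c(900, 500),
                                id = c("long", "short")))
  seqs <- extract_summit_sequences(genome, cs, max_width = 500)
  expect_equal(nchar(seqs[["long"]]), 500L)
  expect_equal(seqs[["long"]], substr(genome[["chr1"]], 1351, 1850))
  expect_equal(nchar(seqs[["short"]]), 100L)
  top1 <- extract_summit_sequences(genome, cs, top_n = 1)
  expect_equal(names(top1), "long")
})
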