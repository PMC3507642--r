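# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the stats functions it calls) wherever the
# quantity can be enumerated or evaluated directly.

# upper hypergeometric tail P(X >= shared) by exhaustive enumeration of
# all C(N, nB) draws, feasible for N <= 12
hyper_tail_enum <- function(N, nA, nB, shared) {
  total <- choose(N, nB)
  hits <- 0
  for (k in max(0, nA + nB - N):min(nA, nB)) {
    if (k >= shared) hits <- hits + choose(nA, k) * choose(N - nA, nB - k)
  }
  hits / total
}

# two-tailed Fisher exact p for a 2x2 table by summing, over all tables
# with the same margins, the probabilities <= that of the observed table
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  prob_of <- function(x) choose(c1, x) * choose(n - c1, r1 - x) /
    choose(n, r1)
  p_obs <- prob_of(a)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  sum(vapply(ks, prob_of, numeric(1))[
    vapply(ks, prob_of, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# one-step biweight evaluated directly from its definition, written
# without reference to the package implementation
biweight_direct <- function(x, cc = 5, eps = 1e-4) {
  m <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0)
    m <- (sort(x)[length(x) / 2] + sort(x)[length(x) / 2 + 1]) / 2
  dev <- abs(x - m)
  s <- sort(dev)[ceiling(length(dev) / 2)]
  if (length(dev) %% 2 == 0)
    s <- (sort(dev)[length(dev) / 2] + sort(dev)[length(dev) / 2 + 1]) / 2
  u <- (x - m) / (cc * s + eps)
  w <- numeric(length(x))
  inside <- abs(u) < 1
  w[inside] <- (1 - u[inside]^2)^2
  if (sum(w) == 0) return(m)
  sum(w * x) / sum(w)
}

# toy cistrome with explicit coordinates
toy_cistrome <- function(starts, ends, chrom = "chr1", scores = NULL,
                         fes = NULL, ids = NULL, label = "toy") {
  cistrome_set(data.frame(
    chrom = chrom, start = starts, end = ends,
    score = scores %||% rep(100, length(starts)),
    fold_enrichment = fes %||% rep(30, length(starts)),
    id = ids %||% sprintf("p%02d", seq_along(starts))), label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
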