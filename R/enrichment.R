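#' Read a GMT gene-signature collection
#'
#' Tab-delimited, one signature per line: name, description/source, then
#' member genes.
#' @param path GMT file
#' @return list of signatures, each `list(name, source, genes)`
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("GMT line with fewer than 3 fields")
    list(name = f[1], source = f[2], genes = unique(f[-(1:2)]))
  })
}

#' Write a GMT gene-signature collection
#' @param signatures list of `list(name, source, genes)`
#' @param path output path
#' @export
write_gmt <- function(signatures, path) {
  writeLines(vapply(signatures, function(s)
    paste(c(s$name, s$source %||% "", s$genes), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Hypergeometric gene-signature enrichment
#'
#' For each signature, tests whether the target gene list overlaps the
#' signature (intersected with the universe) more than expected by chance,
#' using the upper hypergeometric tail, and corrects across signatures
#' with Storey [qvalues()].
#'
#' @param targets gene set (must be a subset of `universe`).
#' @param universe background gene set (e.g. all genes on the expression
#'   platform).
#' @param signatures list of `list(name, source, genes)` as from
#'   [read_gmt()]; signatures with no gene in the universe are skipped
#'   with a warning.
#' @param pi0 optional fixed pi0 passed to [qvalues()].
#' @return data frame `signature`, `signature_size` (within universe),
#'   `overlap`, `expected`, `p`, `q`, sorted by `p`.
#' @export
signature_enrichment <- function(targets, universe, signatures,
                                 pi0 = NULL) {
  targets <- unique(targets); universe <- unique(universe)
  extra <- setdiff(targets, universe)
  if (length(extra)) stopf("%d target gene(s) not in the universe",
                           length(extra))
  rows <- lapply(signatures, function(s) {
    sg <- intersect(s$genes, universe)
    if (!length(sg)) {
      warnf("signature '%s' has no genes in the universe; skipped", s$name)
      return(NULL)
    }
    ov <- length(intersect(targets, sg))
    data.frame(signature = s$name, signature_size = length(sg),
               overlap = ov,
               expected = length(targets) * length(sg) / length(universe),
               p = overlap_enrichment(length(universe), length(sg),
                                      length(targets), ov),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(signature = character(), signature_size = integer(),
                      overlap = integer(), expected = numeric(),
                      p = numeric(), q = numeric()))
  out$q <- qvalues(out$p, pi0 = pi0)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Storey q-values
#'
#' Multiple-testing correction estimating the null proportion pi0 with a
#' single fixed lambda (default 0.5, smoother-free):
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))`; q-values are then the
#' pi0-scaled step-up adjusted p-values (with `pi0 = 1` this is exactly
#' Benjamini-Hochberg).
#'
#' @param pvals p-values in `[0, 1]`.
#' @param lambda tuning point for the pi0 estimate, default 0.5.
#' @param pi0 optional fixed pi0 overriding the estimate (e.g. 1 for BH).
#' @return q-values, order-consistent with `pvals`.
#' @export
qvalues <- function(pvals, lambda = 0.5, pi0 = NULL) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1)) stopf("p-values must lie in [0, 1]")
  if (is.null(pi0))
    pi0 <- min(1, mean(pvals > lambda) / (1 - lambda))
  pi0 <- max(pi0, .Machine$double.eps)
  pmin(pi0 * p.adjust(pvals, method = "BH"), 1)
}

#' Export an enrichment network
#'
#' Nodes are signatures significant at `fdr`; node weight is the
#' signature size. Edges connect signature pairs whose gene overlap is
#' itself enriched, weighted by `-log10` of the pairwise hypergeometric
#' tail p (edges with p = 1 are dropped). The tables load directly into
#' standard graph viewers.
#'
#' @param results a [signature_enrichment()] table.
#' @param signatures the signature list that produced it.
#' @param universe gene universe for the pairwise overlap tests.
#' @param fdr node significance cutoff, default 0.05.
#' @return list of data frames `nodes` (`signature`, `size`, `q`) and
#'   `edges` (`from`, `to`, `overlap`, `p`, `weight`).
#' @export
export_enrichment_network <- function(results, signatures, universe,
                                      fdr = 0.05) {
  universe <- unique(universe)
  sig <- results[results$q < fdr, , drop = FALSE]
  nodes <- data.frame(signature = sig$signature,
                      size = sig$signature_size, q = sig$q,
                      stringsAsFactors = FALSE)
  genes_of <- lapply(signatures, function(s)
    intersect(s$genes, universe))
  names(genes_of) <- vapply(signatures, `[[`, character(1), "name")
  edges <- data.frame(from = character(), to = character(),
                      overlap = integer(), p = numeric(),
                      weight = numeric())
  nm <- nodes$signature
  if (length(nm) >= 2L) {
    cmb <- utils::combn(nm, 2)
    rows <- lapply(seq_len(ncol(cmb)), function(k) {
      a <- genes_of[[cmb[1, k]]]; b <- genes_of[[cmb[2, k]]]
      ov <- length(intersect(a, b))
      p <- overlap_enrichment(length(universe), length(a), length(b), ov)
      data.frame(from = cmb[1, k], to = cmb[2, k], overlap = ov, p = p,
                 weight = -log10(max(p, .Machine$double.xmin)),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
    edges <- edges[edges$p < 1, , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(nodes = nodes, edges = edges)
}

#' Write network node/edge tables as TSV
#' @param network an [export_enrichment_network()] result
#' @param node_path,edge_path output paths
#' @export
write_network <- function(network, node_path, edge_path) {
  write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(node_path, edge_path))
}
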