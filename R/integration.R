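#' Differential-expression table
#'
#' One row per probe set: `probe_id`, `gene`, `fold_change` (signed ratio
#' scale: +2 is a doubling, -2 a halving; never in (-1, 1) or 0),
#' `d_score` and `q_value`.
#'
#' @param table data frame with those columns.
#' @return a validated `DETable` data frame.
#' @export
de_table <- function(table) {
  d <- as.data.frame(table)
  req <- c("probe_id", "gene", "fold_change", "d_score", "q_value")
  miss <- setdiff(req, names(d))
  if (length(miss)) stopf("DE table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(d)) {
    if (any(is.na(d$q_value) | d$q_value < 0 | d$q_value > 1))
      stopf("q_value must lie in [0, 1]")
    if (any(d$fold_change == 0)) stopf("fold_change must be non-zero")
  }
  structure(d[req], class = c("DETable", "data.frame"))
}

#' Read a differential-expression TSV
#'
#' Tab-delimited with header columns probe_id, gene, fold_change,
#' d_score, q_value.
#' @param path file path
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("DE table not found: %s", path)
  de_table(read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))
}

#' Write a differential-expression TSV
#' @param table a [de_table()]
#' @param path output path
#' @export
write_de_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Significantly differentially expressed genes
#'
#' A gene is significant when at least one of its probes has
#' `q_value < fdr` and `|fold_change| > fc_cut` (both strict). Genes whose
#' passing probes disagree in direction are excluded.
#'
#' @param table a [de_table()].
#' @param fdr FDR cutoff, default 0.05.
#' @param fc_cut fold-change magnitude cutoff, default 1.5.
#' @return list with `up` and `down` gene vectors (disjoint) and
#'   `discordant` (excluded genes).
#' @export
de_significant <- function(table, fdr = 0.05, fc_cut = 1.5) {
  if (nrow(table) == 0L) stopf("DE table is empty")
  pass <- table$q_value < fdr & abs(table$fold_change) > fc_cut
  tp <- table[pass, , drop = FALSE]
  up_genes <- unique(tp$gene[tp$fold_change > 0])
  down_genes <- unique(tp$gene[tp$fold_change < 0])
  discordant <- intersect(up_genes, down_genes)
  list(up = setdiff(up_genes, discordant),
       down = setdiff(down_genes, discordant),
       discordant = discordant)
}

#' Concordance of two expression-response profiles
#'
#' Pearson correlation of fold changes and of d-scores over the probes
#' common to both tables (for fold changes the signed-ratio values are
#' mapped to log2 scale first, so +2 and -2 are symmetric), plus
#' hypergeometric overlap tests of the significantly up- and
#' down-regulated gene sets.
#'
#' @param table_a,table_b [de_table()]s with >= 3 shared probes.
#' @param fdr,fc_cut significance cutoffs for the overlap tests.
#' @return list with `r_fc`, `p_fc`, `r_d`, `p_d`, `n_shared`,
#'   `p_overlap_up`, `p_overlap_down`.
#' @export
profile_concordance <- function(table_a, table_b, fdr = 0.05,
                                fc_cut = 1.5) {
  common <- intersect(table_a$probe_id, table_b$probe_id)
  if (length(common) < 3L) stopf("need >= 3 shared probes, found %d",
                                 length(common))
  a <- table_a[match(common, table_a$probe_id), ]
  b <- table_b[match(common, table_b$probe_id), ]
  to_log2 <- function(fc) sign(fc) * log2(abs(fc))
  ct_fc <- cor.test(to_log2(a$fold_change), to_log2(b$fold_change))
  ct_d <- cor.test(a$d_score, b$d_score)
  sig_a <- de_significant(de_table(a), fdr, fc_cut)
  sig_b <- de_significant(de_table(b), fdr, fc_cut)
  universe <- length(unique(c(a$gene, b$gene)))
  ov_p <- function(sa, sb) {
    if (!length(sa) || !length(sb)) return(1)
    overlap_enrichment(universe, length(sa), length(sb),
                       length(intersect(sa, sb)))
  }
  list(r_fc = unname(ct_fc$estimate), p_fc = ct_fc$p.value,
       r_d = unname(ct_d$estimate), p_d = ct_d$p.value,
       n_shared = length(common),
       p_overlap_up = ov_p(sig_a$up, sig_b$up),
       p_overlap_down = ov_p(sig_a$down, sig_b$down))
}

#' Classify direct activation and repression targets
#'
#' A direct activation target is a gene with antagonist-impacted binding
#' near its TSS whose expression is significantly down-regulated under the
#' antagonist; a direct repression target has impacted binding and
#' up-regulated expression.
#'
#' @param impacted_genes output of [map_to_tss()] run on the impacted
#'   sites (data frame `gene`, `peak_id`, `distance`).
#' @param up_genes,down_genes significant gene sets from
#'   [de_significant()] (disjoint).
#' @return data frame `gene`, `mode`, `peaks` (comma-joined supporting
#'   peak ids), `tss_distance` (bp to the nearest supporting peak), class
#'   `DirectTargets`.
#' @export
classify_direct_targets <- function(impacted_genes, up_genes, down_genes) {
  both <- intersect(up_genes, down_genes)
  if (length(both))
    stopf("gene(s) in both up and down sets: %s",
          paste(utils::head(both, 5), collapse = ", "))
  one_mode <- function(gset, mode) {
    sel <- impacted_genes[impacted_genes$gene %in% gset, , drop = FALSE]
    if (!nrow(sel)) return(NULL)
    agg <- split(sel, sel$gene)
    data.frame(gene = names(agg), mode = mode,
               peaks = vapply(agg, function(d)
                 paste(d$peak_id, collapse = ","), character(1)),
               tss_distance = vapply(agg, function(d)
                 min(d$distance), numeric(1)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_mode(down_genes, "activation"),
               one_mode(up_genes, "repression"))
  if (is.null(out))
    out <- data.frame(gene = character(), mode = character(),
                      peaks = character(), tss_distance = numeric())
  rownames(out) <- NULL
  structure(out, class = c("DirectTargets", "data.frame"))
}

#' Packaged qPCR validation fixture
#'
#' Twelve ChIP-enriched regions assayed by real-time quantitative PCR
#' against a gene-desert negative control, with the peak-caller binding
#' score where the region was scored (11 of 12) and the primer pair used.
#' Coordinates are 1-based inclusive as printed.
#'
#' @return data frame with columns `chrom`, `start`, `end`,
#'   `binding_score`, `fold_enrichment_qpcr`, `primer_fwd`, `primer_rev`.
#' @export
ar_qpcr_sites <- function() {
  path <- system.file("extdata", "ar_qpcr_validation.tsv",
                      package = "cistromedose", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Concordance between binding score and qPCR enrichment
#'
#' Pearson correlation of the peak-caller binding score with the qPCR
#' fold enrichment over records carrying both values (raw scale by
#' default; a log option is exposed).
#'
#' @param records data frame with columns `binding_score` and
#'   `fold_enrichment_qpcr`; rows lacking a binding score are excluded.
#' @param log_scale correlate log-transformed values, default `FALSE`.
#' @return list with `r`, `p_two_sided`, `p_one_sided` (upper tail:
#'   positive concordance) and `n` complete pairs.
#' @export
qpcr_concordance <- function(records, log_scale = FALSE) {
  ok <- complete.cases(records[c("binding_score", "fold_enrichment_qpcr")])
  d <- records[ok, , drop = FALSE]
  if (nrow(d) < 3L) stopf("need >= 3 complete record pairs, found %d",
                          nrow(d))
  xs <- d$binding_score; ys <- d$fold_enrichment_qpcr
  if (log_scale) { xs <- log(xs); ys <- log(ys) }
  ct2 <- cor.test(xs, ys, alternative = "two.sided")
  ct1 <- cor.test(xs, ys, alternative = "greater")
  list(r = unname(ct2$estimate), p_two_sided = ct2$p.value,
       p_one_sided = ct1$p.value, n = nrow(d))
}

#' Count qPCR records above an enrichment threshold
#' @param records as in [qpcr_concordance()]
#' @param threshold fold-enrichment cutoff (strict), default 3
#' @return number of records with `fold_enrichment_qpcr > threshold`
#' @export
qpcr_fold_filter <- function(records, threshold = 3) {
  if (!nrow(records)) return(0L)
  sum(records$fold_enrichment_qpcr > threshold, na.rm = TRUE)
}
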