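#' Conserved-element track
#'
#' Non-overlapping genomic elements carrying a conservation score in
#' `[0, 1]` (phastCons-style). Scores above 1 on read are assumed to be
#' UCSC 0-1000 scaled and divided by 1000.
#'
#' @param elements data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `score`.
#' @return a validated `ConservedElements` data frame.
#' @export
conserved_elements <- function(elements) {
  e <- as.data.frame(elements)
  req <- c("chrom", "start", "end", "score")
  miss <- setdiff(req, names(e))
  if (length(miss)) stopf("conserved elements lack column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(e)) {
    if (any(e$score > 1)) e$score <- e$score / 1000
    if (any(e$score < 0 | e$score > 1))
      stopf("conservation scores must lie in [0, 1]")
    if (any(e$end <= e$start)) stopf("element end must exceed start")
    e <- e[order(e$chrom, e$start), , drop = FALSE]
    ov <- unlist(tapply(seq_len(nrow(e)), e$chrom, function(i) {
      if (length(i) < 2) return(FALSE)
      e$start[i][-1] < e$end[i][-length(i)]
    }))
    if (any(ov)) stopf("conserved elements must not overlap within a track")
    rownames(e) <- NULL
  }
  structure(e, class = c("ConservedElements", "data.frame"))
}

#' Read a BED5 conserved-element track
#'
#' Columns chrom, start, end, name, score; scores in 0-1000 are rescaled
#' to `[0, 1]`.
#' @param path file path
#' @return a [conserved_elements()] track
#' @export
read_conserved_elements <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- tryCatch(read.table(path, sep = "\t", stringsAsFactors = FALSE),
                error = function(e) NULL)
  if (is.null(d))
    return(conserved_elements(data.frame(chrom = character(),
                                         start = integer(), end = integer(),
                                         score = numeric())))
  if (ncol(d) < 5L) stopf("BED5 requires 5 columns, found %d", ncol(d))
  conserved_elements(data.frame(chrom = d[[1]], start = d[[2]],
                                end = d[[3]], score = d[[5]]))
}

#' Sample conservation around a summit
#'
#' The conservation value at a genomic position is the score of the
#' covering conserved element, or zero outside all elements. Samples are
#' taken every `step` bp from `-span` to `+span` around the summit.
#'
#' @param elements a [conserved_elements()] track.
#' @param chrom chromosome of the summit.
#' @param summit absolute bp position (>= 0).
#' @param step,span sampling grid, defaults 100 bp and 10000 bp
#'   (2 * span / step + 1 = 201 samples).
#' @param chrom_size optional chromosome length; a summit at or beyond it
#'   is an error.
#' @return numeric vector of scores named by offset.
#' @export
sample_conservation <- function(elements, chrom, summit, step = 100,
                                span = 10000, chrom_size = NULL) {
  if (summit < 0) stopf("summit must be >= 0")
  if (!is.null(chrom_size) && summit >= chrom_size)
    stopf("summit beyond chromosome end")
  offsets <- seq(-span, span, by = step)
  pos <- summit + offsets
  out <- numeric(length(pos))
  e <- elements[elements$chrom == chrom, , drop = FALSE]
  if (nrow(e)) {
    # elements are sorted and disjoint: locate by binary search
    i <- findInterval(pos, e$start)
    hit <- i >= 1L & pos >= 0
    hit[hit] <- pos[hit] < e$end[i[hit]]
    out[hit] <- e$score[i[hit]]
  }
  setNames(out, offsets)
}

#' Mean conservation profile of a cistrome
#'
#' Pointwise mean of [sample_conservation()] over all peak summits. For
#' summit-centered functional elements the profile peaks at offset 0.
#'
#' @param cistrome a `CistromeSet` with at least one peak.
#' @param elements a [conserved_elements()] track.
#' @inheritParams sample_conservation
#' @return data frame `offset`, `mean_score` (class `ConservationProfile`).
#' @export
mean_profile <- function(cistrome, elements, step = 100, span = 10000) {
  if (nrow(cistrome) == 0L) stopf("cistrome is empty")
  mat <- vapply(seq_len(nrow(cistrome)), function(i)
    sample_conservation(elements, cistrome$chrom[i], cistrome$summit[i],
                        step = step, span = span),
    numeric(2 * span / step + 1))
  structure(data.frame(offset = seq(-span, span, by = step),
                       mean_score = rowMeans(mat)),
            class = c("ConservationProfile", "data.frame"))
}

#' Write a conservation profile as TSV
#' @param profile a [mean_profile()] result
#' @param path output path
#' @export
write_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Conservation vs regulation-mode association
#'
#' Classifies each binding site as conserved (summit covered by a
#' conserved element) or not, and tests association between conservation
#' and regulation mode (activation vs repression targets) with a
#' two-tailed Fisher exact test.
#'
#' @param peaks_activation,peaks_repression `CistromeSet`s of sites
#'   associated with each regulation mode (both non-empty).
#' @param elements a [conserved_elements()] track.
#' @return list with the 2x2 `table` (rows: modes; columns:
#'   conserved/non-conserved) and two-tailed `p`.
#' @export
conservation_mode_association <- function(peaks_activation,
                                          peaks_repression, elements) {
  if (nrow(peaks_activation) == 0L || nrow(peaks_repression) == 0L)
    stopf("both mode groups must be non-empty")
  is_cons <- function(cs) vapply(seq_len(nrow(cs)), function(i)
    sample_conservation(elements, cs$chrom[i], cs$summit[i],
                        step = 1, span = 0)[[1]] > 0, logical(1))
  a <- is_cons(peaks_activation)
  r <- is_cons(peaks_repression)
  tab <- matrix(c(sum(a), sum(!a), sum(r), sum(!r)), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("activation", "repression"),
                                c("conserved", "non_conserved")))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
  else fisher.test(tab)$p.value
  list(table = tab, p = p)
}
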