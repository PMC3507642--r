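#' Construct a cistrome set
#'
#' A `CistromeSet` is the collection of binding sites (peaks) of a
#' transcription factor observed in one condition. It is stored as a
#' data frame with one row per peak and a condition label. Coordinates are
#' 0-based half-open throughout the package (BED convention).
#'
#' @param peaks data frame with columns `chrom`, `start`, `end` and
#'   optionally `summit` (absolute bp; defaults to the interval midpoint),
#'   `score` (peak-caller binding score, defaults to 0), `fold_enrichment`
#'   (defaults to 0) and `id` (unique labels, auto-generated when absent).
#' @param label condition name, e.g. `"R1881plus"` or an antagonist dose.
#' @return an object of class `CistromeSet`: the validated peak data frame
#'   with a `label` attribute.
#' @examples
#' cs <- cistrome_set(data.frame(chrom = "chr1", start = 100, end = 600,
#'                               score = 800, fold_enrichment = 25),
#'                    label = "R1881plus")
#' n_peaks(cs)
#' @export
cistrome_set <- function(peaks, label = "cistrome") {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0L) {
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), summit = integer(),
                        score = numeric(), fold_enrichment = numeric(),
                        id = character())
  }
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) stopf("peaks lack required column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(peaks$summit))
    peaks$summit <- floor((peaks$start + peaks$end) / 2)
  if (is.null(peaks$score)) peaks$score <- 0
  if (is.null(peaks$fold_enrichment)) peaks$fold_enrichment <- 0
  if (is.null(peaks$id))
    peaks$id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  peaks$id <- as.character(peaks$id)
  peaks <- peaks[c("chrom", "start", "end", "summit", "score",
                   "fold_enrichment", "id")]
  validate_peaks(peaks)
  structure(peaks, class = c("CistromeSet", "data.frame"), label = label)
}

validate_peaks <- function(p) {
  if (nrow(p) == 0L) return(invisible(p))
  if (any(is.na(p$chrom)) || any(!nzchar(p$chrom)))
    stopf("peak chromosome names must be non-empty")
  if (any(p$start < 0)) stopf("peak start must be >= 0")
  if (any(p$end <= p$start)) stopf("peak end must exceed start")
  bad <- p$summit < p$start | p$summit >= p$end
  if (any(bad))
    stopf("summit outside [start, end) for peak(s): %s",
          paste(utils::head(p$id[bad], 5L), collapse = ", "))
  if (any(p$score < 0)) stopf("peak scores must be >= 0")
  if (any(p$fold_enrichment < 0)) stopf("fold enrichment must be >= 0")
  if (anyDuplicated(p$id)) stopf("peak ids must be unique within a set")
  invisible(p)
}

#' @rdname cistrome_set
#' @param x a `CistromeSet`
#' @export
n_peaks <- function(x) nrow(x)

#' @export
print.CistromeSet <- function(x, ...) {
  cat(sprintf("CistromeSet '%s': %d peak(s) on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' @rdname cistrome_set
#' @export
set_label <- function(x) attr(x, "label")

# internal: GRanges from 0-based half-open coordinates
gr_intervals <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1L, end = end))
}
gr_peaks   <- function(cs) gr_intervals(cs$chrom, cs$start, cs$end)
gr_summits <- function(cs) gr_intervals(cs$chrom, cs$summit, cs$summit + 1L)

#' Read peaks from a file
#'
#' Supports two dialects: `"bed6+"` (BED6 with two optional extra columns,
#' fold enrichment and summit offset relative to `start`) and
#' `"macs-xls"` (a MACS-style tab table with header columns `chr`, `start`,
#' `end`, `summit`, `score` (-10*log10 p-value) and `fold_enrichment`,
#' 1-based inclusive coordinates, converted to 0-based half-open on read).
#'
#' @param path file path.
#' @param dialect `"bed6+"` or `"macs-xls"`.
#' @param label condition label for the resulting set (defaults to the
#'   file base name).
#' @return a [cistrome_set()].
#' @export
read_peaks <- function(path, dialect = c("bed6+", "macs-xls"),
                       label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("peak file not found: %s", path)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (dialect == "macs-xls" && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warnf("no peak records in %s; returning empty set", path)
    return(cistrome_set(data.frame(chrom = character(), start = integer(),
                                   end = integer()), label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  minf <- if (dialect == "bed6+") 3L else 6L
  if (any(nf < minf))
    stopf("malformed line %d in %s: expected >= %d fields, found %d",
          which(nf < minf)[1L], path, minf, nf[which(nf < minf)[1L]])
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v))
      stopf("malformed line %d in %s: non-numeric %s",
            which(is.na(v))[1L], path, what)
    v
  }
  if (dialect == "bed6+") {
    start <- as.integer(num(2, "start"))
    end <- as.integer(num(3, "end"))
    d <- data.frame(chrom = get(1), start = start, end = end,
                    id = if (all(nf >= 4L)) get(4) else NA,
                    score = if (all(nf >= 5L)) num(5, "score") else 0)
    d$fold_enrichment <- if (all(nf >= 7L)) num(7, "fold enrichment") else 0
    d$summit <- if (all(nf >= 8L))
      start + as.integer(num(8, "summit offset")) else NULL
    if (all(is.na(d$id))) d$id <- NULL
  } else {
    start1 <- as.integer(num(2, "start"))
    d <- data.frame(chrom = get(1),
                    start = start1 - 1L,              # 1-based -> 0-based
                    end = as.integer(num(3, "end")),  # inclusive -> half-open
                    summit = as.integer(num(4, "summit")) - 1L,
                    score = num(5, "score"),
                    fold_enrichment = num(6, "fold enrichment"))
  }
  cistrome_set(d, label = label)
}

#' Write peaks as BED6+2
#'
#' Columns: chrom, start, end, id, score, strand (`.`), fold enrichment,
#' summit offset from start.
#' @param x a `CistromeSet`
#' @param path output path
#' @export
write_peaks <- function(x, path) {
  d <- data.frame(x$chrom, x$start, x$end, x$id, x$score, ".",
                  x$fold_enrichment, x$summit - x$start)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene models
#'
#' Minimal transcript table used for TSS association and annotation
#' classification. `tss` is the transcription start: for `+` strand
#' transcripts it equals the transcript start, for `-` strand the last
#' base of the transcript.
#'
#' @param models data frame with columns `gene`, `chrom`, `strand`, `tss`
#'   and optionally `tx_start`, `tx_end`, `exon_starts`, `exon_ends`
#'   (comma-separated 0-based half-open exon coordinates, refFlat style).
#' @return a validated `GeneModels` data frame.
#' @export
gene_models <- function(models) {
  m <- as.data.frame(models)
  req <- c("gene", "chrom", "strand", "tss")
  miss <- setdiff(req, names(m))
  if (length(miss)) stopf("gene models lack column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(m) && !all(m$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  for (opt in c("tx_start", "tx_end"))
    if (is.null(m[[opt]])) m[[opt]] <- NA_integer_
  for (opt in c("exon_starts", "exon_ends"))
    if (is.null(m[[opt]])) m[[opt]] <- ""
  structure(m, class = c("GeneModels", "data.frame"))
}

#' Read a refFlat table
#'
#' Tab-delimited UCSC refFlat: geneName, name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds. One row per
#' transcript; genes may have several transcripts.
#' @param path file path
#' @return a [gene_models()] table
#' @export
read_refflat <- function(path) {
  if (!file.exists(path)) stopf("refFlat file not found: %s", path)
  d <- read.table(path, sep = "\t", header = FALSE, quote = "",
                  comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(d) < 11L) stopf("refFlat table needs 11 columns, found %d",
                           ncol(d))
  names(d)[1:11] <- c("gene", "tx_name", "chrom", "strand", "tx_start",
                      "tx_end", "cds_start", "cds_end", "exon_count",
                      "exon_starts", "exon_ends")
  d$tss <- ifelse(d$strand == "+", d$tx_start, d$tx_end - 1L)
  gene_models(d[c("gene", "chrom", "strand", "tss", "tx_start", "tx_end",
                  "exon_starts", "exon_ends")])
}

#' Overlap two cistrome sets
#'
#' Two peaks overlap when they share at least 1 bp (half-open adjacency
#' does not count).
#'
#' @param a,b `CistromeSet`s on the same assembly.
#' @return a list: `pairs` (data frame of overlapping `a_id`/`b_id`),
#'   `map` (named list a-peak id -> overlapping b-peak ids),
#'   `n_shared_a`, `n_shared_b` (peaks of each set with >= 1 overlap in the
#'   other), `n_unique_a`, `n_unique_b`.
#' @export
overlap_sets <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(pairs = data.frame(a_id = character(), b_id = character()),
                map = list(),
                n_shared_a = 0L, n_shared_b = 0L,
                n_unique_a = nrow(a), n_unique_b = nrow(b)))
  }
  # disjoint chromosome sets are a legitimate empty overlap, not a
  # user-facing condition
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_peaks(a), gr_peaks(b),
                                minoverlap = 1L))
  qa <- S4Vectors::queryHits(hits); sb <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(a_id = a$id[qa], b_id = b$id[sb],
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       map = split(pairs$b_id, pairs$a_id),
       n_shared_a = length(unique(qa)),
       n_shared_b = length(unique(sb)),
       n_unique_a = nrow(a) - length(unique(qa)),
       n_unique_b = nrow(b) - length(unique(sb)))
}

#' Associate peaks with genes by TSS proximity
#'
#' A gene is associated with every peak whose summit (default) lies within
#' `max_dist` bp of one of the gene's transcription start sites; the bound
#' is inclusive. For multi-transcript genes the nearest TSS is used. The
#' distance is the absolute summit-to-TSS offset, regardless of strand.
#'
#' @param cistrome a `CistromeSet`.
#' @param genes a [gene_models()] table.
#' @param max_dist association window in bp (default 25000).
#' @param anchor `"summit"` (default) or `"edge"` (distance from the
#'   nearest peak boundary).
#' @return data frame with columns `gene`, `peak_id`, `distance`, one row
#'   per association; zero rows when nothing associates.
#' @export
map_to_tss <- function(cistrome, genes, max_dist = 25000,
                       anchor = c("summit", "edge")) {
  anchor <- match.arg(anchor)
  if (!is.numeric(max_dist) || max_dist <= 0) stopf("max_dist must be > 0")
  empty <- data.frame(gene = character(), peak_id = character(),
                      distance = numeric())
  g <- as.data.frame(genes)
  bad <- is.na(g$chrom) | !nzchar(g$chrom)
  if (any(bad)) {
    warnf("%d gene model(s) with unknown chromosome skipped", sum(bad))
    g <- g[!bad, , drop = FALSE]
  }
  if (nrow(cistrome) == 0L || nrow(g) == 0L) return(empty)
  win <- gr_intervals(g$chrom, pmax(g$tss - max_dist, 0),
                      g$tss + max_dist + 1L)
  anc <- if (anchor == "summit") gr_summits(cistrome) else
    gr_peaks(cistrome)
  hits <- GenomicRanges::findOverlaps(win, anc)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dist <- if (anchor == "summit") {
    abs(cistrome$summit[si] - g$tss[qi])
  } else {
    pmax(0, pmax(cistrome$start[si] - g$tss[qi],
                 g$tss[qi] - (cistrome$end[si] - 1L)))
  }
  keep <- dist <= max_dist
  out <- data.frame(gene = g$gene[qi][keep],
                    peak_id = cistrome$id[si][keep],
                    distance = dist[keep], stringsAsFactors = FALSE)
  # nearest TSS per (gene, peak): collapse duplicate transcript hits
  out <- out[order(out$gene, out$peak_id, out$distance), , drop = FALSE]
  out <- out[!duplicated(out[c("gene", "peak_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify peaks by genomic annotation
#'
#' Assigns each peak to one category with precedence
#' promoter > exonic > intronic > intergenic (a peak overlapping both a
#' promoter and an exon counts as promoter). Promoters are strand-aware
#' windows around each TSS (`promoter_window[1]` upstream to
#' `promoter_window[2]` downstream). Fold over-representation per category
#' is the observed peak fraction divided by the fraction of the genome the
#' category covers under the same precedence.
#'
#' @param cistrome a `CistromeSet`.
#' @param genes a [gene_models()] table; exon columns may be empty.
#' @param promoter_window length-2 numeric, bp relative to the TSS in
#'   transcript orientation; default `c(-1000, 100)`.
#' @param chrom_sizes named vector of chromosome lengths for the genomic
#'   background; when `NULL` the maximum observed coordinate per chromosome
#'   is used.
#' @return list with `counts` (named integer, sums to `n_peaks`),
#'   `fractions`, `background` and `enrichment` (observed/background;
#'   `NA` where the background fraction is zero).
#' @export
classify_annotation <- function(cistrome, genes,
                                promoter_window = c(-1000, 100),
                                chrom_sizes = NULL) {
  cats <- c("promoter", "exonic", "intronic", "intergenic")
  g <- as.data.frame(genes)
  up <- promoter_window[1]; dn <- promoter_window[2]
  prom_start <- ifelse(g$strand == "+", g$tss + up, g$tss - dn)
  prom_end   <- ifelse(g$strand == "+", g$tss + dn + 1, g$tss - up + 1)
  prom <- gr_intervals(g$chrom, pmax(prom_start, 0), prom_end)

  parse_exons <- function(s) as.integer(strsplit(s, ",")[[1]])
  ex_list <- lapply(seq_len(nrow(g)), function(i) {
    if (!nzchar(g$exon_starts[i])) return(NULL)
    data.frame(chrom = g$chrom[i],
               start = parse_exons(g$exon_starts[i]),
               end = parse_exons(g$exon_ends[i]))
  })
  ex <- do.call(rbind, ex_list)
  exon_gr <- if (is.null(ex) || nrow(ex) == 0L)
    GenomicRanges::GRanges() else gr_intervals(ex$chrom, ex$start, ex$end)
  has_tx <- !is.na(g$tx_start) & !is.na(g$tx_end)
  tx_gr <- if (any(has_tx))
    gr_intervals(g$chrom[has_tx], g$tx_start[has_tx], g$tx_end[has_tx])
  else GenomicRanges::GRanges()

  pk <- gr_peaks(cistrome)
  in_prom <- IRanges::overlapsAny(pk, prom)
  in_exon <- IRanges::overlapsAny(pk, exon_gr)
  in_tx   <- IRanges::overlapsAny(pk, tx_gr)
  cat_of <- ifelse(in_prom, "promoter",
                   ifelse(in_exon, "exonic",
                          ifelse(in_tx, "intronic", "intergenic")))
  counts <- setNames(as.integer(table(factor(cat_of, levels = cats))), cats)

  if (is.null(chrom_sizes)) {
    all_chr <- unique(c(cistrome$chrom, g$chrom))
    chrom_sizes <- vapply(all_chr, function(ch)
      max(c(cistrome$end[cistrome$chrom == ch], g$tss[g$chrom == ch] + 1,
            g$tx_end[g$chrom == ch]), na.rm = TRUE), numeric(1))
  }
  genome_bp <- sum(chrom_sizes)
  cov_bp <- function(grl) {
    if (!length(grl)) return(0)
    sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(grl))))
  }
  prom_r <- GenomicRanges::reduce(prom)
  exon_r <- GenomicRanges::setdiff(GenomicRanges::reduce(exon_gr), prom_r,
                                   ignore.strand = TRUE)
  tx_r <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(GenomicRanges::reduce(tx_gr), prom_r,
                           ignore.strand = TRUE),
    exon_r, ignore.strand = TRUE)
  bg_bp <- c(promoter = cov_bp(prom_r), exonic = cov_bp(exon_r),
             intronic = cov_bp(tx_r))
  bg_bp <- c(bg_bp, intergenic = max(genome_bp - sum(bg_bp), 0))
  background <- bg_bp / genome_bp
  fractions <- if (sum(counts)) counts / sum(counts) else counts * NA_real_
  enrichment <- ifelse(background > 0, fractions / background, NA_real_)
  list(counts = counts, fractions = fractions,
       background = background, enrichment = enrichment)
}
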