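#' Build a binned tag-density track
#'
#' The genome is divided into fixed-width bins (default 32 nt) and each
#' sequenced tag, extended `extension` bp from its 5' end in the 3'
#' direction, increments every bin it overlaps.
#'
#' @param tags data frame with columns `chrom`, `pos` (0-based 5' position)
#'   and `strand` (`+`/`-`).
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param bin_size bin width in bp, default 32.
#' @param extension 3' extension length in bp, default 200 (approximates
#'   the sequenced fragment length).
#' @return a `TagTrack`: list with `bin_size`, `extension`, `chrom_sizes`,
#'   `counts` (named list of per-chromosome integer vectors),
#'   `total_tags` and `n_rejected` (tags outside chromosome bounds).
#' @export
build_tag_track <- function(tags, chrom_sizes, bin_size = 32,
                            extension = 200) {
  if (bin_size <= 0) stopf("bin_size must be > 0")
  if (extension <= 0) stopf("extension must be > 0")
  counts <- lapply(chrom_sizes, function(L)
    integer(ceiling(L / bin_size)))
  n_rej <- 0L; n_acc <- 0L
  if (nrow(tags)) {
    known <- tags$chrom %in% names(chrom_sizes)
    inb <- known & tags$pos >= 0 &
      tags$pos < chrom_sizes[match(tags$chrom, names(chrom_sizes))]
    inb[is.na(inb)] <- FALSE
    n_rej <- sum(!inb)
    t2 <- tags[inb, , drop = FALSE]
    n_acc <- nrow(t2)
    if (n_acc) {
      ext_start <- ifelse(t2$strand == "+", t2$pos, t2$pos - extension + 1L)
      ext_end <- ext_start + extension       # half-open
      for (ch in unique(t2$chrom)) {
        sel <- t2$chrom == ch
        L <- chrom_sizes[[ch]]
        s <- pmax(ext_start[sel], 0L)
        e <- pmin(ext_end[sel], L)
        b0 <- s %/% bin_size
        b1 <- (e - 1L) %/% bin_size
        nb <- b1 - b0 + 1L
        idx <- rep.int(b0, nb) + sequence(nb) # 1-based bin index
        counts[[ch]] <- counts[[ch]] +
          tabulate(idx, nbins = length(counts[[ch]]))
      }
    }
  }
  structure(list(bin_size = bin_size, extension = extension,
                 chrom_sizes = chrom_sizes, counts = counts,
                 total_tags = n_acc, n_rejected = n_rej),
            class = "TagTrack")
}

#' @export
print.TagTrack <- function(x, ...) {
  cat(sprintf("TagTrack: %d chromosome(s), bin %d bp, %d tag(s), %d rejected\n",
              length(x$counts), x$bin_size, x$total_tags, x$n_rejected))
  invisible(x)
}

# bin values overlapping a 0-based half-open interval by >= 1 bp
track_bins <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$counts))
    stopf("chromosome %s not in track", chrom)
  if (end <= start) stopf("zero-width interval")
  b0 <- start %/% track$bin_size
  b1 <- (end - 1L) %/% track$bin_size
  v <- track$counts[[chrom]]
  b1 <- min(b1, length(v) - 1L)
  if (b0 > b1) stopf("interval beyond chromosome end")
  v[(b0 + 1L):(b1 + 1L)]
}

#' One-step Tukey biweight
#'
#' Robust weighted mean with bisquare weights computed once from the
#' median and the (raw, unscaled) median absolute deviation:
#' `u = (x - median) / (c * MAD + eps)`, `w = (1 - u^2)^2` for `|u| < 1`
#' and 0 otherwise. With `MAD = 0` any value off the median gets zero
#' weight, so isolated outliers are dropped entirely.
#'
#' @param x numeric vector.
#' @param c tuning constant, default 5.
#' @param eps guard added to `c * MAD`, default 1e-4.
#' @return the biweight estimate (a single number).
#' @examples
#' tukey_biweight(c(1, 1, 1, 10))  # 1: the outlier's weight is zero
#' @export
tukey_biweight <- function(x, c = 5, eps = 1e-4) {
  if (!length(x)) stopf("empty input")
  m <- median(x)
  s <- median(abs(x - m))
  u <- (x - m) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(m)
  sum(w * x) / sum(w)
}

#' Robust per-site signal
#'
#' Combines the tag-density values of all bins overlapping the binding
#' site (by at least 1 bp) with the one-step Tukey biweight, yielding a
#' signal that can be compared for the same site across conditions.
#'
#' @param track a `TagTrack`.
#' @param peak one-row slice of a `CistromeSet` (or any list with `chrom`,
#'   `start`, `end`, `id`).
#' @return list with `peak_id` and `signal` (non-negative).
#' @export
site_signal <- function(track, peak) {
  v <- track_bins(track, peak$chrom[1], peak$start[1], peak$end[1])
  list(peak_id = as.character(peak$id[1]), signal = tukey_biweight(v))
}

# vectorised site signals for a whole cistrome
site_signals <- function(track, cistrome) {
  vapply(seq_len(nrow(cistrome)), function(i)
    tukey_biweight(track_bins(track, cistrome$chrom[i], cistrome$start[i],
                              cistrome$end[i])), numeric(1))
}

#' Signed fold change of two signals
#'
#' The ratio `r = treated / reference` is reported as `r` when `r >= 1`
#' and as `-1/r` otherwise, so magnitudes are symmetric about 1 and the
#' sign carries the direction (negative = signal loss under treatment).
#'
#' @param s_treated,s_reference positive signals (apply a pseudocount
#'   upstream if a signal can be zero).
#' @return signed fold change(s) with `|value| >= 1`.
#' @export
signed_fold_change <- function(s_treated, s_reference) {
  if (any(s_treated <= 0) || any(s_reference <= 0))
    stopf("signals must be > 0")
  r <- s_treated / s_reference
  ifelse(r >= 1, r, -1 / r)
}

#' Per-site signed fold changes between two tracks
#'
#' Computes the biweight signal of each peak under both tracks and returns
#' the signed fold change treated vs reference. When either signal is 0 a
#' pseudocount is added to both before forming the ratio.
#'
#' @param track_treated,track_reference `TagTrack`s.
#' @param cistrome peaks to quantify.
#' @param pseudocount default 0.5.
#' @return data frame `peak_id`, `signal_treated`, `signal_reference`,
#'   `value` (signed fold change).
#' @export
site_fold_changes <- function(track_treated, track_reference, cistrome,
                              pseudocount = 0.5) {
  st <- site_signals(track_treated, cistrome)
  sr <- site_signals(track_reference, cistrome)
  zero <- st == 0 | sr == 0
  st[zero] <- st[zero] + pseudocount
  sr[zero] <- sr[zero] + pseudocount
  data.frame(peak_id = cistrome$id, signal_treated = st,
             signal_reference = sr,
             value = signed_fold_change(st, sr))
}

#' Moving-average dose trend
#'
#' Smooths signed fold changes (ordered by descending site strength) with
#' a moving average and fits a least-squares line to the smoothed series,
#' exposing how treatment effect varies along the binding-strength
#' spectrum.
#'
#' @param values signed fold changes sorted by descending site strength.
#' @param window moving-average window, default 100.
#' @return list with `ma` (length `n - window + 1`), `slope`, `intercept`
#'   of the linear trend over the smoothed series index.
#' @export
dose_trend <- function(values, window = 100) {
  n <- length(values)
  if (window > n) stopf("window (%d) exceeds series length (%d)", window, n)
  cs <- cumsum(c(0, values))
  ma <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  idx <- seq_along(ma)
  fit <- coef(lm(ma ~ idx))
  list(ma = ma, slope = unname(fit[2]), intercept = unname(fit[1]))
}

#' Export / import a tag track as bedGraph
#'
#' One line per run of equal, non-zero bin counts; fixed-step bins of
#' `bin_size` bp. [read_bedgraph()] rebuilds a track given the chromosome
#' sizes and bin size (intervals must align to bin boundaries).
#' @param track a `TagTrack`
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      bs <- track$bin_size
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep] * bs,
                         pmin(ends[keep] * bs, track$chrom_sizes[[ch]]),
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param chrom_sizes,bin_size,extension track geometry, as in
#'   [build_tag_track()]
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size = 32,
                          extension = 200) {
  counts <- lapply(chrom_sizes, function(L) integer(ceiling(L / bin_size)))
  d <- tryCatch(read.table(path, sep = "\t", stringsAsFactors = FALSE),
                error = function(e) NULL)
  if (!is.null(d)) {
    names(d)[1:4] <- c("chrom", "start", "end", "value")
    if (any(d$start %% bin_size != 0))
      stopf("bedGraph intervals not aligned to %d bp bins", bin_size)
    for (i in seq_len(nrow(d))) {
      ch <- d$chrom[i]
      if (!ch %in% names(counts)) stopf("unknown chromosome %s", ch)
      b0 <- d$start[i] %/% bin_size
      b1 <- (d$end[i] - 1L) %/% bin_size
      counts[[ch]][(b0 + 1L):(b1 + 1L)] <- d$value[i]
    }
  }
  structure(list(bin_size = bin_size, extension = extension,
                 chrom_sizes = chrom_sizes, counts = counts,
                 total_tags = NA_integer_, n_rejected = 0L),
            class = "TagTrack")
}

#' Write a tag track as fixed-step wiggle
#' @inheritParams write_bedgraph
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$counts)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       ch, track$bin_size, track$bin_size), con)
    writeLines(format(track$counts[[ch]], trim = TRUE), con)
  }
  invisible(path)
}
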