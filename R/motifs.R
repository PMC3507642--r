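BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' @param probs 4 x width numeric matrix of base probabilities, rows in
#'   A, C, G, T order (a per-column pseudocount is added and columns are
#'   renormalized).
#' @param pseudocount added to every cell before normalization, default
#'   0.01 (keeps log-odds finite without blunting specificity).
#' @param background optional length-4 base-frequency vector; when absent
#'   the scanned sequence composition is used at scan time.
#' @return an object of class `PWM`.
#' @export
pwm <- function(probs, pseudocount = 0.01, background = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stopf("probs must have 4 rows (A, C, G, T)")
  if (any(probs < 0)) stopf("probabilities must be >= 0")
  p <- sweep(probs + pseudocount, 2, colSums(probs + pseudocount), "/")
  dimnames(p) <- list(BASES, NULL)
  if (!is.null(background)) {
    if (length(background) != 4L) stopf("background must have 4 entries")
    background <- background / sum(background)
    names(background) <- BASES
  }
  structure(list(probs = p, width = ncol(p), pseudocount = pseudocount,
                 background = background), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM: width %d, consensus %s%s\n", x$width, consensus(x),
              if (is_palindromic(x)) " (palindromic)" else ""))
  invisible(x)
}

#' @rdname pwm
#' @param x a `PWM`
#' @export
consensus <- function(x) paste(BASES[apply(x$probs, 2, which.max)],
                               collapse = "")

#' Build a PWM from a consensus sequence
#'
#' Each column places `fidelity` probability on the consensus base and
#' spreads the rest uniformly; `N` gives a uniform column.
#' @param seq consensus string over A, C, G, T, N
#' @param fidelity probability mass on the consensus base, default 0.85
#' @inheritParams pwm
#' @export
pwm_from_consensus <- function(seq, fidelity = 0.85, background = NULL) {
  ch <- strsplit(toupper(seq), "")[[1]]
  probs <- vapply(ch, function(b) {
    if (b == "N") rep(0.25, 4)
    else ifelse(BASES == b, fidelity, (1 - fidelity) / 3)
  }, numeric(4))
  pwm(probs, background = background)
}

# log-odds (bits) matrix for a PWM against a background
logodds_matrix <- function(x, background = NULL) {
  bg <- background %||% x$background %||% rep(0.25, 4)
  bg <- bg / sum(bg)
  log2(x$probs / bg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximal achievable log-odds score of a PWM
#' @inheritParams consensus
#' @param background optional base-frequency vector
#' @export
max_score <- function(x, background = NULL)
  sum(apply(logodds_matrix(x, background), 2, max))

chars_to_int <- function(s) match(strsplit(toupper(s), "")[[1]], BASES)

# scores of all windows of an integer-coded sequence; NA where a window
# contains a non-ACGT base
window_scores <- function(si, lo) {
  w <- ncol(lo); L <- length(si)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1L
  idx <- outer(seq_len(nwin), 0:(w - 1L), "+")
  b <- matrix(si[idx], nrow = nwin)
  rowSums(matrix(lo[cbind(as.vector(b), rep(seq_len(w), each = nwin))],
                 nrow = nwin))
}

count_hits_int <- function(si, lo, threshold) {
  s <- window_scores(si, lo)
  fwd <- sum(!is.na(s) & s >= threshold)
  rc <- rev(5L - si)
  s2 <- window_scores(rc, lo)
  fwd + sum(!is.na(s2) & s2 >= threshold)
}

# composition of a set of sequences as ACGT frequencies
seq_background <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                      "")), levels = BASES))
  f <- as.numeric(tab) + 1
  setNames(f / sum(f), BASES)
}

#' Scan sequences with a PWM
#'
#' Plain log-odds scan of both strands. A window scores the sum of
#' per-position log2(p/background); reverse-strand windows are scored on
#' the reverse complement and reported at their position on the input
#' strand. Windows containing non-ACGT bases are skipped.
#'
#' @param seqs character vector of sequences (names become `seq_id`;
#'   unnamed input is numbered).
#' @param x a [pwm()].
#' @param threshold minimum score in bits; default 60% of the PWM's
#'   maximal achievable score against the background.
#' @param background length-4 base frequencies; defaults to the PWM's
#'   stored background, else the composition of `seqs`.
#' @return data frame `seq_id`, `position` (0-based match start on the
#'   input strand), `strand`, `score`.
#' @export
scan_pwm <- function(seqs, x, threshold = NULL, background = NULL) {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  bg <- background %||% x$background %||% seq_background(seqs)
  lo <- logodds_matrix(x, bg)
  if (is.null(threshold)) threshold <- 0.6 * sum(apply(lo, 2, max))
  w <- x$width
  res <- lapply(names(seqs), function(id) {
    si <- chars_to_int(seqs[[id]])
    L <- length(si)
    if (L < w) return(NULL)
    sf <- window_scores(si, lo)
    sr <- window_scores(rev(5L - si), lo)
    kf <- which(!is.na(sf) & sf >= threshold)
    kr <- which(!is.na(sr) & sr >= threshold)
    rbind(
      if (length(kf)) data.frame(seq_id = id, position = kf - 1L,
                                 strand = "+", score = sf[kf]),
      if (length(kr)) data.frame(seq_id = id,
                                 position = L - w + 1L - kr,
                                 strand = "-", score = sr[kr])
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(seq_id = character(), position = integer(),
                      strand = character(), score = numeric())
  rownames(out) <- NULL
  out
}

#' Is a PWM palindromic?
#'
#' True when the probability matrix equals its reverse complement
#' (columns reversed, bases complemented) within `tol` elementwise — the
#' signature of a motif bound by a head-to-head dimer.
#' @inheritParams consensus
#' @param tol elementwise tolerance, default 1e-6
#' @export
is_palindromic <- function(x, tol = 1e-6) {
  rc <- x$probs[4:1, rev(seq_len(x$width)), drop = FALSE]
  all(abs(x$probs - rc) <= tol)
}

#' Matched-background motif specificity Z-score
#'
#' Counts PWM hits (both strands) in the bound sequences, then repeats the
#' count in `background_groups` random groups of the same number of
#' sequences of the same lengths sampled from the same chromosomes of the
#' genome. Z is the distance of the bound count from the random-group mean
#' in units of the random-group standard deviation.
#'
#' @param bound_seqs character vector of bound-site sequences.
#' @param x a [pwm()].
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences to sample matched groups from.
#' @param chroms chromosome of origin for each bound sequence; defaults to
#'   parsing names of the form `"chrom:start-end"`, else all sequences are
#'   matched against all chromosomes.
#' @param threshold,background as in [scan_pwm()]; the same log-odds
#'   matrix and cutoff are applied to bound and random groups.
#' @param background_groups number of random groups, default 100.
#' @param seed RNG seed; results are reproducible given
#'   (seed, genome, pwm).
#' @return list with `z`, `bound_hits`, `random_mean`, `random_sd`,
#'   `random_counts`. When the random counts have zero variance `z` is
#'   `Inf` (or `-Inf`/`NaN`) with a warning.
#' @export
motif_zscore <- function(bound_seqs, x, genome, chroms = NULL,
                         threshold = NULL, background = NULL,
                         background_groups = 100, seed = 1) {
  genome <- setNames(as.character(genome), names(genome))
  if (is.null(names(genome)))
    names(genome) <- sprintf("chr%d", seq_along(genome))
  if (is.null(chroms)) {
    nm <- names(bound_seqs)
    if (!is.null(nm) && all(grepl(":", nm)))
      chroms <- sub(":.*$", "", nm)
    else
      chroms <- sample(names(genome), length(bound_seqs), replace = TRUE)
  }
  if (!all(chroms %in% names(genome)))
    stopf("bound-sequence chromosome(s) missing from genome")
  bg <- background %||% x$background %||% seq_background(bound_seqs)
  lo <- logodds_matrix(x, bg)
  if (is.null(threshold)) threshold <- 0.6 * sum(apply(lo, 2, max))
  gint <- lapply(genome, chars_to_int)
  lens <- nchar(bound_seqs)
  obs <- sum(vapply(bound_seqs, function(s)
    count_hits_int(chars_to_int(s), lo, threshold), numeric(1)))
  counts <- with_seed(seed, {
    vapply(seq_len(background_groups), function(g) {
      sum(vapply(seq_along(bound_seqs), function(i) {
        gi <- gint[[chroms[i]]]
        L <- length(gi); len <- lens[i]
        if (L < len) stopf("chromosome %s shorter than a bound sequence",
                           chroms[i])
        s0 <- sample.int(L - len + 1L, 1L)
        count_hits_int(gi[s0:(s0 + len - 1L)], lo, threshold)
      }, numeric(1)))
    }, numeric(1))
  })
  mu <- mean(counts); sdev <- stats::sd(counts)
  if (sdev == 0) warnf("random-group counts have zero variance; Z unbounded")
  list(z = (obs - mu) / sdev, bound_hits = obs, random_mean = mu,
       random_sd = sdev, random_counts = counts)
}

#' Spacing histogram between two motif element sets
#'
#' For every pair of A and B hits on the same sequence, the
#' middle-to-middle distance is recorded when it falls within `range`
#' (default 10 to 50 bp). A sharp mode indicates a geometric constraint
#' between the two bound factors.
#'
#' @param hits_a,hits_b hit tables from [scan_pwm()] (sharing `seq_id`s).
#' @param width_a,width_b widths of the two motifs in bp.
#' @param range length-2 integer, inclusive distance range.
#' @return list with `distances` (grid), `counts`, and `mode` (modal
#'   distance; smallest on ties; `NA` when there are no co-occurrences).
#' @export
pair_spacing <- function(hits_a, hits_b, width_a, width_b,
                         range = c(10L, 50L)) {
  grid <- seq.int(range[1], range[2])
  counts <- integer(length(grid))
  shared <- intersect(unique(hits_a$seq_id), unique(hits_b$seq_id))
  for (id in shared) {
    ma <- hits_a$position[hits_a$seq_id == id] + width_a / 2
    mb <- hits_b$position[hits_b$seq_id == id] + width_b / 2
    d <- round(abs(outer(ma, mb, "-")))
    d <- d[d >= range[1] & d <= range[2]]
    if (length(d))
      counts <- counts + tabulate(d - range[1] + 1L, nbins = length(grid))
  }
  mode <- if (sum(counts)) grid[which.max(counts)] else NA_integer_
  list(distances = grid, counts = counts, mode = mode)
}

#' Motif presence vs regulation-mode association
#'
#' Two-tailed Fisher exact test of a motif's presence at binding sites
#' against the mode of regulation of their target genes.
#'
#' @param presence logical vector, motif present at each site.
#' @param mode character vector (`"activation"`/`"repression"`), parallel
#'   to `presence`; both modes must be represented.
#' @return list with the 2x2 `table` and two-tailed `p`.
#' @export
motif_mode_association <- function(presence, mode) {
  if (length(presence) != length(mode)) stopf("inputs must be parallel")
  if (length(unique(mode)) < 2L)
    stopf("both regulation modes must be represented")
  tab <- table(factor(mode), factor(presence, levels = c(TRUE, FALSE)))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
  else fisher.test(tab)$p.value
  list(table = tab, p = p)
}

#' Binding-score vs motif-presence association
#'
#' Rank-sum comparison of binding scores for sites with and without the
#' motif; delegates to [compare_strength_groups()].
#' @param scores_with,scores_without numeric score vectors
#' @export
score_strength_association <- function(scores_with, scores_without)
  compare_strength_groups(scores_with, scores_without)

#' Extract summit-centered sequences for motif discovery
#'
#' Takes the `top_n` strongest sites (by [sort_by_strength()] order) and
#' returns their sequences; sites longer than `max_width` are trimmed to
#' `max_width` bp centered on the summit. Intended to feed external
#' ab initio discovery tools.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param cistrome a `CistromeSet`.
#' @param max_width maximum sequence length, default 500.
#' @param top_n number of strongest sites to keep, default 2500.
#' @return named character vector (`id` -> sequence) with a `chroms`
#'   attribute giving each sequence's chromosome.
#' @export
extract_summit_sequences <- function(genome, cistrome, max_width = 500,
                                     top_n = 2500) {
  genome <- setNames(as.character(genome), names(genome))
  cs <- sort_by_strength(cistrome)
  cs <- utils::head(cs, top_n)
  seqs <- character(nrow(cs)); chroms <- character(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    ch <- cs$chrom[i]
    if (!ch %in% names(genome)) stopf("chromosome %s not in genome", ch)
    s <- cs$start[i]; e <- cs$end[i]
    if (e - s > max_width) {
      s <- max(cs$summit[i] - max_width %/% 2, 0)
      e <- s + max_width
    }
    e <- min(e, nchar(genome[[ch]]))
    seqs[i] <- substr(genome[[ch]], s + 1L, e)
    chroms[i] <- ch
  }
  names(seqs) <- cs$id
  attr(seqs, "chroms") <- chroms
  seqs
}

#' Read sequences from a FASTA file
#' @param path FASTA file
#' @return named character vector
#' @export
read_sequences <- function(path)
  as.character(Biostrings::readDNAStringSet(path))

#' Write sequences to a FASTA file
#' @param seqs named character vector
#' @param path output path
#' @export
write_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' PWM text input/output
#'
#' `write_pwm_tsv`/`read_pwm_tsv` use a simple 4-row (A, C, G, T) by
#' width tab table. `write_meme_minimal`/`read_meme_minimal` use the MEME
#' minimal motif text format (first motif only on read).
#' @param x a [pwm()]
#' @param path file path
#' @export
write_pwm_tsv <- function(x, path) {
  write.table(cbind(base = BASES, as.data.frame(x$probs)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm_tsv
#' @export
read_pwm_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, row.names = 1)
  pwm(as.matrix(d)[BASES, , drop = FALSE], pseudocount = 0)
}

#' @rdname write_pwm_tsv
#' @param name motif name written in the MEME header
#' @export
write_meme_minimal <- function(x, path, name = "motif_1") {
  bg <- x$background %||% rep(0.25, 4)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
             "", "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3],
                     bg[4]), "",
             sprintf("MOTIF %s", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     x$width),
             apply(x$probs, 2, function(col)
               sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3],
                       col[4])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm_tsv
#' @export
read_meme_minimal <- function(path) {
  lines <- readLines(path)
  bg <- NULL
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    v <- as.numeric(strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]][c(2, 4, 6, 8)])
    if (!anyNA(v)) bg <- v
  }
  hdr <- grep("^letter-probability matrix", lines)
  if (!length(hdr)) stopf("no letter-probability matrix in %s", path)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr[1]]))
  rows <- lines[(hdr[1] + 1):(hdr[1] + w)]
  m <- t(vapply(rows, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4]), numeric(4)))
  pwm(t(m), pseudocount = 0, background = bg)
}
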