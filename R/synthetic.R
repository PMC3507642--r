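#' Built-in synthetic motifs
#'
#' `default_are_pwm()` is a 15 bp perfectly palindromic hormone-response
#' element (AGAACAnnnTGTTCT-style inverted repeat with a neutral center),
#' the kind of motif bound by a steroid-receptor homodimer.
#' `default_partner_pwm()` is a forkhead-like 7 bp partner element.
#' @export
default_are_pwm <- function()
  pwm_from_consensus("AGAACANNNTGTTCT", fidelity = 0.85)

#' @rdname default_are_pwm
#' @export
default_partner_pwm <- function() pwm_from_consensus("TGTTTAC",
                                                     fidelity = 0.85)

#' Synthetic experiment configuration
#'
#' Defines the study conditions emulated by the generator: a genome, a
#' spectrum of site affinities, a dose series with near-nested occupancy
#' (weaker sites lost first), Poisson tag counts with site enrichment,
#' swapped-channel negative peaks below the confidence cutoffs, conserved
#' elements centered on summits, palindromic + partner motifs planted at
#' preferred spacing, and expression responses coupled to binding loss.
#'
#' @param seed root RNG seed.
#' @param n_chroms,chrom_length genome shape (default 4 x 5 Mb).
#' @param n_sites number of binding sites, default 2000.
#' @param affinity_meanlog,affinity_sdlog log-normal affinity law.
#' @param conditions named numeric vector of occupancy quantiles in
#'   increasing stringency: a site is occupied in a condition when its
#'   affinity is at or above that quantile of the affinity distribution.
#'   The default mirrors an agonist-saturated reference (all sites), three
#'   antagonist doses of increasing impact, and an agonist-free minimum.
#' @param occupancy_noise probability that a site's occupancy call is
#'   flipped, independently per site and condition (in `[0, 0.5)`).
#' @param background_rate Poisson mean tag count per 32 bp bin outside
#'   sites (about the genome-wide tag density of a 50M-read experiment).
#' @param enrichment_gain added Poisson mean per bin per affinity unit at
#'   fully occupied sites.
#' @param residual_exponent binding at a site below a condition's
#'   affinity threshold is not zero but retains a residual fraction
#'   `(affinity/threshold)^residual_exponent` of its full enrichment
#'   (mass-action-style depletion), so sites further below the threshold
#'   lose proportionally more signal.
#' @param site_width peak width in bp.
#' @param score_base,score_scale,score_sd,fe_base,fe_scale,fe_sd linear
#'   models mapping affinity to the emitted binding score and fold
#'   enrichment (spanning roughly 500-3100 and 20-45 for the default
#'   affinity law).
#' @param n_negative_peaks swapped-channel peaks per condition.
#' @param n_genes,frac_linked,activation_fraction expression coupling:
#'   number of genes, fraction linked one-to-one to sites, fraction of
#'   linked genes regulated by activation (the rest by repression).
#' @param conserved_width,conserved_score conservation planting.
#' @param are_pwm,partner_pwm,partner_spacing motif planting; spacing is
#'   middle-to-middle in bp.
#' @param motif_mut_max maximal per-base mutation rate of the planted
#'   consensus for the weakest site (decays to 0 for the strongest, so
#'   stronger sites carry cleaner motifs).
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_chroms = 4, chrom_length = 5e6,
                             n_sites = 2000,
                             affinity_meanlog = 0, affinity_sdlog = 0.5,
                             conditions = c(R1881plus = 0,
                                            antag_0.1uM = 0.2592,
                                            antag_1uM = 0.5184,
                                            antag_10uM = 0.8554,
                                            R1881minus = 0.864),
                             occupancy_noise = 0.02,
                             background_rate = 2,
                             enrichment_gain = 10,
                             residual_exponent = 2,
                             site_width = 400,
                             score_base = 510, score_scale = 350,
                             score_sd = 3,
                             fe_base = 21, fe_scale = 10, fe_sd = 0.3,
                             n_negative_peaks = 300,
                             n_genes = 1000, frac_linked = 0.4,
                             activation_fraction = 0.5,
                             conserved_width = 300,
                             conserved_score = 0.85,
                             are_pwm = default_are_pwm(),
                             partner_pwm = default_partner_pwm(),
                             partner_spacing = 15,
                             motif_mut_max = 0.15) {
  cfg <- as.list(environment())
  if (cfg$n_sites <= 0 || cfg$n_genes <= 0 || cfg$n_chroms <= 0)
    stopf("counts must be > 0")
  if (cfg$occupancy_noise < 0 || cfg$occupancy_noise >= 0.5)
    stopf("occupancy_noise must lie in [0, 0.5)")
  if (is.unsorted(cfg$conditions))
    stopf("condition occupancy quantiles must be non-decreasing (doses ordered by increasing stringency)")
  if (any(cfg$conditions < 0 | cfg$conditions >= 1))
    stopf("occupancy quantiles must lie in [0, 1)")
  structure(cfg, class = "SyntheticConfig")
}

#' Generate the synthetic ground truth
#'
#' Draws site positions and affinities, occupancy per condition (affinity
#' at or above the condition's threshold, flipped with probability
#' `occupancy_noise`), per-site emitted score/fold-enrichment, gene-site
#' linkage with regulation modes, and (optionally) the genome sequence
#' with the palindromic element and its partner planted at each site.
#'
#' @param config a [synthetic_config()].
#' @param sequences also generate the genome sequence with planted motifs
#'   (needed by motif analyses; off by default as it dominates run time
#'   for large genomes).
#' @return a `TruthSet` list: `config`, `sites` (with affinity, score,
#'   fold enrichment, coordinates), `occupancy` (site x condition logical
#'   matrix), `thresholds`, `genes` (TSS, linkage, mode), and `genome`
#'   (named character vector) when `sequences = TRUE`.
#' @export
generate_truth <- function(config, sequences = FALSE) {
  cfg <- config
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  sites <- with_seed(substream_seed(cfg$seed, "sites"), {
    # one jittered grid slot per site: guarantees separation, keeps
    # placement random
    per_chrom <- diff(round(seq(0, cfg$n_sites,
                                length.out = cfg$n_chroms + 1)))
    margin <- 30000
    rows <- lapply(seq_len(cfg$n_chroms), function(ci) {
      n <- per_chrom[ci]
      if (n == 0) return(NULL)
      slot <- (cfg$chrom_length - 2 * margin) / n
      centers <- margin + (seq_len(n) - 0.5) * slot +
        runif(n, -0.25, 0.25) * slot
      data.frame(chrom = chroms[ci], summit = as.integer(round(centers)))
    })
    s <- do.call(rbind, rows)
    s$affinity <- rlnorm(nrow(s), cfg$affinity_meanlog, cfg$affinity_sdlog)
    s$score <- cfg$score_base + cfg$score_scale * s$affinity +
      rnorm(nrow(s), 0, cfg$score_sd)
    s$fold_enrichment <- cfg$fe_base + cfg$fe_scale * s$affinity +
      rnorm(nrow(s), 0, cfg$fe_sd)
    s$start <- s$summit - cfg$site_width %/% 2L
    s$end <- s$start + cfg$site_width
    s$id <- sprintf("site_%05d", seq_len(nrow(s)))
    s
  })

  thresholds <- quantile(sites$affinity, cfg$conditions, names = FALSE)
  names(thresholds) <- names(cfg$conditions)
  occ_clean <- vapply(thresholds, function(th) sites$affinity >= th,
                      logical(nrow(sites)))
  occupancy <- with_seed(substream_seed(cfg$seed, "occupancy"), {
    flips <- matrix(runif(length(occ_clean)) < cfg$occupancy_noise,
                    nrow = nrow(occ_clean))
    xor(occ_clean, flips)
  })
  dimnames(occupancy) <- list(sites$id, names(cfg$conditions))
  dimnames(occ_clean) <- dimnames(occupancy)

  genes <- with_seed(substream_seed(cfg$seed, "genes"), {
    n <- cfg$n_genes
    n_linked <- round(cfg$frac_linked * n)
    if (n_linked > nrow(sites))
      stopf("frac_linked requires more sites than available")
    g <- data.frame(gene = sprintf("GENE%04d", seq_len(n)),
                    linked = c(rep(TRUE, n_linked),
                               rep(FALSE, n - n_linked)),
                    site_id = NA_character_, mode = NA_character_,
                    chrom = NA_character_, tss = NA_integer_,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
    linked_sites <- sample(nrow(sites), n_linked)
    g$site_id[seq_len(n_linked)] <- sites$id[linked_sites]
    g$mode[seq_len(n_linked)] <-
      ifelse(runif(n_linked) < cfg$activation_fraction,
             "activation", "repression")
    g$chrom[seq_len(n_linked)] <- sites$chrom[linked_sites]
    off <- sample(c(-1, 1), n_linked, TRUE) *
      round(runif(n_linked, 500, 20000))
    g$tss[seq_len(n_linked)] <-
      pmax(sites$summit[linked_sites] + off, 0L)
    unl <- which(!g$linked)
    g$chrom[unl] <- sample(chroms, length(unl), replace = TRUE)
    g$tss[unl] <- round(runif(length(unl), 1000, cfg$chrom_length - 1000))
    g
  })

  truth <- list(config = cfg, chrom_sizes = chrom_sizes, sites = sites,
                thresholds = thresholds, occupancy = occupancy,
                occupancy_noise_free = occ_clean, genes = genes)
  if (sequences) truth$genome <- synth_genome(truth)
  structure(truth, class = "TruthSet")
}

# random genome with motifs planted at every site; motif fidelity
# improves with affinity rank so stronger sites carry cleaner elements
synth_genome <- function(truth) {
  cfg <- truth$config
  with_seed(substream_seed(cfg$seed, "genome"), {
    genome <- vapply(names(truth$chrom_sizes), function(ch)
      paste(sample(BASES, truth$chrom_sizes[[ch]], replace = TRUE),
            collapse = ""), character(1))
    are_cons <- strsplit(consensus(cfg$are_pwm), "")[[1]]
    par_cons <- strsplit(consensus(cfg$partner_pwm), "")[[1]]
    w_are <- length(are_cons); w_par <- length(par_cons)
    pct <- rank(truth$sites$affinity) / nrow(truth$sites)
    p_mut <- cfg$motif_mut_max * (1 - pct)
    for (i in seq_len(nrow(truth$sites))) {
      ch <- truth$sites$chrom[i]; sm <- truth$sites$summit[i]
      mutate <- function(cons, p) {
        hit <- runif(length(cons)) < p
        cons[hit] <- sample(BASES, sum(hit), replace = TRUE)
        paste(cons, collapse = "")
      }
      a0 <- sm - w_are %/% 2L                       # ARE centered on summit
      substr(genome[[ch]], a0 + 1L, a0 + w_are) <-
        mutate(are_cons, p_mut[i])
      # partner middle-to-middle at the configured spacing, downstream
      pmid <- sm + cfg$partner_spacing
      p0 <- pmid - w_par %/% 2L
      substr(genome[[ch]], p0 + 1L, p0 + w_par) <-
        mutate(par_cons, p_mut[i])
    }
    genome
  })
}

truth_conditions <- function(truth) colnames(truth$occupancy)

#' Planted percent impact
#'
#' The ground-truth analogue of [percent_impact()]: among sites occupied
#' in the maximum (first) condition but not the minimum (last) condition,
#' the percentage not occupied in `condition`. With `noise_free = TRUE`
#' the occupancy implied directly by the affinity thresholds is used.
#'
#' @param truth a `TruthSet`.
#' @param condition condition label.
#' @param noise_free ignore the planted occupancy noise.
#' @export
truth_impact <- function(truth, condition, noise_free = FALSE) {
  occ <- if (noise_free) truth$occupancy_noise_free else truth$occupancy
  conds <- colnames(occ)
  differential <- occ[, conds[1]] & !occ[, conds[length(conds)]]
  if (!sum(differential)) stopf("no differential sites in truth")
  100 * sum(differential & !occ[, condition]) / sum(differential)
}

#' Emit the observable data for one condition
#'
#' Produces what a ChIP experiment of the condition would yield: a binned
#' tag track (Poisson background everywhere plus affinity-proportional
#' enrichment over occupied sites), the positive peak set (occupied
#' sites), a swapped-channel negative peak set with scores strictly below
#' the confidence cutoffs, a conserved-element track centered on occupied
#' summits, and (when the truth carries a genome) the occupied-site
#' sequences.
#'
#' @param truth a `TruthSet` from [generate_truth()].
#' @param condition one of the configured condition labels.
#' @param sequences extract occupied-site sequences (requires
#'   `generate_truth(..., sequences = TRUE)`).
#' @return list with `track`, `positive`, `negative`, `conserved` and
#'   optionally `sequences` (named `id -> sequence`, `chroms` attribute).
#' @export
emit_condition <- function(truth, condition, sequences = FALSE) {
  cfg <- truth$config
  if (!condition %in% truth_conditions(truth))
    stopf("unknown condition '%s'", condition)
  occ <- truth$occupancy[, condition]
  s <- truth$sites
  bin <- 32L

  # occupied sites carry full enrichment; sites below the condition's
  # threshold keep a residual (affinity/threshold)^h fraction, so weaker
  # sites lose proportionally more signal under antagonism
  thr <- truth$thresholds[[condition]]
  frac <- ifelse(occ, 1,
                 pmin((s$affinity / max(thr, .Machine$double.eps))^
                        cfg$residual_exponent, 0.8))
  track <- with_seed(substream_seed(cfg$seed, paste0("track_", condition)), {
    counts <- lapply(truth$chrom_sizes, function(L) {
      nb <- as.integer(ceiling(L / bin))
      rpois(nb, cfg$background_rate)
    })
    for (i in which(frac > 0)) {
      ch <- s$chrom[i]
      b0 <- s$start[i] %/% bin + 1L
      b1 <- (s$end[i] - 1L) %/% bin + 1L
      counts[[ch]][b0:b1] <- counts[[ch]][b0:b1] +
        rpois(b1 - b0 + 1L, cfg$enrichment_gain * s$affinity[i] * frac[i])
    }
    structure(list(bin_size = bin, extension = 200,
                   chrom_sizes = truth$chrom_sizes,
                   counts = lapply(counts, as.integer),
                   total_tags = NA_integer_, n_rejected = 0L),
              class = "TagTrack")
  })

  positive <- cistrome_set(s[occ, c("chrom", "start", "end", "summit",
                                    "score", "fold_enrichment", "id")],
                           label = condition)

  negative <- with_seed(substream_seed(cfg$seed, paste0("neg_", condition)), {
    n <- cfg$n_negative_peaks
    ch <- sample(names(truth$chrom_sizes), n, replace = TRUE)
    pos <- round(runif(n, 5000, cfg$chrom_length - 5000))
    # keep spurious peaks clear of true sites
    for (k in seq_len(n)) {
      same <- s$summit[s$chrom == ch[k]]
      while (length(same) && min(abs(same - pos[k])) < 1500)
        pos[k] <- round(runif(1, 5000, cfg$chrom_length - 5000))
    }
    w <- cfg$site_width
    cistrome_set(data.frame(chrom = ch, start = pos - w %/% 2L,
                            end = pos - w %/% 2L + w, summit = pos,
                            score = runif(n, 50, 0.96 * cfg$score_base),
                            fold_enrichment = runif(n, 2,
                                                    0.9 * cfg$fe_base),
                            id = sprintf("neg_%05d", seq_len(n))),
                 label = paste0(condition, "_swapped"))
  })

  half_w <- cfg$conserved_width %/% 2L
  cons <- s[occ, , drop = FALSE]
  cons_df <- data.frame(chrom = cons$chrom,
                        start = pmax(cons$summit - half_w, 0L),
                        end = cons$summit - half_w + cfg$conserved_width,
                        score = cfg$conserved_score)
  conserved <- conserved_elements(cons_df)

  out <- list(track = track, positive = positive, negative = negative,
              conserved = conserved)
  if (sequences) {
    if (is.null(truth$genome))
      stopf("truth has no genome; call generate_truth(sequences = TRUE)")
    seqs <- substring(truth$genome[cons$chrom], cons$start + 1L, cons$end)
    names(seqs) <- cons$id
    attr(seqs, "chroms") <- cons$chrom
    out$sequences <- seqs
  }
  out
}

#' Emit a differential-expression table for one condition
#'
#' Genes linked to a site occupied in the reference (first) condition but
#' lost in `condition` respond: activation-mode genes go down, repression
#' -mode genes go up, with log2 magnitudes drawn clear of the 1.5-fold
#' cutoff in expectation. All other genes are null. d-scores are standard
#' normal under the null and shifted for responders; p-values derive from
#' the d-scores and q-values from the resulting mixture via [qvalues()].
#'
#' @param truth a `TruthSet`.
#' @param condition condition label.
#' @return a [de_table()] (one probe per gene, probe ids `<gene>_at`)
#'   with attribute `responders` naming the truly responding genes.
#' @export
emit_expression <- function(truth, condition) {
  cfg <- truth$config
  if (!condition %in% truth_conditions(truth))
    stopf("unknown condition '%s'", condition)
  ref <- truth_conditions(truth)[1]
  g <- truth$genes
  site_i <- match(g$site_id, truth$sites$id)
  linked <- !is.na(site_i)
  lost <- logical(nrow(g))
  lost[linked] <- truth$occupancy[site_i[linked], ref] &
    !truth$occupancy[site_i[linked], condition]
  with_seed(substream_seed(cfg$seed, paste0("expr_", condition)), {
    n <- nrow(g)
    sgn <- ifelse(g$mode == "activation", -1, 1)
    l2 <- abs(rnorm(n, 0, 0.15))                    # null log2 magnitude
    l2[lost] <- rnorm(sum(lost), 1.3, 0.35)        # responders
    l2 <- pmax(l2, 0)
    fc_sign <- ifelse(lost, sgn, sample(c(-1, 1), n, replace = TRUE))
    d <- rnorm(n)                                   # null d-scores
    d[lost] <- fc_sign[lost] * (6 + rnorm(sum(lost)))
    p <- 2 * pnorm(-abs(d))
    tab <- de_table(data.frame(
      probe_id = paste0(g$gene, "_at"), gene = g$gene,
      fold_change = fc_sign * 2^l2, d_score = d,
      q_value = qvalues(p)))
    attr(tab, "responders") <- g$gene[lost]
    tab
  })
}
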