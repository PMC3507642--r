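#' Assemble a pipeline run configuration
#'
#' Two modes. Synthetic mode (`synthetic` = list of [synthetic_config()]
#' arguments) generates a full dose-series experiment and runs every
#' stage against its ground truth. File mode takes peak files for the
#' maximum, minimum and treated cistromes (plus optionally a
#' swapped-channel negative set, a DE table, a refFlat gene table and a
#' GMT signature file) and runs the filtering/impact/target stages.
#'
#' @param synthetic list of [synthetic_config()] arguments, or `NULL`.
#' @param max_peaks,min_peaks,negative_peaks BED paths (file mode).
#' @param treated_peaks named character vector of BED paths, one per dose
#'   (file mode).
#' @param de_path,genes_path,signatures_path optional TSV/refFlat/GMT
#'   paths.
#' @param thresholds `"auto"` or list(score_cut, fe_cut) for
#'   [filter_high_confidence()].
#' @param fdr,fc_cut,tss_max_dist integration cutoffs.
#' @param stages named logical list toggling `signal`, `conservation`,
#'   `motif`, `expression`, `enrichment`.
#' @param seed root seed recorded in the report.
#' @param out_dir when given, stage artifacts are written there and
#'   checksummed in the report.
#' @return a `RunConfig` list.
#' @export
run_config <- function(synthetic = NULL,
                       max_peaks = NULL, min_peaks = NULL,
                       treated_peaks = NULL, negative_peaks = NULL,
                       de_path = NULL, genes_path = NULL,
                       signatures_path = NULL,
                       thresholds = list(score_cut = 500, fe_cut = 20),
                       fdr = 0.05, fc_cut = 1.5, tss_max_dist = 25000,
                       stages = list(signal = TRUE, conservation = TRUE,
                                     motif = FALSE, expression = TRUE,
                                     enrichment = FALSE),
                       seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Validate a run configuration
#'
#' @param config a [run_config()].
#' @return character vector of problems; empty when the config is
#'   runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$synthetic)) {
    for (f in c("max_peaks", "min_peaks")) {
      if (is.null(config[[f]])) add(sprintf("missing path: %s", f))
      else if (!file.exists(config[[f]]))
        add(sprintf("%s file not found: %s", f, config[[f]]))
    }
    if (is.null(config$treated_peaks) || !length(config$treated_peaks))
      add("missing path: treated_peaks")
    else for (p in config$treated_peaks)
      if (!file.exists(p)) add(sprintf("treated peak file not found: %s", p))
    for (f in c("negative_peaks", "de_path", "genes_path",
                "signatures_path"))
      if (!is.null(config[[f]]) && !file.exists(config[[f]]))
        add(sprintf("%s file not found: %s", f, config[[f]]))
  } else if (!is.list(config$synthetic)) {
    add("synthetic must be a list of synthetic_config() arguments")
  }
  if (!identical(config$thresholds, "auto")) {
    if (!is.list(config$thresholds) ||
        is.null(config$thresholds$score_cut) ||
        is.null(config$thresholds$fe_cut))
      add("thresholds must be 'auto' or list(score_cut, fe_cut)")
    else if (config$thresholds$score_cut < 0 || config$thresholds$fe_cut < 0)
      add("thresholds must be >= 0")
  }
  if (!is.numeric(config$fdr) || config$fdr <= 0 || config$fdr >= 1)
    add("fdr must lie in (0, 1)")
  if (!is.numeric(config$fc_cut) || config$fc_cut < 1)
    add("fc_cut must be >= 1")
  if (!is.numeric(config$tss_max_dist) || config$tss_max_dist <= 0)
    add("tss_max_dist must be > 0")
  problems
}

#' Read / write a run configuration as YAML
#' @param path YAML file
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds) && identical(y$thresholds, "auto"))
    y$thresholds <- "auto"
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config a [run_config()]
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_stage <- function(fmt, ...)
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))

#' Run the analysis pipeline end-to-end
#'
#' Executes filter, quantify, compare, conserve, (optionally) motif,
#' integrate and enrich stages in dependency order and returns a
#' `RunReport`. Reruns with the same configuration are deterministic.
#'
#' @param config a validated [run_config()].
#' @return a `RunReport` list: per-condition high-confidence site counts,
#'   the percent-impact dose series, trend statistics, conservation
#'   profile summary, direct-target counts (plus recovery statistics in
#'   synthetic mode), enrichment results when enabled, artifact checksums
#'   and the seed.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stopf("invalid configuration:\n- %s", paste(problems, collapse = "\n- "))
  report <- list(seed = config$seed, stages_run = character(0),
                 stages_failed = character(0), artifacts = list())
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_artifact <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(path)
    report$artifacts[[name]] <<- unname(tools::md5sum(path))
    invisible(path)
  }

  synthetic <- !is.null(config$synthetic)
  if (synthetic) {
    log_stage("generating synthetic truth")
    cfg <- do.call(synthetic_config,
                   c(config$synthetic,
                     if (is.null(config$synthetic$seed))
                       list(seed = config$seed)))
    truth <- generate_truth(cfg, sequences = isTRUE(config$stages$motif))
    conds <- truth_conditions(truth)
    emissions <- lapply(conds, function(cd)
      emit_condition(truth, cd, sequences = isTRUE(config$stages$motif)))
    names(emissions) <- conds
    raw <- lapply(emissions, `[[`, "positive")
    negs <- lapply(emissions, `[[`, "negative")
    genes <- gene_models(truth$genes[c("gene", "chrom", "strand", "tss")])
  } else {
    log_stage("reading peak files")
    # condition order mirrors the dose series: maximum first, minimum last
    raw <- c(list(read_peaks(config$max_peaks, label = "maximum")),
             lapply(seq_along(config$treated_peaks), function(i)
               read_peaks(config$treated_peaks[[i]],
                          label = names(config$treated_peaks)[i] %||%
                            sprintf("treated_%d", i))),
             list(read_peaks(config$min_peaks, label = "minimum")))
    names(raw) <- c("maximum",
                    names(config$treated_peaks) %||%
                      sprintf("treated_%d",
                              seq_along(config$treated_peaks)),
                    "minimum")
    conds <- names(raw)
    negs <- if (!is.null(config$negative_peaks))
      setNames(rep(list(read_peaks(config$negative_peaks,
                                   label = "negative")), length(conds)),
               conds)
    else NULL
    genes <- if (!is.null(config$genes_path))
      read_refflat(config$genes_path) else NULL
    truth <- NULL
  }

  log_stage("filtering high-confidence cistromes")
  hc <- lapply(conds, function(cd)
    filter_high_confidence(raw[[cd]], negative = negs[[cd]],
                           thresholds = config$thresholds))
  names(hc) <- conds
  report$site_counts <- vapply(hc, nrow, integer(1))
  report$stages_run <- c(report$stages_run, "filter")
  for (cd in conds)
    save_artifact(sprintf("peaks_%s.bed", cd),
                  function(p) write_peaks(hc[[cd]], p))

  max_cond <- conds[1]; min_cond <- conds[length(conds)]
  doses <- setdiff(conds, c(max_cond, min_cond))
  log_stage("computing percent-impact dose series")
  impact <- do.call(rbind, lapply(doses, function(cd) {
    pi <- percent_impact(hc[[max_cond]], hc[[min_cond]], hc[[cd]])
    data.frame(condition = cd, n_sites = nrow(hc[[cd]]),
               differential_sites = pi$differential_sites,
               lost = pi$lost_in_treated,
               percent_impact = pi$percent_impact,
               planted_impact = if (synthetic)
                 truth_impact(truth, cd) else NA_real_)
  }))
  report$impact <- impact
  report$stages_run <- c(report$stages_run, "impact")
  save_artifact("impact.tsv", function(p)
    write.table(impact, p, sep = "\t", quote = FALSE, row.names = FALSE))

  top_dose <- if (length(doses)) doses[length(doses)] else min_cond
  if (isTRUE(config$stages$signal) && synthetic) {
    log_stage("quantifying signal fold changes (%s vs %s)",
              top_dose, max_cond)
    sorted <- sort_by_strength(hc[[max_cond]])
    fc <- site_fold_changes(emissions[[top_dose]]$track,
                            emissions[[max_cond]]$track, sorted)
    window <- min(100L, nrow(sorted))
    tr <- dose_trend(fc$value, window = window)
    sp <- stats::cor.test(seq_len(nrow(fc)), abs(fc$value),
                          method = "spearman", exact = FALSE)
    report$trend <- list(window = window, slope = tr$slope,
                         spearman_rho = unname(sp$estimate),
                         spearman_p = sp$p.value)
    report$stages_run <- c(report$stages_run, "signal")
    save_artifact(sprintf("track_%s.bedgraph", top_dose), function(p)
      write_bedgraph(emissions[[top_dose]]$track, p))
  }

  if (isTRUE(config$stages$conservation) && synthetic) {
    log_stage("conservation profile around %s summits", max_cond)
    prof <- mean_profile(hc[[max_cond]], emissions[[max_cond]]$conserved)
    report$conservation <- list(
      at_summit = prof$mean_score[prof$offset == 0],
      at_5kb = mean(prof$mean_score[abs(prof$offset) == 5000]))
    report$stages_run <- c(report$stages_run, "conservation")
    save_artifact("conservation_profile.tsv", function(p)
      write_profile(prof, p))
  }

  if (isTRUE(config$stages$motif) && synthetic) {
    log_stage("motif scan and spacing")
    seqs <- emissions[[max_cond]]$sequences
    hits_are <- scan_pwm(seqs, truth$config$are_pwm)
    hits_par <- scan_pwm(seqs, truth$config$partner_pwm)
    spacing <- pair_spacing(hits_are, hits_par,
                            truth$config$are_pwm$width,
                            truth$config$partner_pwm$width)
    report$motif <- list(n_sites_with_element =
                           length(unique(hits_are$seq_id)),
                         spacing_mode = spacing$mode)
    report$stages_run <- c(report$stages_run, "motif")
  }

  de <- NULL
  if (isTRUE(config$stages$expression)) {
    if (synthetic) de <- emit_expression(truth, top_dose)
    else if (!is.null(config$de_path)) de <- read_de_table(config$de_path)
  }
  if (!is.null(de) && !is.null(genes)) {
    log_stage("classifying direct targets at %s", top_dose)
    pi_top <- percent_impact(hc[[max_cond]], hc[[min_cond]],
                             hc[[top_dose]])
    diffs <- hc[[max_cond]][hc[[max_cond]]$id %in% pi_top$differential_ids, ,
                            drop = FALSE]
    in_tr <- diffs$id %in% overlap_sets(
      cistrome_set(as.data.frame(diffs)), hc[[top_dose]])$pairs$a_id
    impacted <- cistrome_set(as.data.frame(diffs)[!in_tr, , drop = FALSE],
                             label = "impacted")
    gmap <- map_to_tss(impacted, genes, max_dist = config$tss_max_dist)
    sig <- de_significant(de, fdr = config$fdr, fc_cut = config$fc_cut)
    targets <- classify_direct_targets(gmap, sig$up, sig$down)
    report$targets <- list(
      n_activation = sum(targets$mode == "activation"),
      n_repression = sum(targets$mode == "repression"))
    if (synthetic) {
      resp <- attr(de, "responders")
      g <- truth$genes
      truth_mode <- setNames(g$mode, g$gene)
      truth_tg <- resp
      called <- targets$gene
      correct <- called[called %in% truth_tg &
                          truth_mode[called] == targets$mode]
      report$targets$sensitivity <-
        if (length(truth_tg)) length(correct) / length(truth_tg) else NA
      report$targets$precision <-
        if (length(called)) length(correct) / length(called) else NA
    }
    report$stages_run <- c(report$stages_run, "targets")
    save_artifact("direct_targets.tsv", function(p)
      write.table(targets, p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    if (isTRUE(config$stages$enrichment) &&
        !is.null(config$signatures_path)) {
      log_stage("signature enrichment")
      sigs <- read_gmt(config$signatures_path)
      universe <- unique(de$gene)
      enr <- signature_enrichment(
        intersect(targets$gene, universe), universe, sigs)
      report$enrichment <- enr
      report$stages_run <- c(report$stages_run, "enrichment")
      save_artifact("enrichment.tsv", function(p)
        write.table(enr, p, sep = "\t", quote = FALSE, row.names = FALSE))
    }
  }

  save_artifact("report.json", function(p)
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  structure(report, class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport\n  stages:", paste(x$stages_run, collapse = ", "), "\n")
  cat("  high-confidence sites:\n")
  print(x$site_counts)
  if (!is.null(x$impact)) {
    cat("  percent impact by dose:\n")
    print(x$impact[c("condition", "n_sites", "percent_impact")])
  }
  if (!is.null(x$targets))
    cat(sprintf("  direct targets: %d activation, %d repression\n",
                x$targets$n_activation, x$targets$n_repression))
  invisible(x)
}
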