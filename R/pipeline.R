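## End-to-end orchestration: simulate (or load) inputs, then run
## DMR calling -> meQTL classification -> stability -> chromatin
## segmentation and transitions -> enrichment -> enhancer classification ->
## expression link, writing standard-format outputs and a manifest.

#' Pipeline run configuration
#'
#' Collects every tunable threshold with its default: DMR delta 0.1 and
#' pSAM 0.1; meQTL window 5 kb at 10% FDR; stability bound 0.05; 1000
#' shuffles; 16 HMM states with up to 400 Baum-Welch iterations;
#' correlation alpha 0.05; differential-expression FDR 0.10.
#'
#' @param delta,psam DMR retention thresholds.
#' @param meqtl_window,meqtl_fdr meQTL association window (bp) and target
#'   FDR.
#' @param stability_bound quantitative stability bound.
#' @param shuffles enrichment randomizations.
#' @param hmm_states,hmm_max_iter chromatin model size and iteration cap.
#' @param alpha Spearman significance cutoff.
#' @param de_fdr BH threshold for differential expression.
#' @param sam_perm SAM label permutations.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param sim [sim_config()] used when no dataset is supplied.
#' @return list of class `run_config`.
#' @export
run_config <- function(delta = 0.1, psam = 0.1, meqtl_window = 5000,
                       meqtl_fdr = 0.10, stability_bound = 0.05,
                       shuffles = 1000L, hmm_states = 16L,
                       hmm_max_iter = 400L, alpha = 0.05, de_fdr = 0.10,
                       sam_perm = 100L, seed = 1L,
                       sim = sim_config(seed = seed)) {
  stopifnot(delta >= 0, delta <= 1, psam > 0, psam <= 1,
            meqtl_window > 0, meqtl_fdr > 0, meqtl_fdr < 1,
            stability_bound >= 0, shuffles >= 1, hmm_states >= 2,
            alpha > 0, alpha < 1, de_fdr > 0, de_fdr < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config run_config.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$genome <- as.list(cfg$sim$genome)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  simargs <- cfg$sim
  simargs$genome <- unlist(simargs$genome)
  simargs$baseline_meth_profile <- lapply(simargs$baseline_meth_profile,
                                          unlist)
  cfg$sim <- do.call(sim_config, simargs)
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order on a simulated (default) or supplied
#' dataset; each stage reseeds deterministically from the global seed, so
#' two runs with the same seed produce identical outputs. Outputs are
#' written under `outdir` in standard formats together with a
#' `manifest.json` recording parameters, per-stage summaries and output
#' checksums.
#'
#' @param config [run_config()].
#' @param sim optional `sim_data`; by default simulated from
#'   `config$sim`.
#' @param outdir output directory, or `NULL` to skip writing.
#' @return list of class `pipeline_run` with per-stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), sim = NULL,
                         outdir = NULL) {
  if (is.null(sim)) sim <- simulate_dataset(config$sim)
  res <- list(config = config)
  ms0 <- sim$methylomes[[1L]]

  set.seed(derive_seed(config$seed, 11L))
  calls <- call_dmrs(ms0, delta_cutoff = config$delta,
                     p_cutoff = config$psam, n_perm = config$sam_perm)
  res$dmr <- calls

  set.seed(derive_seed(config$seed, 12L))
  res$meqtl <- tryCatch(
    classify_dmrs(calls$dmrs, ms0, sim$genotypes,
                  fdr = config$meqtl_fdr,
                  window_bp = config$meqtl_window),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "stage_error"))
  dmrs <- calls$dmrs
  if (!inherits(res$meqtl, "stage_error"))
    dmrs$dmr_class <- res$meqtl$table$dmr_class

  later <- sim$methylomes[-1L]
  if (length(later)) {
    res$stability <- assess_stability(dmrs, later,
                                      bound = config$stability_bound)
    res$stability_summary <- stability_summary(
      res$stability,
      if (!is.null(dmrs$dmr_class))
        stats::setNames(dmrs$dmr_class, dmrs$dmr_id))
  }

  set.seed(derive_seed(config$seed, 13L))
  chrom <- sim$chromatin
  hmm <- train_hmm(chrom$tracks, chrom$bins,
                   n_states = config$hmm_states,
                   max_iter = config$hmm_max_iter)
  seg <- vapply(chrom$tracks, function(tr)
    segment_track(hmm, tr, chrom$bins), integer(nrow(chrom$bins)))
  cons_smk <- merge_group(seg[, chrom$groups$smoking, drop = FALSE])
  cons_ns <- merge_group(seg[, chrom$groups$non_smoking, drop = FALSE])
  masks <- list()
  if (!is.null(dmrs$dmr_class)) {
    masks$ngDMR <- dmrs[dmrs$dmr_class == "ngDMR", , drop = FALSE]
    masks$gDMR <- dmrs[dmrs$dmr_class == "gDMR", , drop = FALSE]
  }
  res$chromatin <- list(
    hmm = hmm, segmentation = seg,
    consensus = list(smoking = cons_smk, non_smoking = cons_ns),
    transitions = chromatin_transitions(cons_ns, cons_smk, chrom$bins,
                                        masks))
  elements <- segmentation_elements(chrom$bins, cons_ns)
  elements <- classify_elements(elements, sim$genes)
  res$elements <- elements

  set.seed(derive_seed(config$seed, 14L))
  roi_list <- split(elements[, c("chrom", "start", "end")],
                    elements$category)
  roi_list <- roi_list[vapply(roi_list, nrow, 1L) > 0]
  res$enrichment <- if (nrow(dmrs))
    enrichment_by_class(dmrs, roi_list, config$sim$genome,
                        n_shuffles = config$shuffles)

  enh <- elements[elements$category == "enhancer", , drop = FALSE]
  res$enhancers <- classify_enhancers(enh, sim$genes, sim$interactions,
                                      dmrs)

  set.seed(derive_seed(config$seed, 15L))
  targets <- assign_targets(dmrs, elements, sim$genes, sim$interactions)
  res$targets <- targets
  res$correlation <- tryCatch(
    correlate_meth_expr(targets, dmrs, ms0, sim$expression,
                        alpha = config$alpha),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "stage_error"))
  res$de <- differential_expression(
    sim$expression, exposure_groups(ms0$samples), fdr = config$de_fdr)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_dmrs(dmrs, file.path(outdir, "dmrs.bed"))
    if (!inherits(res$meqtl, "stage_error"))
      utils::write.table(res$meqtl$table,
                         file.path(outdir, "classified.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$stability))
      utils::write.table(res$stability,
                         file.path(outdir, "stability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(cbind(chrom$bins,
                    data.frame(state_ns = cons_ns, state_smk = cons_smk)),
              file.path(outdir, "consensus_states.bed"))
    if (!is.null(res$enrichment))
      utils::write.table(res$enrichment,
                         file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$enhancers, file.path(outdir, "enhancers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!inherits(res$correlation, "stage_error"))
      utils::write.table(res$correlation$records,
                         file.path(outdir, "correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$de, file.path(outdir, "diffexpr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(outdir, full.names = TRUE)
    files <- files[!grepl("manifest", files)]
    manifest <- list(
      seed = config$seed,
      parameters = list(delta = config$delta, psam = config$psam,
                        meqtl_window = config$meqtl_window,
                        meqtl_fdr = config$meqtl_fdr,
                        stability_bound = config$stability_bound,
                        shuffles = config$shuffles,
                        hmm_states = config$hmm_states,
                        hmm_max_iter = config$hmm_max_iter,
                        alpha = config$alpha, de_fdr = config$de_fdr),
      summary = pipeline_summary(res),
      outputs = as.list(stats::setNames(tools::md5sum(files),
                                        basename(files))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }
  class(res) <- "pipeline_run"
  res
}

#' Headline summary of a pipeline run
#' @param res pipeline_run (or the internal result list).
#' @return list of headline numbers (DMR counts by class, stability
#'   fractions, transition fractions, enrichment folds, correlation
#'   proportions).
#' @export
pipeline_summary <- function(res) {
  out <- list(n_dmrs = nrow(res$dmr$dmrs))
  if (!inherits(res$meqtl, "stage_error") && !is.null(res$meqtl))
    out$n_gdmr <- res$meqtl$n_gdmr
  if (!is.null(res$stability_summary))
    out$stability <- res$stability_summary
  if (!is.null(res$chromatin))
    out$transition_fractions <-
      as.list(res$chromatin$transitions$fractions)
  if (!is.null(res$enrichment))
    out$enrichment_folds <- stats::setNames(
      as.list(res$enrichment$fold_change), res$enrichment$roi_class)
  if (!inherits(res$correlation, "stage_error") &&
      !is.null(res$correlation))
    out$correlation <- res$correlation$summary
  out
}

#' @method print pipeline_run
#' @export
print.pipeline_run <- function(x, ...) {
  s <- pipeline_summary(x)
  cat("Pipeline run:", s$n_dmrs, "DMRs")
  if (!is.null(s$n_gdmr)) cat(" (", s$n_gdmr, "gDMR )")
  cat("\n")
  if (!is.null(s$transition_fractions)) {
    fr <- unlist(s$transition_fractions)
    cat("  chromatin transitions:",
        paste(names(fr), round(100 * fr, 1), sep = "=", collapse = ", "),
        "%\n")
  }
  invisible(x)
}
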