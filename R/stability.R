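## Longitudinal stability of DMRs: re-evaluate the group methylation
## difference of regions called at birth in later-timepoint methylomes.
## Qualitative stability keeps the direction; quantitative stability
## additionally bounds the shrinkage of |delta| at 5 percentage points
## (increases never break stability).

#' Assess longitudinal stability of DMRs
#'
#' For each DMR called at the reference timepoint, the smoking minus
#' non-smoking difference of per-sample regional mean raw methylation is
#' recomputed in each later methylome. A DMR is qualitatively stable at a
#' timepoint when the sign of the difference is unchanged, and
#' quantitatively stable when additionally the decrease in `|delta|`
#' relative to the reference does not exceed `bound` (absolute percentage
#' points on the methylation scale).
#'
#' @param dmrs DMR data.frame from the reference timepoint (needs
#'   `dmr_id`, `chrom`, `start`, `end`, `delta_raw`).
#' @param ms_later named list of later-timepoint MethylomeSets (names used
#'   as timepoint labels); groups from each set's own metadata.
#' @param bound maximum tolerated decrease in `|delta|` (default 0.05).
#' @param reference_deltas optional deltas at the reference timepoint
#'   (default `dmrs$delta_raw`).
#' @return data.frame of class `stability_calls`: one row per DMR and later
#'   timepoint with delta_t0, delta_t, qualitative_stable,
#'   quantitative_stable (`NA` where the region has no covered CpGs).
#' @export
assess_stability <- function(dmrs, ms_later, bound = 0.05,
                             reference_deltas = dmrs$delta_raw) {
  stopifnot(length(names(ms_later)) == length(ms_later))
  empty <- data.frame(dmr_id = character(), timepoint = character(),
                      delta_t0 = numeric(), delta_t = numeric(),
                      qualitative_stable = logical(),
                      quantitative_stable = logical())
  if (!nrow(dmrs)) {
    class(empty) <- c("stability_calls", "data.frame")
    return(empty)
  }
  out <- list()
  for (tp in names(ms_later)) {
    ms <- ms_later[[tp]]
    grp <- exposure_groups(ms$samples)
    for (i in seq_len(nrow(dmrs))) {
      m <- region_mean_meth(ms, dmrs$chrom[i], dmrs$start[i], dmrs$end[i])
      d0 <- reference_deltas[i]
      if (all(is.na(m))) {
        out[[length(out) + 1L]] <-
          data.frame(dmr_id = dmrs$dmr_id[i], timepoint = tp,
                     delta_t0 = d0, delta_t = NA_real_,
                     qualitative_stable = NA, quantitative_stable = NA)
        next
      }
      dt <- mean(m[grp$smoking], na.rm = TRUE) -
        mean(m[grp$non_smoking], na.rm = TRUE)
      qual <- sign(dt) == sign(d0)
      quant <- qual && (abs(d0) - abs(dt)) <= bound
      out[[length(out) + 1L]] <-
        data.frame(dmr_id = dmrs$dmr_id[i], timepoint = tp,
                   delta_t0 = d0, delta_t = dt,
                   qualitative_stable = qual, quantitative_stable = quant)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("stability_calls", "data.frame")
  out
}

#' Summarise stability fractions, optionally by DMR class
#'
#' @param calls [assess_stability()] output.
#' @param classes optional named vector mapping dmr_id to gDMR/ngDMR.
#' @return data.frame of fractions qualitatively / quantitatively stable
#'   per timepoint (and class).
#' @export
stability_summary <- function(calls, classes = NULL) {
  calls <- calls[!is.na(calls$qualitative_stable), , drop = FALSE]
  grpv <- if (is.null(classes)) rep("all", nrow(calls))
  else unname(classes[calls$dmr_id])
  agg <- function(sub) data.frame(
    n = nrow(sub),
    frac_qualitative = mean(sub$qualitative_stable),
    frac_quantitative = mean(sub$quantitative_stable))
  sp <- split(calls, list(calls$timepoint, grpv), drop = TRUE)
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cbind(data.frame(timepoint = parts[1],
                     dmr_class = paste(parts[-1], collapse = ".")),
          agg(sp[[nm]]))
  }))
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of samples on CpG methylation in regions
#'
#' CpGs inside the given regions with coverage at least `min_cov` in every
#' sample form the feature matrix; samples are clustered on the Euclidean
#' distance of raw methylation (average linkage). For individuals measured
#' at several timepoints the summary reports whether each individual's
#' samples are mutual nearest neighbours, i.e. whether the tree clusters by
#' individual rather than by year.
#'
#' @param ms MethylomeSet spanning all samples and timepoints (metadata
#'   needs `individual_id`).
#' @param regions interval data.frame (e.g. the ngDMR set).
#' @param min_cov minimum coverage in all samples (default 10).
#' @return list of class `sample_clustering`: `hclust` tree, `n_cpgs`,
#'   `pairing` (per individual: mutual nearest-neighbour flag).
#' @export
cluster_samples <- function(ms, regions, min_cov = 10L) {
  cov <- coverage_matrix(ms)
  inreg <- rep(FALSE, nrow(ms$sites))
  for (i in seq_len(nrow(regions))) {
    inreg <- inreg | (ms$sites$chrom == regions$chrom[i] &
                        ms$sites$pos >= regions$start[i] &
                        ms$sites$pos < regions$end[i])
  }
  keep <- inreg & apply(cov >= min_cov, 1, all)
  if (!any(keep)) stop("no CpGs pass the coverage filter")
  r <- raw_meth(subset_methylome(ms, sites = which(keep)))
  d <- stats::dist(t(r))
  hc <- stats::hclust(d, method = "average")
  dm <- as.matrix(d)
  diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)
  ind <- ms$samples$individual_id
  pairing <- vapply(unique(ind), function(id) {
    ii <- which(ind == id)
    if (length(ii) < 2L) return(NA)
    all(vapply(ii, function(i) ind[nn[i]] == id, TRUE))
  }, TRUE)
  structure(list(hclust = hc, n_cpgs = sum(keep),
                 pairing = data.frame(individual_id = unique(ind),
                                      timepoints_pair_first =
                                        unname(pairing))),
            class = "sample_clustering")
}

#' @method print sample_clustering
#' @export
print.sample_clustering <- function(x, ...) {
  ok <- x$pairing$timepoints_pair_first
  cat("Sample clustering on", x$n_cpgs, "CpGs;",
      sum(ok, na.rm = TRUE), "/", sum(!is.na(ok)),
      "individuals cluster by sample across timepoints\n")
  invisible(x)
}
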