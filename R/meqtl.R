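## meQTL classification: correlate SNP dosages within +/- 5 kb of each DMR
## with the DMR's per-sample mean raw methylation; calibrate an |r|
## threshold at a target permutation FDR and split DMRs into
## genotype-influenced (gDMR) and non-genetically-influenced (ngDMR).

#' Associate DMRs with nearby SNPs
#'
#' For each DMR, every SNP within `window_bp` of the region is correlated
#' (Pearson by default, pairwise-complete on non-missing dosages) with the
#' DMR's per-sample mean raw methylation; the SNP with maximal `|r|` is the
#' best association. SNPs with constant dosage or fewer than `min_samples`
#' complete pairs are skipped.
#'
#' @param dmrs DMR data.frame (needs `dmr_id`, `chrom`, `start`, `end`).
#' @param ms MethylomeSet (same samples as the dosage columns, in order).
#' @param gt GenotypeTable.
#' @param window_bp association window around the DMR (default 5000).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_samples minimum complete pairs per SNP (default 3).
#' @return data.frame: dmr_id, snp_id, distance_bp, r, is_cpg_destroying,
#'   best (logical, maximal |r| per DMR); DMRs with no in-window SNP are
#'   absent.
#' @export
associate_snps <- function(dmrs, ms, gt, window_bp = 5000,
                           method = c("pearson", "spearman"),
                           min_samples = 3L) {
  method <- match.arg(method)
  if (!nrow(dmrs))
    return(data.frame(dmr_id = character(), snp_id = character(),
                      distance_bp = integer(), r = numeric(),
                      is_cpg_destroying = logical(), best = logical()))
  meth <- t(vapply(seq_len(nrow(dmrs)), function(i)
    region_mean_meth(ms, dmrs$chrom[i], dmrs$start[i], dmrs$end[i]),
    numeric(nrow(ms$samples))))
  out <- list()
  for (i in seq_len(nrow(dmrs))) {
    insnp <- which(gt$snps$chrom == dmrs$chrom[i] &
                     gt$snps$pos >= dmrs$start[i] - window_bp &
                     gt$snps$pos < dmrs$end[i] + window_bp)
    if (!length(insnp)) next
    for (j in insnp) {
      dos <- gt$dosage[j, ]
      ok <- !is.na(dos) & !is.na(meth[i, ])
      if (sum(ok) < min_samples) next
      if (length(unique(dos[ok])) < 2L || stats::sd(meth[i, ok]) == 0)
        next
      r <- stats::cor(dos[ok], meth[i, ok], method = method)
      dist_bp <- if (gt$snps$pos[j] >= dmrs$start[i] &&
                     gt$snps$pos[j] < dmrs$end[i]) 0L
      else min(abs(gt$snps$pos[j] - dmrs$start[i]),
               abs(gt$snps$pos[j] - (dmrs$end[i] - 1L)))
      out[[length(out) + 1L]] <-
        data.frame(dmr_id = dmrs$dmr_id[i], snp_id = gt$snps$snp_id[j],
                   distance_bp = dist_bp, r = r,
                   is_cpg_destroying = isTRUE(gt$snps$cpg_destroying[j]))
    }
  }
  if (!length(out))
    return(data.frame(dmr_id = character(), snp_id = character(),
                      distance_bp = integer(), r = numeric(),
                      is_cpg_destroying = logical(), best = logical()))
  out <- do.call(rbind, out)
  out$best <- FALSE
  for (id in unique(out$dmr_id)) {
    ii <- which(out$dmr_id == id)
    out$best[ii[which.max(abs(out$r[ii]))]] <- TRUE
  }
  out
}

## null distribution of per-DMR best |r|: permute sample assignment of the
## dosage matrix, recompute the max-|r| envelope per DMR
meqtl_null_best_r <- function(dmrs, ms, gt, window_bp, method,
                              min_samples, n_perm) {
  nulls <- matrix(NA_real_, nrow(dmrs), n_perm)
  gt2 <- gt
  ns <- ncol(gt$dosage)
  for (k in seq_len(n_perm)) {
    gt2$dosage <- gt$dosage[, sample(ns), drop = FALSE]
    a <- associate_snps(dmrs, ms, gt2, window_bp, method, min_samples)
    if (nrow(a)) {
      b <- a[a$best, ]
      nulls[match(b$dmr_id, dmrs$dmr_id), k] <- abs(b$r)
    }
  }
  nulls
}

#' Classify DMRs as gDMR or ngDMR at a target FDR
#'
#' The `|r|` threshold is calibrated from a permutation null: dosage
#' vectors are permuted across samples `n_perm` times, the per-DMR
#' max-`|r|` recomputed each time, and the threshold set to the
#' `(1 - fdr)` quantile of the pooled null values, so that an uncorrelated
#' genotype produces a false gDMR call at rate `fdr` among DMRs carrying
#' an in-window SNP. A DMR is gDMR iff its best association exceeds the
#' threshold; DMRs without any in-window SNP are ngDMR.
#'
#' @param dmrs DMR data.frame (>= 20 rows for a stable calibration).
#' @param ms MethylomeSet.
#' @param gt GenotypeTable.
#' @param fdr target FDR for gDMR calls (default 0.10).
#' @param window_bp,method,min_samples as in [associate_snps()].
#' @param n_perm dosage permutations for the null (default 200).
#' @param r_threshold optional fixed threshold overriding the calibration.
#' @param associations optional precomputed [associate_snps()] result.
#' @return list of class `dmr_classification`: `table` (dmr_id, best_snp,
#'   best_r, is_cpg_destroying, dmr_class), `r_threshold`, `fdr_target`,
#'   `n_gdmr`, `n_total`.
#' @export
classify_dmrs <- function(dmrs, ms, gt, fdr = 0.10, window_bp = 5000,
                          method = "pearson", min_samples = 3L,
                          n_perm = 200L, r_threshold = NULL,
                          associations = NULL) {
  if (is.null(r_threshold) && nrow(dmrs) < 20L)
    stop("fewer than 20 DMRs: threshold calibration unstable")
  if (is.null(associations))
    associations <- associate_snps(dmrs, ms, gt, window_bp, method,
                                   min_samples)
  best <- associations[associations$best, , drop = FALSE]
  best_r <- rep(NA_real_, nrow(dmrs))
  best_r[match(best$dmr_id, dmrs$dmr_id)] <- abs(best$r)
  if (is.null(r_threshold)) {
    ## the (1 - fdr) quantile of the permutation null of the per-DMR best
    ## |r|: among DMRs with an in-window SNP, a null (uncorrelated)
    ## genotype exceeds the threshold with probability fdr, so the false
    ## gDMR call rate is held at the target
    nulls <- meqtl_null_best_r(dmrs, ms, gt, window_bp, method,
                               min_samples, n_perm)
    nv <- nulls[is.finite(nulls)]
    if (!length(nv)) stop("no DMR has an in-window SNP")
    r_threshold <- stats::quantile(nv, 1 - fdr, names = FALSE)
  }
  cls <- ifelse(!is.na(best_r) & best_r > r_threshold, "gDMR", "ngDMR")
  tab <- data.frame(dmr_id = dmrs$dmr_id,
                    best_snp = NA_character_,
                    best_r = best_r,
                    is_cpg_destroying = FALSE,
                    dmr_class = cls,
                    stringsAsFactors = FALSE)
  if (nrow(best)) {
    mi <- match(best$dmr_id, tab$dmr_id)
    tab$best_snp[mi] <- best$snp_id
    tab$best_r[mi] <- best$r
  }
  tab$is_cpg_destroying <- flag_cpg_destroying(dmrs, gt, window_bp)
  structure(list(table = tab, r_threshold = r_threshold,
                 fdr_target = fdr, n_gdmr = sum(cls == "gDMR"),
                 n_total = nrow(dmrs)),
            class = "dmr_classification")
}

#' @method print dmr_classification
#' @export
print.dmr_classification <- function(x, ...) {
  cat("DMR classification: ", x$n_gdmr, "/", x$n_total,
      " gDMR (|r| > ", format(x$r_threshold),
      ", target FDR ", x$fdr_target, ")\n", sep = "")
  invisible(x)
}

#' Flag DMRs with an in-window CpG-destroying SNP
#'
#' @param dmrs DMR data.frame.
#' @param gt GenotypeTable.
#' @param window_bp association window (default 5000).
#' @return logical vector along DMR rows.
#' @export
flag_cpg_destroying <- function(dmrs, gt, window_bp = 5000) {
  cg <- which(gt$snps$cpg_destroying %in% TRUE)
  vapply(seq_len(nrow(dmrs)), function(i) {
    any(gt$snps$chrom[cg] == dmrs$chrom[i] &
          gt$snps$pos[cg] >= dmrs$start[i] - window_bp &
          gt$snps$pos[cg] < dmrs$end[i] + window_bp)
  }, TRUE)
}
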