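## DMR calling: per-site group statistics on smoothed methylation, candidate
## segmentation, SAM-style moderated testing with permutation p-values,
## delta filtering and a permutation FDR scan across delta thresholds.

row_group_stats <- function(x, idx) {
  n <- length(idx)
  m <- rowMeans(x[, idx, drop = FALSE])
  v <- rowSums((x[, idx, drop = FALSE] - m)^2) / (n - 1L)
  list(mean = m, var = v, n = n)
}

#' Per-site group-difference statistic on smoothed methylation
#'
#' Signal-to-noise statistic (smoking minus non-smoking) per CpG with the
#' pooled SD floored at its 75th percentile across sites, which stabilises
#' the statistic where the smoothed values are locally near-constant.
#'
#' @param smoothed sites x samples smoothed methylation matrix.
#' @param groups list with integer indices `smoking` and `non_smoking`.
#' @param sd_floor_quantile quantile of the pooled SD used as floor.
#' @return numeric vector of per-site statistics.
#' @export
site_stat <- function(smoothed, groups, sd_floor_quantile = 0.75) {
  g1 <- row_group_stats(smoothed, groups$smoking)
  g2 <- row_group_stats(smoothed, groups$non_smoking)
  sd_pool <- sqrt(((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) /
                    (g1$n + g2$n - 2))
  fl <- stats::quantile(sd_pool[is.finite(sd_pool)], sd_floor_quantile,
                        names = FALSE)
  sd_pool <- pmax(sd_pool, fl)
  (g1$mean - g2$mean) / (sd_pool * sqrt(1 / g1$n + 1 / g2$n))
}

#' Call candidate DMRs from smoothed methylation
#'
#' Consecutive CpGs (within `maxGap` of each other) whose per-site statistic
#' exceeds the `cutoff_quantile` quantile of its absolute values, all with
#' the same sign, are merged into candidate regions; candidates with fewer
#' than `min_cpgs` sites are dropped.
#'
#' @param ms MethylomeSet.
#' @param smoothed matrix from [smooth_methylome()].
#' @param groups list with indices `smoking`, `non_smoking` (each >= 2).
#' @param cutoff_quantile quantile of the absolute per-site statistic used
#'   as candidate threshold (default 0.975).
#' @param min_cpgs minimum CpGs per candidate.
#' @param maxGap maximum within-candidate CpG gap in bp.
#' @return data.frame of candidates with site index ranges and region-level
#'   deltas (raw and smoothed, smoking minus non-smoking).
#' @export
candidate_dmrs <- function(ms, smoothed, groups, cutoff_quantile = 0.975,
                           min_cpgs = 3L, maxGap = 2000) {
  if (length(groups$smoking) < 2L || length(groups$non_smoking) < 2L)
    stop("each group needs >= 2 samples")
  stat <- site_stat(smoothed, groups)
  cut <- stats::quantile(abs(stat[is.finite(stat)]), cutoff_quantile,
                         names = FALSE)
  above <- is.finite(stat) & abs(stat) > cut
  sgn <- sign(stat)
  ## break runs at chromosome changes, large gaps, sign changes
  chrom <- ms$sites$chrom
  pos <- ms$sites$pos
  nb <- length(stat)
  newrun <- c(TRUE, chrom[-1] != chrom[-nb] |
                diff(pos) > maxGap |
                sgn[-1] != sgn[-nb] |
                !above[-1] | !above[-nb])
  runid <- cumsum(newrun)
  keep <- above
  cand <- list()
  for (r in unique(runid[keep])) {
    ii <- which(runid == r & keep)
    if (length(ii) < min_cpgs) next
    cand[[length(cand) + 1L]] <-
      data.frame(chrom = chrom[ii[1]], start = pos[ii[1]],
                 end = pos[ii[length(ii)]] + 2L,
                 n_cpgs = length(ii),
                 idx_start = ii[1], idx_end = ii[length(ii)],
                 stat_mean = mean(stat[ii]))
  }
  if (!length(cand))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      idx_start = integer(), idx_end = integer(),
                      stat_mean = numeric(), delta_raw = numeric(),
                      delta_smooth = numeric()))
  cand <- do.call(rbind, cand)
  sm <- candidate_sample_means(ms, cand)
  smo <- candidate_smooth_means(smoothed, cand)
  cand$delta_raw <- rowMeans(sm[, groups$smoking, drop = FALSE],
                             na.rm = TRUE) -
    rowMeans(sm[, groups$non_smoking, drop = FALSE], na.rm = TRUE)
  cand$delta_smooth <- rowMeans(smo[, groups$smoking, drop = FALSE]) -
    rowMeans(smo[, groups$non_smoking, drop = FALSE])
  rownames(cand) <- NULL
  cand
}

#' Per-candidate per-sample mean raw methylation
#' @param ms MethylomeSet.
#' @param cand candidate data.frame with `idx_start`, `idx_end`.
#' @return candidates x samples matrix.
#' @export
candidate_sample_means <- function(ms, cand) {
  r <- raw_meth(ms)
  t(vapply(seq_len(nrow(cand)), function(i) {
    colMeans(r[cand$idx_start[i]:cand$idx_end[i], , drop = FALSE],
             na.rm = TRUE)
  }, numeric(ncol(r))))
}

candidate_smooth_means <- function(smoothed, cand) {
  t(vapply(seq_len(nrow(cand)), function(i) {
    colMeans(smoothed[cand$idx_start[i]:cand$idx_end[i], , drop = FALSE],
             na.rm = TRUE)
  }, numeric(ncol(smoothed))))
}

sam_d <- function(means, i1, i2, s0) {
  g1 <- row_group_stats(means, i1)
  g2 <- row_group_stats(means, i2)
  s <- sqrt(((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) /
              (g1$n + g2$n - 2)) * sqrt(1 / g1$n + 1 / g2$n)
  num <- g1$mean - g2$mean
  d <- num / (s + s0)
  d[num == 0 & s + s0 == 0] <- 0  # identical groups: a zero effect, not 0/0
  list(d = d, s = s)
}

#' SAM-style moderated test over candidate regions
#'
#' Statistic `d = (mean_smoking - mean_non_smoking) / (s + s0)` on
#' per-candidate per-sample mean raw methylation, with `s` the two-sample
#' pooled standard error and fudge factor `s0` the median of the
#' per-candidate `s` values. P-values come from group-label permutations
#' pooled over the full candidate set (`+1` corrected); with
#' `exact = TRUE` all distinct label assignments are enumerated.
#'
#' @param ms MethylomeSet.
#' @param cand candidate data.frame (from [candidate_dmrs()]).
#' @param groups list with indices `smoking`, `non_smoking`.
#' @param n_perm number of label permutations (>= 20).
#' @param exact enumerate all label assignments instead of sampling.
#' @param s0 optional fudge-factor override (default: median of the
#'   per-candidate standard errors; `s0 = 0` reduces `d` to the ordinary
#'   two-sample t numerator over its standard error).
#' @return list with `d`, `s0` and `p_sam` per candidate.
#' @export
sam_moderated_test <- function(ms, cand, groups, n_perm = 100L,
                               exact = FALSE, s0 = NULL) {
  if (!exact && n_perm < 20L) stop("n_perm must be >= 20")
  means <- candidate_sample_means(ms, cand)
  sam_test_on_means(means, groups, n_perm, exact, s0)
}

## core on a candidates x samples matrix (reused by the FDR scan)
sam_test_on_means <- function(means, groups, n_perm = 100L,
                              exact = FALSE, s0 = NULL) {
  i1 <- groups$smoking; i2 <- groups$non_smoking
  obs0 <- sam_d(means, i1, i2, 0)
  if (is.null(s0)) s0 <- stats::median(obs0$s)
  d_obs <- sam_d(means, i1, i2, s0)$d
  nall <- ncol(means)
  n1 <- length(i1)
  cols <- c(i1, i2)
  if (exact) {
    sel <- utils::combn(length(cols), n1)
    null <- unlist(lapply(seq_len(ncol(sel)), function(k) {
      j1 <- cols[sel[, k]]
      j2 <- setdiff(cols, j1)
      sam_d(means, j1, j2, s0)$d
    }))
  } else {
    null <- unlist(lapply(seq_len(n_perm), function(k) {
      perm <- sample(cols)
      sam_d(means, perm[seq_len(n1)], perm[-seq_len(n1)], s0)$d
    }))
  }
  null <- abs(null[is.finite(null)])
  p <- vapply(abs(d_obs), function(a) (1 + sum(null >= a)) /
                (1 + length(null)), 1.0)
  list(d = d_obs, s0 = s0, p_sam = p)
}

#' Filter and rank candidates into DMRs
#'
#' Retains candidates with `p_sam < p_cutoff` and absolute mean methylation
#' difference above `delta_cutoff` in both raw and smoothed data, ranked by
#' p-value then absolute delta, ties broken by genomic coordinate.
#'
#' @param cand candidate data.frame with `delta_raw`, `delta_smooth`.
#' @param p_sam per-candidate p-values.
#' @param delta_cutoff methylation-difference threshold (default 0.1).
#' @param p_cutoff p-value threshold (default 0.1).
#' @param d optional per-candidate statistic carried into the output.
#' @return data.frame of DMRs with `dmr_id`, deltas, `p_sam`, `direction`.
#' @export
filter_dmrs <- function(cand, p_sam, delta_cutoff = 0.1, p_cutoff = 0.1,
                        d = NULL) {
  keep <- p_sam < p_cutoff & abs(cand$delta_raw) > delta_cutoff &
    abs(cand$delta_smooth) > delta_cutoff
  out <- cand[keep, , drop = FALSE]
  out$p_sam <- p_sam[keep]
  out$t_group <- if (is.null(d)) out$stat_mean else d[keep]
  out$direction <- ifelse(out$delta_raw > 0, "hyper", "hypo")
  o <- order(out$p_sam, -abs(out$delta_raw), out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out$dmr_id <- sprintf("dmr%04d", seq_len(nrow(out)))
  else out$dmr_id <- character(0)
  out
}

#' Full DMR caller
#'
#' Smooth, segment into candidates, test (SAM moderated statistic with
#' permutation p) and filter. Group labels come from `ms$samples$exposure`.
#'
#' @param ms MethylomeSet.
#' @param params [smooth_params()].
#' @param delta_cutoff,p_cutoff retention thresholds (defaults 0.1 / 0.1).
#' @param cutoff_quantile candidate per-site statistic quantile.
#' @param n_perm SAM permutations.
#' @param smoothed optional precomputed smoothing matrix.
#' @return list of class `dmr_calls` with `dmrs`, `candidates`, `smoothed`,
#'   `groups`, `params`.
#' @export
call_dmrs <- function(ms, params = smooth_params(), delta_cutoff = 0.1,
                      p_cutoff = 0.1, cutoff_quantile = 0.975,
                      n_perm = 100L, smoothed = NULL) {
  if (is.null(smoothed)) smoothed <- smooth_methylome(ms, params)
  groups <- exposure_groups(ms$samples)
  cand <- candidate_dmrs(ms, smoothed, groups,
                         cutoff_quantile = cutoff_quantile,
                         maxGap = params$maxGap)
  if (!nrow(cand)) {
    dmrs <- filter_dmrs(cand, numeric(0), delta_cutoff, p_cutoff)
  } else {
    sam <- sam_moderated_test(ms, cand, groups, n_perm = n_perm)
    dmrs <- filter_dmrs(cand, sam$p_sam, delta_cutoff, p_cutoff, d = sam$d)
  }
  structure(list(dmrs = dmrs, candidates = cand, smoothed = smoothed,
                 groups = groups, params = params),
            class = "dmr_calls")
}

#' @method print dmr_calls
#' @export
print.dmr_calls <- function(x, ...) {
  cat("DMR calls:", nrow(x$dmrs), "DMRs from", nrow(x$candidates),
      "candidates (", sum(x$dmrs$direction == "hyper"), "hyper /",
      sum(x$dmrs$direction == "hypo"), "hypo )\n")
  invisible(x)
}

#' Permutation FDR scan over delta thresholds
#'
#' For each permutation of the group labels the caller
#' (candidates -> SAM -> filter) is re-run and DMRs counted at each delta
#' threshold; smoothing is per-sample and label-invariant so the smoothed
#' matrix is computed once and reused. The FDR at a threshold is the median
#' over permutations of the ratio of permutation DMR count to observed DMR
#' count (`NA` when nothing is observed at that threshold).
#'
#' @param ms MethylomeSet.
#' @param thresholds delta cutoffs to scan.
#' @param n_perm outer label permutations.
#' @param sam_perm inner SAM permutations per run.
#' @param params,p_cutoff,cutoff_quantile as in [call_dmrs()].
#' @param smoothed optional precomputed smoothing matrix.
#' @return data.frame of class `fdr_scan`: threshold, n_dmrs, median_fdr,
#'   n_permutations.
#' @export
permutation_fdr_scan <- function(ms, thresholds = seq(0.01, 0.25, by = 0.02),
                                 n_perm = 100L, sam_perm = 50L,
                                 params = smooth_params(), p_cutoff = 0.1,
                                 cutoff_quantile = 0.975, smoothed = NULL) {
  if (is.null(smoothed)) smoothed <- smooth_methylome(ms, params)
  groups <- exposure_groups(ms$samples)
  count_at <- function(grp) {
    cand <- candidate_dmrs(ms, smoothed, grp,
                           cutoff_quantile = cutoff_quantile,
                           maxGap = params$maxGap)
    if (!nrow(cand)) return(rep(0L, length(thresholds)))
    sam <- sam_moderated_test(ms, cand, grp, n_perm = sam_perm)
    vapply(thresholds, function(th)
      nrow(filter_dmrs(cand, sam$p_sam, th, p_cutoff)), 1L)
  }
  obs <- count_at(groups)
  all_idx <- c(groups$smoking, groups$non_smoking)
  n1 <- length(groups$smoking)
  perm_counts <- matrix(0L, n_perm, length(thresholds))
  for (k in seq_len(n_perm)) {
    perm <- sample(all_idx)
    perm_counts[k, ] <- count_at(list(smoking = perm[seq_len(n1)],
                                      non_smoking = perm[-seq_len(n1)]))
  }
  fdr <- vapply(seq_along(thresholds), function(j) {
    if (obs[j] == 0L) return(NA_real_)
    stats::median(perm_counts[, j] / obs[j])
  }, 1.0)
  out <- structure(data.frame(threshold = thresholds, n_dmrs = obs,
                              median_fdr = fdr, n_permutations = n_perm),
                   class = c("fdr_scan", "data.frame"))
  attr(out, "perm_counts") <- perm_counts  # permutations x thresholds
  out
}

#' Promoter methylation screen over lineage-marker genes
#'
#' Mean raw promoter methylation per sample for a set of marker promoters
#' reflecting blood cell-type composition, with group means and the
#' smoking minus non-smoking difference per marker. Group differences all
#' below the DMR delta cutoff support that cutoff as a guard against
#' cell-composition artefacts.
#'
#' @param ms MethylomeSet.
#' @param markers interval data.frame of marker promoters with a `name`
#'   column.
#' @param groups group indices (default from sample metadata).
#' @return data.frame per marker: n_cpgs, group means, delta (NA with a
#'   warning for markers without covered CpGs).
#' @export
lineage_marker_screen <- function(ms, markers,
                                  groups = exposure_groups(ms$samples)) {
  res <- lapply(seq_len(nrow(markers)), function(i) {
    sel <- ms$sites$chrom == markers$chrom[i] &
      ms$sites$pos >= markers$start[i] & ms$sites$pos < markers$end[i]
    cov_ok <- sel & rowSums(coverage_matrix(ms)) > 0
    if (!any(cov_ok)) {
      warning("marker ", markers$name[i], " has no covered CpGs")
      return(data.frame(name = markers$name[i], n_cpgs = 0L,
                        mean_smoking = NA_real_,
                        mean_non_smoking = NA_real_, delta = NA_real_))
    }
    m <- region_mean_meth(ms, markers$chrom[i], markers$start[i],
                          markers$end[i])
    data.frame(name = markers$name[i], n_cpgs = sum(cov_ok),
               mean_smoking = mean(m[groups$smoking], na.rm = TRUE),
               mean_non_smoking = mean(m[groups$non_smoking], na.rm = TRUE),
               delta = mean(m[groups$smoking], na.rm = TRUE) -
                 mean(m[groups$non_smoking], na.rm = TRUE))
  })
  do.call(rbind, res)
}

#' Write DMRs as extended BED
#' @param dmrs DMR data.frame.
#' @param path output path.
#' @export
write_dmrs <- function(dmrs, path) {
  d <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                  name = dmrs$dmr_id, score = round(-10 * log10(dmrs$p_sam)),
                  strand = ".", n_cpgs = dmrs$n_cpgs,
                  delta_raw = dmrs$delta_raw,
                  delta_smooth = dmrs$delta_smooth, p_sam = dmrs$p_sam,
                  direction = dmrs$direction)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
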