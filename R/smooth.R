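## BSmooth-style smoothing of bisulfite counts: per sample and chromosome
## segment, a coverage-weighted tricube local quadratic fit on the logit
## scale, evaluated at every CpG.

#' Smoothing parameters
#'
#' Defaults match the calling configuration used throughout: windows of at
#' least `ns = 11` CpGs and total width at least 1 kb (`h = 500` half-width),
#' with smoothing broken wherever consecutive CpGs are more than
#' `maxGap = 2000` bp apart.
#'
#' @param ns minimum number of CpGs per smoothing window (>= 2).
#' @param h minimum window half-width in bp.
#' @param maxGap segment-breaking gap in bp.
#' @return list of class `smooth_params`.
#' @export
smooth_params <- function(ns = 11L, h = 500, maxGap = 2000) {
  if (ns < 2L) stop("ns must be >= 2")
  if (h < 1) stop("h must be >= 1")
  structure(list(ns = as.integer(ns), h = as.numeric(h),
                 maxGap = as.numeric(maxGap)), class = "smooth_params")
}

## clamped logit: exact for interior methylation values, bounded at the
## extremes so fully (un)methylated sites stay finite
.logit_eps <- 0.005
clamped_logit <- function(p, eps = .logit_eps) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' Split sorted positions into segments at large gaps
#' @param pos sorted integer positions.
#' @param maxGap gap threshold in bp.
#' @return integer segment id per position.
#' @keywords internal
gap_segments <- function(pos, maxGap) {
  if (!length(pos)) return(integer(0))
  cumsum(c(1L, as.integer(diff(pos) > maxGap)))
}

#' Smooth a MethylomeSet
#'
#' For each sample and each chromosome segment (chromosomes are split at
#' CpG gaps larger than `maxGap`), every site receives the value of a
#' coverage-weighted local quadratic fit on the logit methylation scale
#' over the smallest symmetric window containing at least `ns` CpGs and
#' spanning at least `h` bp on each side (tricube distance kernel). Sites
#' with zero coverage carry no weight but still receive the smoothed value.
#' Segments with fewer than `ns` CpGs fall back to the coverage-weighted
#' segment mean and are flagged in the `"fallback_segments"` attribute.
#'
#' @param ms MethylomeSet (sites sorted).
#' @param params [smooth_params()].
#' @return numeric matrix (sites x samples) of smoothed methylation in
#'   \[0, 1\], with attribute `fallback_segments` (data.frame of flagged
#'   segments, possibly empty).
#' @export
smooth_methylome <- function(ms, params = smooth_params()) {
  n <- coverage_matrix(ms)
  raw <- ms$M / pmax(n, 1L)
  y <- clamped_logit(raw)
  y[n == 0] <- 0  # zero weight anyway
  out <- matrix(NA_real_, nrow(ms$sites), ncol(ms$M))
  fallback <- list()
  for (ch in unique(ms$sites$chrom)) {
    idx <- which(ms$sites$chrom == ch)
    seg <- gap_segments(ms$sites$pos[idx], params$maxGap)
    for (sg in unique(seg)) {
      ii <- idx[seg == sg]
      pos <- ms$sites$pos[ii]
      if (length(ii) < params$ns) {
        for (j in seq_len(ncol(out))) {
          w <- as.numeric(n[ii, j])
          out[ii, j] <- if (sum(w) > 0)
            stats::plogis(sum(w * y[ii, j]) / sum(w)) else NA_real_
        }
        fallback[[length(fallback) + 1L]] <-
          data.frame(chrom = ch, start = pos[1], end = pos[length(pos)] + 1L,
                     n_cpgs = length(ii))
        next
      }
      for (j in seq_len(ncol(out))) {
        fit <- smooth_segment_cpp(as.integer(pos), y[ii, j],
                                  as.numeric(n[ii, j]),
                                  params$ns, params$h)
        out[ii, j] <- stats::plogis(fit)
      }
    }
  }
  colnames(out) <- ms$samples$sample_id
  attr(out, "fallback_segments") <-
    if (length(fallback)) do.call(rbind, fallback)
    else data.frame(chrom = character(), start = integer(),
                    end = integer(), n_cpgs = integer())
  out
}
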