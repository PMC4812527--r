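## MethylomeSet: the raw observable of WGBS -- per-CpG methylated (M) and
## unmethylated (U) read counts, site x sample, plus sample metadata.

#' Construct a MethylomeSet
#'
#' @param sites data.frame with columns `chrom` and `pos` (0-based CpG
#'   positions), one row per site.
#' @param M,U integer matrices (sites x samples) of methylated and
#'   unmethylated read counts.
#' @param samples data.frame of sample metadata with at least `sample_id`;
#'   the cohort design uses `individual_id`, `role` (mother/child),
#'   `exposure` (smoking/non_smoking) and `timepoint_years`.
#' @return object of class `MethylomeSet`.
#' @export
MethylomeSet <- function(sites, M, U, samples) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (!identical(dim(M), dim(U))) stop("M and U dimensions differ")
  if (nrow(M) != nrow(sites)) stop("count rows != number of sites")
  if (ncol(M) != nrow(samples)) stop("count columns != number of samples")
  if (any(M < 0) || any(U < 0)) stop("negative counts")
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  M <- M[o, , drop = FALSE]; U <- U[o, , drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicate CpG sites")
  colnames(M) <- colnames(U) <- samples$sample_id
  structure(list(sites = sites, M = M, U = U,
                 samples = as.data.frame(samples)),
            class = "MethylomeSet")
}

#' @method print MethylomeSet
#' @export
print.MethylomeSet <- function(x, ...) {
  cat("MethylomeSet:", nrow(x$sites), "CpG sites x",
      nrow(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  if ("exposure" %in% names(x$samples))
    cat("  exposure:", paste(names(table(x$samples$exposure)),
                             table(x$samples$exposure),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-site coverage matrix
#' @param ms MethylomeSet.
#' @return integer matrix M + U.
#' @export
coverage_matrix <- function(ms) ms$M + ms$U

#' Raw methylation fractions
#'
#' M / (M + U); `NA` where coverage is zero.
#'
#' @param ms MethylomeSet.
#' @return numeric matrix in \[0, 1\].
#' @export
raw_meth <- function(ms) {
  n <- ms$M + ms$U
  r <- ms$M / n
  r[n == 0] <- NA_real_
  r
}

#' Read per-sample CpG coverage files into a MethylomeSet
#'
#' Each file is a Bismark-coverage-style tab table with four columns:
#' chromosome, 1-based CpG position, methylated count, unmethylated count.
#' Positions are converted to the internal 0-based convention. Sites are the
#' union across samples; a site absent from one sample gets coverage 0 there.
#'
#' @param paths named character vector of file paths; names are sample ids
#'   and must match `meta$sample_id`.
#' @param meta sample metadata data.frame (see [MethylomeSet()]).
#' @return MethylomeSet.
#' @export
read_methylome <- function(paths, meta) {
  if (is.null(names(paths))) stop("paths must be named by sample id")
  meta <- as.data.frame(meta)
  if (!setequal(names(paths), meta$sample_id))
    stop("path names do not match meta$sample_id")
  paths <- paths[match(meta$sample_id, names(paths))]
  per <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    x <- tryCatch(
      utils::read.table(p, sep = "\t", header = FALSE,
                        colClasses = c("character", "integer", "integer",
                                       "integer")),
      error = function(e) stop("malformed coverage file ", p, ": ",
                               conditionMessage(e)))
    if (any(is.na(x[[2]])) || any(is.na(x[[3]])) || any(is.na(x[[4]]))) {
      bad <- which(is.na(x[[2]]) | is.na(x[[3]]) | is.na(x[[4]]))[1L]
      stop("malformed line ", bad, " in ", p)
    }
    if (any(x[[3]] < 0L) || any(x[[4]] < 0L))
      stop("negative count in ", p)
    key <- paste(x[[1]], x[[2]])
    if (anyDuplicated(key))
      stop("duplicate site in ", p, " at line ", which(duplicated(key))[1L])
    data.frame(chrom = x[[1]], pos = x[[2]] - 1L, M = x[[3]], U = x[[4]],
               stringsAsFactors = FALSE)
  })
  all_sites <- unique(do.call(rbind, lapply(per, function(d)
    d[, c("chrom", "pos")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), ,
                         drop = FALSE]
  rownames(all_sites) <- NULL
  key <- paste(all_sites$chrom, all_sites$pos)
  M <- U <- matrix(0L, nrow(all_sites), length(per))
  for (i in seq_along(per)) {
    j <- match(paste(per[[i]]$chrom, per[[i]]$pos), key)
    M[j, i] <- per[[i]]$M
    U[j, i] <- per[[i]]$U
  }
  MethylomeSet(all_sites, M, U, meta)
}

#' Write a MethylomeSet as per-sample coverage files
#'
#' Inverse of [read_methylome()] (1-based positions on disk). Sites with zero
#' coverage in a sample are omitted from that sample's file.
#'
#' @param ms MethylomeSet.
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_methylome <- function(ms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (i in seq_len(nrow(ms$samples))) {
    sid <- ms$samples$sample_id[i]
    keep <- (ms$M[, i] + ms$U[, i]) > 0L
    d <- data.frame(ms$sites$chrom[keep], ms$sites$pos[keep] + 1L,
                    ms$M[keep, i], ms$U[keep, i])
    p <- file.path(dir, paste0(sid, ".cov"))
    utils::write.table(d, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out[sid] <- p
  }
  out
}

#' Read or write sample metadata
#'
#' Tab-separated with header; columns `sample_id`, `individual_id`, `role`,
#' `exposure`, `timepoint_years`. Validates the design invariants: one
#' sample per (individual, timepoint) and exposure constant within an
#' individual.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_sample_meta(m)
}

#' @rdname read_sample_meta
#' @param meta metadata data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_sample_meta <- function(m) {
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id")
  if (all(c("individual_id", "timepoint_years") %in% names(m)) &&
      anyDuplicated(m[, c("individual_id", "timepoint_years")]))
    stop("duplicate (individual_id, timepoint_years)")
  if (all(c("individual_id", "exposure") %in% names(m))) {
    sp <- split(m$exposure, m$individual_id)
    if (any(vapply(sp, function(e) length(unique(e)), 1L) > 1L))
      stop("exposure not constant within individual")
  }
  m
}

#' Subset a MethylomeSet by samples or sites
#'
#' @param ms MethylomeSet.
#' @param samples logical/integer index or character sample ids.
#' @param sites logical/integer index into site rows.
#' @return MethylomeSet.
#' @export
subset_methylome <- function(ms, samples = NULL, sites = NULL) {
  M <- ms$M; U <- ms$U; sm <- ms$samples; st <- ms$sites
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, sm$sample_id)
    M <- M[, samples, drop = FALSE]; U <- U[, samples, drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
  }
  if (!is.null(sites)) {
    M <- M[sites, , drop = FALSE]; U <- U[sites, , drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  rownames(sm) <- rownames(st) <- NULL
  MethylomeSet(st, M, U, sm)
}

#' Group index helper: which samples are exposed?
#' @param samples sample metadata data.frame.
#' @return list with integer indices `smoking` and `non_smoking`.
#' @export
exposure_groups <- function(samples) {
  list(smoking = which(samples$exposure == "smoking"),
       non_smoking = which(samples$exposure == "non_smoking"))
}

#' Per-sample mean raw methylation over a region
#'
#' Mean of per-site raw methylation fractions across the CpGs of a region,
#' per sample (sites without coverage in a sample are dropped for that
#' sample). This raw regional mean is the DMR-level summary used throughout
#' (meQTL association, stability, expression coupling).
#'
#' @param ms MethylomeSet.
#' @param chrom,start,end region, 0-based half-open.
#' @return numeric vector along samples (`NA` when no site is covered).
#' @export
region_mean_meth <- function(ms, chrom, start, end) {
  sel <- ms$sites$chrom == chrom & ms$sites$pos >= start &
    ms$sites$pos < end
  if (!any(sel)) return(rep(NA_real_, nrow(ms$samples)))
  r <- raw_meth(subset_methylome(ms, sites = which(sel)))
  colMeans(r, na.rm = TRUE)
}
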