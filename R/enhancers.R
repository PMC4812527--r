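## Enhancer classification: locate enhancers relative to gene bodies,
## attach interaction-derived target genes, flag differentially methylated
## enhancers (DMEs) and their genotype class, and identify commuting /
## exclusive commuting enhancers.

#' Classify enhancers by location, targets and differential methylation
#'
#' Location is intragenic when the enhancer overlaps any gene body (the
#' host is the gene with the largest overlap); targets are genes linked by
#' any interaction whose anchor region overlaps the enhancer. An enhancer
#' is a DME iff it overlaps at least one DMR; its class is gDME if any
#' overlapping DMR is a gDMR, else ngDME. A commuting enhancer is
#' intragenic with at least one target other than its host; an exclusive
#' commuting enhancer is a commuting enhancer whose targets do not include
#' the host.
#'
#' @param enhancers interval data.frame.
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end` gene body).
#' @param interactions region-gene pair table (see [read_interactions()]).
#' @param dmrs DMR data.frame; a `dmr_class` column (gDMR/ngDMR) drives
#'   `dme_class`.
#' @return data.frame: one row per enhancer with location, host_gene,
#'   n_targets, targets (comma-joined), is_dme, dme_class, commuting,
#'   exclusive_commuting.
#' @export
classify_enhancers <- function(enhancers, genes, interactions, dmrs) {
  n <- nrow(enhancers)
  host <- rep(NA_character_, n)
  ov <- interval_overlaps(enhancers, genes)
  if (nrow(ov)) {
    ov$olap <- pmin(enhancers$end[ov$query], genes$end[ov$subject]) -
      pmax(enhancers$start[ov$query], genes$start[ov$subject])
    for (q in unique(ov$query)) {
      sub <- ov[ov$query == q, ]
      host[q] <- genes$gene_id[sub$subject[which.max(sub$olap)]]
    }
  }
  targets <- vector("list", n)
  iv <- interactions[, c("chrom", "start", "end")]
  ovi <- interval_overlaps(enhancers, iv)
  for (q in unique(ovi$query))
    targets[[q]] <- sort(unique(interactions$gene_id[
      ovi$subject[ovi$query == q]]))
  is_dme <- overlaps_any(enhancers, dmrs)
  dme_class <- rep(NA_character_, n)
  if ("dmr_class" %in% names(dmrs) && nrow(dmrs)) {
    ovd <- interval_overlaps(enhancers, dmrs)
    for (q in unique(ovd$query)) {
      cls <- dmrs$dmr_class[ovd$subject[ovd$query == q]]
      dme_class[q] <- if (any(cls == "gDMR", na.rm = TRUE)) "gDME"
      else "ngDME"
    }
  }
  location <- ifelse(is.na(host), "intergenic", "intragenic")
  commuting <- vapply(seq_len(n), function(i) {
    location[i] == "intragenic" &&
      length(setdiff(targets[[i]], host[i])) >= 1L
  }, TRUE)
  exclusive <- commuting & vapply(seq_len(n), function(i)
    !(host[i] %in% targets[[i]]), TRUE)
  data.frame(chrom = enhancers$chrom, start = enhancers$start,
             end = enhancers$end, location = location, host_gene = host,
             n_targets = lengths(targets),
             targets = vapply(targets, paste, "", collapse = ","),
             is_dme = is_dme, dme_class = dme_class,
             commuting = commuting, exclusive_commuting = exclusive,
             stringsAsFactors = FALSE)
}

#' Compare DMEs with other enhancers
#'
#' Two-sided Mann-Whitney tests of element length and of target count, DME
#' versus non-DME, separately for intragenic and intergenic elements.
#' Strata with fewer than 3 elements on either side are skipped with a
#' warning.
#'
#' @param ann [classify_enhancers()] output.
#' @return data.frame: stratum, variable, n_dme, n_other, median_dme,
#'   median_other, p (NA when skipped).
#' @export
compare_dme_vs_enhancers <- function(ann) {
  out <- list()
  for (loc in c("intragenic", "intergenic")) {
    sub <- ann[ann$location == loc, , drop = FALSE]
    for (v in c("length", "n_targets")) {
      x <- if (v == "length") sub$end - sub$start else sub$n_targets
      a <- x[sub$is_dme]; b <- x[!sub$is_dme]
      if (length(a) < 3L || length(b) < 3L) {
        warning("stratum ", loc, "/", v, " skipped (< 3 elements)")
        p <- NA_real_
      } else {
        p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        stratum = loc, variable = v,
        n_dme = length(a), n_other = length(b),
        median_dme = if (length(a)) stats::median(a) else NA_real_,
        median_other = if (length(b)) stats::median(b) else NA_real_,
        p = p)
    }
  }
  do.call(rbind, out)
}
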