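## Methylation-expression integration: target-gene assignment by chromatin
## category, Spearman coupling of DMR methylation with target expression,
## genome-wide moderated differential expression with BH correction,
## hypergeometric gene-set enrichment, and the odds-ratio extrapolation
## arithmetic.

#' Assign target genes to DMRs by chromatin category
#'
#' Each DMR contributes one record per overlapped element category. For
#' void or promoter (TSS-associated) categories the target is the gene
#' with the nearest TSS to the DMR midpoint (ties to the lower-coordinate
#' gene); for repressed or enhancer categories the targets come from the
#' interaction pairs overlapping the DMR; for DMRs in enhancers the
#' element's own interaction targets are unioned in (DME rule). DMRs
#' overlapping no element are treated as void.
#'
#' @param dmrs DMR data.frame.
#' @param elements classified element table ([classify_elements()]).
#' @param genes gene table with `tss`.
#' @param interactions region-gene pair table.
#' @return data.frame: dmr_id, category, gene_id (one row per target;
#'   rows with `NA` gene_id mark enhancer/repressed DMRs with no
#'   interaction target, excluded from correlation).
#' @export
assign_targets <- function(dmrs, elements, genes, interactions) {
  if (!nrow(dmrs))
    return(data.frame(dmr_id = character(), category = character(),
                      gene_id = character()))
  mid <- (dmrs$start + dmrs$end) / 2
  nearest_gene <- vapply(seq_len(nrow(dmrs)), function(i) {
    same <- which(genes$chrom == dmrs$chrom[i])
    if (!length(same)) return(NA_character_)
    d <- abs(genes$tss[same] - mid[i])
    cand <- same[d == min(d)]
    genes$gene_id[cand[which.min(genes$tss[cand])]]
  }, "")
  iv <- interactions[, c("chrom", "start", "end")]
  ovi <- interval_overlaps(dmrs, iv)
  dmr_itargets <- lapply(seq_len(nrow(dmrs)), function(i)
    unique(interactions$gene_id[ovi$subject[ovi$query == i]]))
  ove <- interval_overlaps(dmrs, elements)
  out <- list()
  for (i in seq_len(nrow(dmrs))) {
    el <- ove$subject[ove$query == i]
    cats <- if (length(el)) unique(elements$category[el]) else "void"
    for (cat in cats) {
      if (cat %in% c("void", "promoter")) {
        gid <- nearest_gene[i]
      } else if (cat == "enhancer") {
        enh_el <- el[elements$category[el] == "enhancer"]
        enh_iv <- elements[enh_el, c("chrom", "start", "end"),
                           drop = FALSE]
        ov2 <- interval_overlaps(enh_iv, iv)
        enh_targets <- unique(interactions$gene_id[ov2$subject])
        gid <- union(dmr_itargets[[i]], enh_targets)  # DME union rule
        if (!length(gid)) gid <- NA_character_
      } else {  # repressed / bivalent / amplification: interaction-derived
        gid <- dmr_itargets[[i]]
        if (!length(gid)) gid <- NA_character_
      }
      out[[length(out) + 1L]] <-
        data.frame(dmr_id = dmrs$dmr_id[i], category = cat,
                   gene_id = gid, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate DMR methylation with target-gene expression
#'
#' Spearman correlation (and test) between each DMR's per-sample mean raw
#' methylation and its target gene's expression, by chromatin category.
#' Pairs with constant methylation or expression are skipped, as are
#' records without a target.
#'
#' @param targets [assign_targets()] output.
#' @param dmrs DMR data.frame (coordinates for the methylation summary).
#' @param ms MethylomeSet.
#' @param expr genes x samples expression matrix; columns matched to
#'   `ms$samples$sample_id` via `expr_samples`.
#' @param expr_samples sample ids for the expression columns (default
#'   `colnames(expr)`).
#' @param alpha significance cutoff (default 0.05).
#' @return list of class `meth_expr_correlation`: `records` (dmr_id,
#'   gene_id, category, rho, p, sign) and `summary` (per category:
#'   fraction significant, split positive/negative).
#' @export
correlate_meth_expr <- function(targets, dmrs, ms, expr,
                                expr_samples = colnames(expr),
                                alpha = 0.05) {
  common <- intersect(ms$samples$sample_id, expr_samples)
  if (length(common) < 5L) stop("need >= 5 samples with both measurements")
  mi <- match(common, ms$samples$sample_id)
  ei <- match(common, expr_samples)
  targets <- targets[!is.na(targets$gene_id), , drop = FALSE]
  targets <- targets[targets$gene_id %in% rownames(expr), , drop = FALSE]
  recs <- list()
  meth_cache <- new.env()
  for (k in seq_len(nrow(targets))) {
    id <- targets$dmr_id[k]
    if (is.null(meth_cache[[id]])) {
      i <- match(id, dmrs$dmr_id)
      meth_cache[[id]] <- region_mean_meth(ms, dmrs$chrom[i],
                                           dmrs$start[i], dmrs$end[i])[mi]
    }
    m <- meth_cache[[id]]
    e <- expr[targets$gene_id[k], ei]
    ok <- !is.na(m) & !is.na(e)
    if (sum(ok) < 5L) next
    if (stats::sd(m[ok]) == 0 || stats::sd(e[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(m[ok], e[ok],
                                           method = "spearman"))
    recs[[length(recs) + 1L]] <- data.frame(
      dmr_id = id, gene_id = targets$gene_id[k],
      category = targets$category[k],
      rho = unname(ct$estimate), p = ct$p.value,
      sign = ifelse(unname(ct$estimate) >= 0, "positive", "negative"),
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(dmr_id = character(), gene_id = character(),
               category = character(), rho = numeric(), p = numeric(),
               sign = character())
  sm <- lapply(split(records, records$category), function(sub) {
    sig <- sub$p < alpha
    data.frame(category = sub$category[1], n_pairs = nrow(sub),
               frac_significant = mean(sig),
               frac_sig_negative = mean(sig & sub$rho < 0),
               frac_sig_positive = mean(sig & sub$rho >= 0))
  })
  summary <- if (length(sm)) do.call(rbind, sm) else
    data.frame(category = character(), n_pairs = integer(),
               frac_significant = numeric(), frac_sig_negative = numeric(),
               frac_sig_positive = numeric())
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary, alpha = alpha),
            class = "meth_expr_correlation")
}

#' @method print meth_expr_correlation
#' @export
print.meth_expr_correlation <- function(x, ...) {
  cat("Methylation-expression coupling (alpha =", x$alpha, "):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Genome-wide moderated differential expression
#'
#' Per-gene two-sample test on normalized expression with the pooled
#' variance shrunk toward the gene-wise median
#' (`s*^2 = (s_g^2 + median(s_g^2)) / 2`), t-distributed p-values with
#' `n1 + n2 - 2` degrees of freedom and Benjamini-Hochberg adjustment.
#'
#' @param expr genes x samples matrix.
#' @param groups list with column indices `smoking`, `non_smoking`
#'   (each >= 2).
#' @param fdr BH threshold for the significant set (default 0.10).
#' @return data.frame: gene_id, diff, t, p, q, significant.
#' @export
differential_expression <- function(expr, groups, fdr = 0.10) {
  i1 <- groups$smoking; i2 <- groups$non_smoking
  if (length(i1) < 2L || length(i2) < 2L) stop("group size < 2")
  g1 <- row_group_stats(expr, i1)
  g2 <- row_group_stats(expr, i2)
  s2 <- ((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) / (g1$n + g2$n - 2)
  s2s <- (s2 + stats::median(s2)) / 2
  se <- sqrt(s2s * (1 / g1$n + 1 / g2$n))
  tt <- (g1$mean - g2$mean) / se
  df <- g1$n + g2$n - 2
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(expr), diff = g1$mean - g2$mean,
             t = tt, p = p, q = q, significant = q <= fdr,
             stringsAsFactors = FALSE)
}

#' Gene-set enrichment of DMR target genes
#'
#' Hypergeometric upper-tail p per set against the universe, BH-adjusted;
#' optionally a set-level differential-expression score: the permutation p
#' of the mean absolute per-gene DE statistic in the set against
#' size-matched random gene sets.
#'
#' @param target_genes character vector of target gene ids.
#' @param sets named list of gene-id vectors.
#' @param universe character vector of all candidate gene ids.
#' @param de optional [differential_expression()] table for the DE score.
#' @param n_draws random size-matched sets for the DE score (default 1000).
#' @return data.frame: set_id, counts, p (hypergeometric), q (BH),
#'   de_score_p.
#' @export
geneset_enrichment <- function(target_genes, sets, universe, de = NULL,
                               n_draws = 1000L) {
  if (!length(universe)) stop("empty universe")
  targets <- intersect(unique(target_genes), universe)
  res <- lapply(names(sets), function(sid) {
    set <- intersect(sets[[sid]], universe)
    k <- length(intersect(targets, set))
    ## P(X >= k), X ~ Hypergeom(|set| white, |universe|-|set| black,
    ## |targets| drawn)
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(targets), lower.tail = FALSE)
    dp <- NA_real_
    if (!is.null(de) && length(set) > 0L) {
      tvec <- stats::setNames(abs(de$t), de$gene_id)
      inset <- intersect(set, de$gene_id)
      if (length(inset)) {
        obs <- mean(tvec[inset])
        null <- vapply(seq_len(n_draws), function(j)
          mean(tvec[sample(de$gene_id, length(inset))]), 1.0)
        dp <- (1 + sum(null >= obs)) / (1 + n_draws)
      }
    }
    data.frame(set_id = sid, n_targets_in_set = k,
               n_targets_total = length(targets),
               set_size = length(set), universe_size = length(universe),
               p = p, de_score_p = dp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("set_id", "n_targets_in_set", "n_targets_total", "set_size",
          "universe_size", "p", "q", "de_score_p")]
}

#' Linear odds-ratio risk extrapolation
#'
#' Converts a per-unit odds ratio into a percent risk increase over a
#' number of units under the linear reading
#' `(OR - 1) * 100 * units` (an OR of 1.40 per 10% methylation loss reads
#' as a 40% risk increase per unit and ~400% over full loss); the
#' multiplicative alternative `OR^units` is reported alongside.
#'
#' @param or_per_unit odds ratio per unit exposure (> 0).
#' @param units number of units to extrapolate over.
#' @return list: percent_increase_linear, percent_increase_multiplicative.
#' @export
extrapolate_odds <- function(or_per_unit, units) {
  if (or_per_unit <= 0) stop("or_per_unit must be > 0")
  list(percent_increase_linear = (or_per_unit - 1) * 100 * units,
       percent_increase_multiplicative = (or_per_unit^units - 1) * 100)
}
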