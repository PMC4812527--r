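test_that("target assignment applies the category rules", {
  genes <- data.frame(gene_id = c("G7", "G8"), chrom = "chr1",
                      start = c(50000, 70000), end = c(60000, 80000),
                      tss = c(50000, 70000))
  elements <- data.frame(chrom = "chr1",
                         start = c(1000, 10000), end = c(2000, 11000),
                         state = c(2L, 13L),
                         category = c("enhancer", "repressed"))
  inter <- data.frame(chrom = "chr1",
                      start = c(1000, 1000, 1500), end = c(2000, 2000, 1600),
                      gene_id = c("G1", "G2", "G3"))
  dmrs <- data.frame(dmr_id = c("d1", "d2", "d3"), chrom = "chr1",
                     start = c(30000, 1400, 10100),
                     end = c(30500, 1700, 10400))
  tg <- assign_targets(dmrs, elements, genes, inter)
  ## d1 overlaps nothing -> void, nearest TSS is G7
  expect_equal(tg$gene_id[tg$dmr_id == "d1"], "G7")
  expect_equal(tg$category[tg$dmr_id == "d1"], "void")
  ## d2 in an enhancer: union of its own and the element's targets
  expect_setequal(tg$gene_id[tg$dmr_id == "d2"], c("G1", "G2", "G3"))
  ## d3 in a repressed element with no interaction -> empty target record
  expect_true(is.na(tg$gene_id[tg$dmr_id == "d3"]))
  ## equidistant TSS tie goes to the lower coordinate gene
  dmrs2 <- data.frame(dmr_id = "tie", chrom = "chr1", start = 59990,
                      end = 60010)
  tg2 <- assign_targets(dmrs2, elements[0, ], genes, inter)
  expect_equal(tg2$gene_id, "G7")
})

test_that("Spearman coupling records and summaries behave", {
  pos <- seq(0, 900, by = 100)
  meth <- matrix(seq(0.1, 0.8, length.out = 10), 10, 10)
  ms <- make_ms(pos, meth, cov = 100L,
                exposure = rep(c("smoking", "non_smoking"), each = 5))
  ## perfectly anti-monotone expression for one gene
  m <- region_mean_meth(ms, "chr1", 0, 1000)
  m <- m + seq(0, 0.09, length.out = 10)  # distinct per sample
  ms2 <- make_ms(pos, matrix(rep(m, each = 10), 10, 10), cov = 100L,
                 exposure = rep(c("smoking", "non_smoking"), each = 5))
  expr <- rbind(G1 = -rank(region_mean_meth(ms2, "chr1", 0, 1000)),
                G2 = rnorm(10))
  colnames(expr) <- ms2$samples$sample_id
  dmrs <- data.frame(dmr_id = "d1", chrom = "chr1", start = 0, end = 1000)
  targets <- data.frame(dmr_id = "d1", category = "enhancer",
                        gene_id = c("G1", "G2"))
  cc <- correlate_meth_expr(targets, dmrs, ms2, expr)
  r1 <- cc$records[cc$records$gene_id == "G1", ]
  expect_equal(r1$rho, -1)
  expect_lt(r1$p, 0.05)
  expect_equal(r1$sign, "negative")
  ## invariance to a monotone transform of expression
  expr2 <- expr; expr2["G1", ] <- exp(expr["G1", ] / 3)
  cc2 <- correlate_meth_expr(targets, dmrs, ms2, expr2)
  expect_equal(cc2$records$rho, cc$records$rho)
  ## constant expression is skipped
  expr3 <- expr; expr3["G2", ] <- 5
  cc3 <- correlate_meth_expr(targets, dmrs, ms2, expr3)
  expect_equal(nrow(cc3$records), 1L)
  expect_error(correlate_meth_expr(targets, dmrs,
                                   subset_methylome(ms2, samples = 1:3),
                                   expr), ">= 5 samples")
})

test_that("planted coupling signs are recovered and the null is calibrated", {
  sim <- small_sim()
  ms <- sim$methylomes$t0
  tr <- sim$truth$pairs
  dmrs <- unique(tr[, c("chrom", "start", "end")])
  dmrs$dmr_id <- sprintf("p%03d", seq_len(nrow(dmrs)))
  key <- paste(tr$chrom, tr$start)
  tr$dmr_id <- dmrs$dmr_id[match(key, paste(dmrs$chrom, dmrs$start))]
  targets <- data.frame(dmr_id = tr$dmr_id,
                        category = ifelse(tr$coupling == "enhancer",
                                          "enhancer", "repressed"),
                        gene_id = tr$gene_id)
  cc <- correlate_meth_expr(targets, dmrs, ms, sim$expression)
  sm <- cc$summary
  enh <- sm[sm$category == "enhancer", ]
  rep_ <- sm[sm$category == "repressed", ]
  ## the sign asymmetry: enhancers couple negatively, repressed positively
  expect_gt(enh$frac_sig_negative, enh$frac_sig_positive)
  expect_gt(rep_$frac_sig_positive, rep_$frac_sig_negative)
  expect_gt(enh$frac_significant, 0.5)
  ## permuted sample labels: about alpha of pairs significant
  set.seed(91)
  expr_perm <- sim$expression[, sample(ncol(sim$expression))]
  colnames(expr_perm) <- colnames(sim$expression)
  cc0 <- correlate_meth_expr(targets, dmrs, ms, expr_perm)
  frac0 <- mean(cc0$records$p < 0.05)
  expect_lt(frac0, 0.25)
})

test_that("moderated differential expression matches the step-up oracle", {
  set.seed(93)
  expr <- matrix(rnorm(200 * 12, 10, 0.25), 200, 12,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  groups <- list(smoking = 1:6, non_smoking = 7:12)
  de0 <- differential_expression(expr, groups)
  expect_equal(sum(de0$significant), 0L)
  ## planted 1-unit shifts (2-fold on a log2 scale) in 50 genes, SD 0.25
  expr2 <- expr
  expr2[1:50, 1:6] <- expr2[1:50, 1:6] + 1
  de2 <- differential_expression(expr2, groups)
  expect_gte(mean(de2$significant[1:50]), 0.8)
  expect_lte(mean(de2$significant[51:200]), 0.1)
  ## BH rejection set equals the textbook step-up rule
  bh_oracle <- function(p, q) {
    o <- order(p)
    k <- which(p[o] <= seq_along(p) / length(p) * q)
    rej <- rep(FALSE, length(p))
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  for (rep_i in 1:5) {
    p <- runif(sample(5:20, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH") <= 0.1, bh_oracle(p, 0.1))
  }
  expect_equal(de2$significant, bh_oracle(de2$p, 0.10))
  expect_error(differential_expression(expr, list(smoking = 1,
                                                  non_smoking = 2:12)),
               "group size")
})

test_that("gene-set enrichment matches the hypergeometric tail sum", {
  ## 2x2 oracle: 10 of a 50-gene set among 100 targets from 10000 genes
  universe <- sprintf("u%05d", 1:10000)
  set <- universe[1:50]
  targets <- c(universe[1:10], universe[101:190])
  res <- geneset_enrichment(targets, list(s = set), universe)
  tail_sum <- sum(sapply(10:50, function(k)
    choose(50, k) * choose(9950, 100 - k) / choose(10000, 100)))
  expect_equal(res$p, tail_sum, tolerance = 1e-12)
  ## extreme containment is overwhelmingly significant
  res2 <- geneset_enrichment(set, list(s = set), universe)
  expect_lt(res2$q, 1e-10)
  ## null targets: p roughly uniform
  set.seed(95)
  sets <- lapply(1:40, function(i) sample(universe, 50))
  names(sets) <- paste0("s", 1:40)
  res3 <- geneset_enrichment(sample(universe, 100), sets, universe)
  expect_gt(mean(res3$p > 0.05), 0.7)
  expect_error(geneset_enrichment(targets, list(s = set), character(0)),
               "universe")
  ## set-level DE score flags a shifted set
  de <- data.frame(gene_id = universe[1:500],
                   t = c(rnorm(50, 4), rnorm(450)))
  res4 <- geneset_enrichment(universe[1:50],
                             list(hot = universe[1:50],
                                  cold = universe[451:500]),
                             universe[1:500], de = de, n_draws = 200)
  expect_lt(res4$de_score_p[1], 0.05)
  expect_gt(res4$de_score_p[2], 0.2)
})

test_that("odds-ratio extrapolation reproduces the linear reading", {
  e1 <- extrapolate_odds(1.40, 1)
  expect_equal(e1$percent_increase_linear, 40, tolerance = 1e-12)
  e10 <- extrapolate_odds(1.40, 10)
  expect_equal(e10$percent_increase_linear, 400, tolerance = 1e-12)
  expect_equal(e10$percent_increase_multiplicative, (1.4^10 - 1) * 100)
  expect_equal(extrapolate_odds(1, 7)$percent_increase_linear, 0)
  expect_error(extrapolate_odds(0, 1), "> 0")
})
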