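test_that("same seed gives bit-identical outputs", {
  cfg <- sim_config(genome = c(chr1 = 5e5), n_exposure_dmrs = 3,
                    n_genotype_dmrs = 2, n_cpg_destroying_snps = 1,
                    n_null_snps = 10, timepoints = 0L,
                    n_enhancer_gene_pairs = 5, seed = 3L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$methylomes$t0$M, b$methylomes$t0$M)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$chromatin$tracks, b$chromatin$tracks)
  expect_identical(a$expression, b$expression)
})

test_that("null configuration plants no group difference", {
  cfg <- sim_config(genome = c(chr1 = 1e6), n_exposure_dmrs = 6,
                    n_genotype_dmrs = 0, n_cpg_destroying_snps = 0,
                    n_null_snps = 0, exposure_effect = 0, meqtl_slope = 0,
                    timepoints = 0L, n_enhancer_gene_pairs = 2, seed = 5L)
  sim <- simulate_dataset(cfg)
  ms <- sim$methylomes$t0
  grp <- exposure_groups(ms$samples)
  deltas <- vapply(seq_len(nrow(sim$truth$dmrs)), function(i) {
    m <- region_mean_meth(ms, sim$truth$dmrs$chrom[i],
                          sim$truth$dmrs$start[i], sim$truth$dmrs$end[i])
    mean(m[grp$smoking]) - mean(m[grp$non_smoking])
  }, 1.0)
  ## expectation 0; binomial/beta-binomial noise only
  expect_lt(max(abs(deltas)), 0.08)
  expect_lt(abs(mean(deltas)), 0.03)
})

test_that("planted exposure delta is recovered in the raw counts", {
  ## Monte-Carlo: mean raw group difference over planted CpGs ~ 0.2
  sim <- small_sim()
  ms <- sim$methylomes$t0
  grp <- exposure_groups(ms$samples)
  r <- raw_meth(ms)
  tr <- sim$truth$dmrs[sim$truth$dmrs$class == "exposure", ]
  site_deltas <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    sel <- ms$sites$chrom == tr$chrom[i] & ms$sites$pos >= tr$start[i] &
      ms$sites$pos < tr$end[i]
    d <- rowMeans(r[sel, grp$smoking], na.rm = TRUE) -
      rowMeans(r[sel, grp$non_smoking], na.rm = TRUE)
    d * tr$sign[i]
  }))
  expect_gt(length(site_deltas), 120)
  expect_lt(abs(mean(site_deltas, na.rm = TRUE) - 0.2), 0.03)
})

test_that("CpG-destroying SNPs force carrier methylation to 0.5 / 0", {
  sim <- small_sim()
  ms <- sim$methylomes$t0
  r <- raw_meth(ms)
  gt <- sim$genotypes
  ds <- sim$truth$destroy_sites
  het <- hom <- wt <- numeric(0)
  for (k in seq_len(nrow(ds))) {
    si <- which(ms$sites$chrom == ds$chrom[k] & ms$sites$pos == ds$pos[k])
    dos <- gt$dosage[ds$snp_id[k], ]
    het <- c(het, r[si, dos == 1L])
    hom <- c(hom, r[si, dos == 2L])
    wt <- c(wt, r[si, dos == 0L])
  }
  expect_lt(abs(mean(het, na.rm = TRUE) - 0.5), 0.06)
  expect_lt(mean(hom, na.rm = TRUE), 0.03)
  expect_gt(mean(wt, na.rm = TRUE), 0.85)
})

test_that("planted DMRs satisfy caller preconditions", {
  sim <- small_sim()
  expect_true(all(sim$truth$dmrs$n_cpgs >= 11))
  expect_true(all(sim$truth$dmrs$end - sim$truth$dmrs$start >= 1000))
  ## disjoint planting
  tr <- sim$truth$dmrs
  expect_false(any(duplicated(
    interval_overlaps(tr, tr)$query[
      interval_overlaps(tr, tr)$query !=
        interval_overlaps(tr, tr)$subject])))
})

test_that("chromatin tracks: noiseless limit, no-transition limit, emissions", {
  cfg <- sim_config(genome = c(chr1 = 3e5), n_exposure_dmrs = 2,
                    n_genotype_dmrs = 0, n_cpg_destroying_snps = 0,
                    n_null_snps = 0, timepoints = 0L, p_on = 1, p_off = 0,
                    n_enhancer_gene_pairs = 2, seed = 9L)
  meth <- simulate_methylomes(cfg)
  chrom <- simulate_chromatin(cfg, meth$truth)
  tab <- chromatin_state_table()
  pat <- as.matrix(tab[match(chrom$consensus$smoking, tab$state),
                       chromatin_marks()])
  expect_equal(unname(chrom$tracks$smk01), unname(pat))  # p_on=1, p_off=0
  cfg0 <- sim_config(genome = c(chr1 = 3e5), n_exposure_dmrs = 2,
                     n_genotype_dmrs = 0, n_cpg_destroying_snps = 0,
                     n_null_snps = 0, timepoints = 0L,
                     transition_fraction = 0,
                     n_enhancer_gene_pairs = 2, seed = 9L)
  chrom0 <- simulate_chromatin(cfg0, meth$truth)
  expect_identical(chrom0$consensus$smoking, chrom0$consensus$non_smoking)
  ## a planted enhancer-coupled DMR carries an active state with both
  ## active marks in the consensus
  enh_dmr <- meth$truth$dmrs[meth$truth$dmrs$class == "exposure", ][
    chrom$coupling == "enhancer", ][1, ]
  ii <- which(chrom$bins$chrom == enh_dmr$chrom &
                chrom$bins$end > enh_dmr$start &
                chrom$bins$start < enh_dmr$end)
  st <- unique(chrom$consensus$non_smoking[ii])
  expect_true(all(tab$meta[match(st, tab$state)] == "active"))
})

test_that("expression coupling hits the target correlation magnitude", {
  sim <- small_sim()  # rho = 0.6, 16 samples, 20 pairs
  ms <- sim$methylomes$t0
  rhos <- vapply(seq_len(nrow(sim$truth$pairs)), function(j) {
    p <- sim$truth$pairs[j, ]
    m <- region_mean_meth(ms, p$chrom, p$start, p$end)
    suppressWarnings(cor(m, sim$expression[p$gene_id, ],
                         method = "spearman"))
  }, 1.0)
  signs <- ifelse(sim$truth$pairs$coupling == "enhancer", -1, 1)
  expect_true(all(sign(rhos) == signs))  # sign structure
  expect_lt(abs(mean(abs(rhos)) - 0.6), 0.12)
  ## noise-free limit: coupling is an exact monotone map
  cfg1 <- sim_config(genome = c(chr1 = 5e5), n_exposure_dmrs = 4,
                     n_genotype_dmrs = 0, n_cpg_destroying_snps = 0,
                     n_null_snps = 0, timepoints = 0L,
                     n_enhancer_gene_pairs = 4, expr_coupling_rho = 1,
                     seed = 13L)
  s1 <- simulate_dataset(cfg1)
  p <- s1$truth$pairs[s1$truth$pairs$coupling == "enhancer", ][1, ]
  m <- region_mean_meth(s1$methylomes$t0, p$chrom, p$start, p$end)
  expect_equal(suppressWarnings(
    cor(m, s1$expression[p$gene_id, ], method = "spearman")), -1)
})

test_that("an undersized genome fails placement with a clear error", {
  cfg <- sim_config(genome = c(chr1 = 3e4), n_exposure_dmrs = 50,
                    timepoints = 0L, seed = 1L)
  expect_error(simulate_methylomes(cfg), "too small")
  expect_error(sim_config(n_states_planted = 17L), "16")
})
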