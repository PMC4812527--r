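test_that("candidate segmentation recovers planted blocks exactly", {
  ## clean data: per-sample constant offsets give a flat within-group SD,
  ## the planted block is the only group difference
  n <- 2000
  pos <- seq(0, by = 100, length.out = n)
  offs <- c(-0.015, -0.005, 0.005, 0.015)  # sums to zero in each group
  base <- matrix(0.5, n, 8) + rep(c(offs, offs), each = n)
  block <- 61:80
  base[block, 1:4] <- base[block, 1:4] + 0.3  # smoking group shifted
  ms <- make_ms(pos, base, cov = 200L)
  sm <- smooth_methylome(ms)
  grp <- exposure_groups(ms$samples)
  cand <- candidate_dmrs(ms, sm, grp)
  ## exactly one candidate overlaps the block and covers it fully; the
  ## local quadratic fit can add small opposite-sign side lobes at the
  ## step, which never carry a material methylation difference
  block_iv <- data.frame(chrom = "chr1", start = pos[min(block)],
                         end = pos[max(block)] + 2)
  hit <- overlaps_any(cand, block_iv)
  expect_equal(sum(hit), 1L)
  main <- cand[hit, ]
  expect_lte(main$idx_start, min(block))
  expect_gte(main$idx_end, max(block))
  expect_gte(main$idx_start, min(block) - 8)
  expect_lte(main$idx_end, max(block) + 8)
  expect_gte(main$delta_raw, 0.2)  # block delta diluted by edge sites
  expect_true(all(abs(cand$delta_raw[!hit]) < 0.05))
  ## two blocks separated by a sub-threshold valley -> two main candidates
  base2 <- matrix(0.5, n, 8) + rep(c(offs, offs), each = n)
  base2[41:60, 1:4] <- base2[41:60, 1:4] + 0.3
  base2[121:140, 1:4] <- base2[121:140, 1:4] + 0.3
  ms2 <- make_ms(pos, base2, cov = 200L)
  cand2 <- candidate_dmrs(ms2, smooth_methylome(ms2), grp)
  expect_equal(sum(abs(cand2$delta_raw) > 0.1), 2L)
  expect_equal(length(unique(cand2$idx_start[abs(cand2$delta_raw) > 0.1])),
               2L)
  expect_error(candidate_dmrs(ms, sm, list(smoking = integer(),
                                           non_smoking = 1:8)),
               ">= 2 samples")
})

test_that("SAM statistic: null candidates, s0 = 0 reduction, exact p", {
  set.seed(43)
  pos <- seq(0, by = 100, length.out = 30)
  meth <- matrix(rep(runif(30, 0.3, 0.7), 8), 30, 8)  # identical samples
  ms <- make_ms(pos, meth, cov = 50L)
  grp <- exposure_groups(ms$samples)
  cand <- data.frame(chrom = "chr1", start = 0, end = 3000, n_cpgs = 30,
                     idx_start = c(1, 11), idx_end = c(10, 20),
                     stat_mean = 0)
  sam <- sam_moderated_test(ms, cand, grp, n_perm = 50)
  expect_equal(sam$d, c(0, 0))
  expect_gt(min(sam$p_sam), 0.9)
  ## s0 = 0 on noisy data: d equals the textbook pooled-variance t
  meth2 <- matrix(runif(30 * 8, 0.2, 0.8), 30, 8)
  ms2 <- make_ms(pos, meth2, cov = 100L)
  cand1 <- cand[1, ]
  sam2 <- sam_moderated_test(ms2, cand1, grp, n_perm = 20, s0 = 0)
  means <- candidate_sample_means(ms2, cand1)
  tt <- t.test(means[1, grp$smoking], means[1, grp$non_smoking],
               var.equal = TRUE)
  expect_equal(sam2$d[1], unname(tt$statistic), tolerance = 1e-10)
  ## exact permutation p matches exhaustive enumeration (3 vs 3)
  ms3 <- make_ms(pos, meth2[, 1:6], cov = 100L,
                 exposure = rep(c("smoking", "non_smoking"), each = 3))
  grp3 <- exposure_groups(ms3$samples)
  sam3 <- sam_moderated_test(ms3, cand, grp3, exact = TRUE)
  means3 <- candidate_sample_means(ms3, cand)
  s0 <- sam3$s0
  dfun <- function(i1, i2, row) {
    m1 <- mean(means3[row, i1]); m2 <- mean(means3[row, i2])
    sp <- sqrt(((2) * var(means3[row, i1]) + (2) * var(means3[row, i2])) /
                 4) * sqrt(2 / 3)
    (m1 - m2) / (sp + s0)
  }
  combos <- combn(6, 3)
  null <- abs(unlist(lapply(seq_len(ncol(combos)), function(k)
    sapply(1:2, function(r) dfun(combos[, k],
                                 setdiff(1:6, combos[, k]), r)))))
  p_oracle <- sapply(1:2, function(r)
    (1 + sum(null >= abs(dfun(1:3, 4:6, r)))) / (1 + length(null)))
  expect_equal(sam3$p_sam, p_oracle, tolerance = 1e-12)
  expect_error(sam_moderated_test(ms2, cand, grp, n_perm = 5), ">= 20")
})

test_that("delta filter requires both raw and smoothed differences", {
  cand <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                     end = c(50, 150, 250), n_cpgs = 5,
                     idx_start = 1, idx_end = 5, stat_mean = 1,
                     delta_raw = c(0.15, 0.12, 0.3),
                     delta_smooth = c(0.08, 0.11, -0.3))
  out <- filter_dmrs(cand, p_sam = c(0.05, 0.05, 0.05))
  expect_equal(nrow(out), 2L)       # first candidate fails the smoothed delta
  expect_true(all(out$direction == "hyper"))
  out2 <- filter_dmrs(cand, p_sam = c(0.05, 0.05, 0.5))
  expect_equal(nrow(out2), 1L)      # p filter removes the third
  ## monotone in the cutoff
  counts <- sapply(seq(0.05, 0.15, by = 0.01), function(th)
    nrow(filter_dmrs(cand, p_sam = rep(0.01, 3), delta_cutoff = th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("direction disagreement between raw and smoothed is retained consistently", {
  cand <- data.frame(chrom = "chr1", start = 0, end = 100, n_cpgs = 5,
                     idx_start = 1, idx_end = 5, stat_mean = -1,
                     delta_raw = -0.2, delta_smooth = -0.15)
  out <- filter_dmrs(cand, p_sam = 0.01)
  expect_equal(out$direction, "hypo")
})

test_that("caller recovers planted DMRs on the shared simulation", {
  sim <- small_sim()
  calls <- call_dmrs(sim$methylomes$t0)
  tr <- sim$truth$dmrs
  exp_tr <- tr[tr$class == "exposure", ]
  sens <- mean(overlaps_any(exp_tr, calls$dmrs))
  expect_gte(sens, 0.9)
  fdr <- if (nrow(calls$dmrs)) mean(!overlaps_any(calls$dmrs, tr)) else 0
  expect_lte(fdr, 0.15)
  ## deterministic given the seed
  set.seed(99); c1 <- call_dmrs(sim$methylomes$t0, smoothed = calls$smoothed)
  set.seed(99); c2 <- call_dmrs(sim$methylomes$t0, smoothed = calls$smoothed)
  expect_identical(c1$dmrs, c2$dmrs)
})

test_that("FDR scan is consistent with direct filtering and reports NA at empty thresholds", {
  sim <- small_sim()
  ms <- subset_methylome(sim$methylomes$t0,
                         sites = sim$methylomes$t0$sites$chrom == "chr1")
  sm <- smooth_methylome(ms)
  set.seed(5)
  scan <- permutation_fdr_scan(ms, thresholds = c(0.1, 0.9),
                               n_perm = 20, sam_perm = 30, smoothed = sm)
  expect_true(all(diff(scan$n_dmrs) <= 0))  # counts non-increasing
  grp <- exposure_groups(ms$samples)
  cand <- candidate_dmrs(ms, sm, grp)
  sam <- sam_moderated_test(ms, cand, grp, n_perm = 30)
  expect_equal(scan$n_dmrs[1], nrow(filter_dmrs(cand, sam$p_sam, 0.1)))
  expect_true(is.na(scan$median_fdr[2]))    # nothing observed at 0.9
})

test_that("lineage-marker screen reports promoter deltas", {
  pos <- seq(0, by = 50, length.out = 120)
  meth <- matrix(0.4, 120, 8)
  meth[21:40, 1:4] <- 0.45  # 5% shift at marker 2 in the smoking group
  ms <- make_ms(pos, meth, cov = 200L)
  markers <- data.frame(chrom = "chr1",
                        start = c(0, 1000, 2000), end = c(999, 1999, 2999),
                        name = c("m1", "m2", "m3"))
  scr <- lineage_marker_screen(ms, markers)
  expect_equal(scr$delta[1], 0, tolerance = 1e-12)
  expect_equal(scr$delta[2], 0.05, tolerance = 0.005)
  expect_true(all(abs(scr$delta) < 0.1))  # below the DMR cutoff
  markers2 <- rbind(markers,
                    data.frame(chrom = "chr2", start = 0, end = 100,
                               name = "m4"))
  expect_warning(scr2 <- lineage_marker_screen(ms, markers2),
                 "no covered")
  expect_true(is.na(scr2$delta[4]))
})
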