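test_that("the canonical state table enumerates all 16 mark combinations", {
  tab <- chromatin_state_table()
  expect_equal(nrow(tab), 16L)
  pat <- as.matrix(tab[, chromatin_marks()])
  expect_equal(nrow(unique(pat)), 16L)  # all combinations, no repeats
  expect_equal(as.vector(table(factor(tab$meta,
                                      c("void", "active", "bivalent",
                                        "repressed", "amplification")))),
               c(1L, 3L, 8L, 3L, 1L))
  expect_equal(tab$label[1], "Void")
  expect_equal(tab$label[16], "Amplification")
  expect_true(all(tab$state[tab$meta == "active"] %in% 1:3))
  expect_true(all(tab$state[tab$meta == "repressed"] %in% 12:14))
  expect_error(meta_states(99L), "unmapped")
})

test_that("posterior decoding equals the brute-force forward-backward oracle", {
  set.seed(71)
  S <- 5
  E <- matrix(runif(S * 4, 0.05, 0.95), S, 4)
  A <- matrix(runif(S * S), S, S); A <- A / rowSums(A)
  pi <- rep(1 / S, S)
  obs <- matrix(rbinom(50 * 4, 1, 0.4), 50, 4)
  storage.mode(obs) <- "integer"
  got <- envmeth:::posterior_cpp(obs, E, A, pi)
  want <- fb_oracle(obs, E, A, pi)
  expect_equal(got$posterior, want, tolerance = 1e-10, ignore_attr = TRUE)
  ## decoding through the model object uses the same posterior argmax
  hmm <- structure(list(emission = E, transition = A, initial = pi,
                        mark_names = chromatin_marks(), n_states = S),
                   class = "ChromatinHmm")
  bins <- data.frame(chrom = "chr1", start = seq(0, by = 200,
                                                 length.out = 50),
                     end = seq(200, by = 200, length.out = 50))
  seg <- segment_track(hmm, obs, bins)
  expect_equal(seg, max.col(want, ties.method = "first") - 1L)
  ## viterbi agrees on this clean model's strongly identified bins
  segv <- segment_track(hmm, obs, bins, method = "viterbi")
  expect_equal(length(segv), 50L)
  expect_error(segment_track(hmm, obs[, 1:3], bins), "mark count")
})

test_that("Baum-Welch log-likelihood is monotone and recovers planted emissions", {
  cfg <- sim_config(genome = c(chr1 = 6e5), n_exposure_dmrs = 4,
                    n_genotype_dmrs = 0, n_cpg_destroying_snps = 0,
                    n_null_snps = 0, timepoints = 0L, p_on = 0.95,
                    p_off = 0.02, n_enhancer_gene_pairs = 4, seed = 17L)
  meth <- simulate_methylomes(cfg)
  chrom <- simulate_chromatin(cfg, meth$truth)
  set.seed(73)
  hmm <- train_hmm(chrom$tracks, chrom$bins, max_iter = 60)
  expect_true(all(diff(hmm$loglik) >= -1e-6))  # EM property
  ## decoding accuracy against the planted consensus
  seg <- segment_track(hmm, chrom$tracks$smk01, chrom$bins)
  acc <- mean(seg == chrom$consensus$smoking)
  expect_gte(acc, 0.9)
  ## canonical relabelling: emission of the Void state is near zero, the
  ## Amplification state near one for every mark
  expect_lt(max(hmm$emission[1, ]), 0.2)
  expect_error(train_hmm(chrom$tracks[1], chrom$bins[1:30, ]),
               "fewer bins")
})

test_that("group consensus follows the two-sample support rule", {
  expect_equal(merge_group(matrix(c(5, 5, 0), 1)), 5L)
  expect_equal(merge_group(matrix(c(5, 7, 0), 1)), 0L)
  expect_equal(merge_group(matrix(c(5, 5, 7, 7), 1)), 5L)  # tie -> lower
  expect_equal(merge_group(matrix(c(0, 0, 5), 1)), 0L)
  expect_error(merge_group(matrix(5, 1, 1)), "min_samples")
})

test_that("TSS association chains through abutting and nearby elements", {
  ## chain: e1 overlaps the TSS, e2 abuts e1, e3 is 300 bp from e2; e4 is
  ## further out and only near the flank-added e3, so the chain stops
  el <- data.frame(chrom = "chr1",
                   start = c(1000, 1200, 1700, 2301),
                   end = c(1200, 1400, 2200, 2400),
                   state = 2L)
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 1100,
                      end = 5000, tss = 1100)
  assoc <- annotate_tss(el, genes)
  expect_equal(assoc, c(TRUE, TRUE, TRUE, FALSE))
  ## a gap of exactly 400 bp from a direct neighbour is associated, 401 not
  el2 <- data.frame(chrom = "chr1",
                    start = c(1000, 1200, 1800),
                    end = c(1200, 1400, 1900), state = 2L)
  expect_true(annotate_tss(el2, genes)[3])
  el2$start[3] <- 1801; el2$end[3] <- 1901
  expect_false(annotate_tss(el2, genes)[3])
})

test_that("element categories split active states by TSS association", {
  el <- data.frame(chrom = "chr1",
                   start = c(0, 5000, 9000, 12000),
                   end = c(200, 5200, 9200, 12200),
                   state = c(2L, 13L, 5L, 2L))
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 100,
                      end = 3000, tss = 100)
  cl <- classify_elements(el, genes)
  expect_equal(cl$category, c("promoter", "repressed", "bivalent",
                              "enhancer"))
})

test_that("transition summaries count changed chromatin and its direction", {
  bins <- data.frame(chrom = "chr1", start = seq(0, by = 200,
                                                 length.out = 100),
                     end = seq(200, by = 200, length.out = 100))
  same <- rep(0L, 100)
  tsum <- chromatin_transitions(same, same, bins)
  expect_equal(tsum$n_changed_bins, 0L)
  expect_true(all(is.na(tsum$fractions)))
  ## 20 changed bins: 12 to active (state 1), 6 to repressed (12),
  ## 2 to bivalent (4)
  smk <- same
  smk[1:12] <- 1L; smk[21:26] <- 12L; smk[31:32] <- 4L
  tsum2 <- chromatin_transitions(same, smk, bins)
  expect_equal(tsum2$n_changed_bins, 20L)
  expect_equal(unname(tsum2$fractions["active"]), 0.6)
  expect_equal(unname(tsum2$fractions["repressed"]), 0.3)
  expect_equal(sum(tsum2$fractions), 1)
  expect_equal(tsum2$p_asymmetry,
               binom.test(12, 18, 0.5)$p.value)
  ## mask restriction and enrichment fold
  mask <- data.frame(chrom = "chr1", start = 0, end = 200 * 40)
  tsum3 <- chromatin_transitions(same, smk, bins, masks = list(m = mask))
  expect_equal(tsum3$masked$m$n_changed_bins, 20L)
  expect_equal(tsum3$masked$m$fold_change, (20 / 40) / (20 / 100))
  expect_error(chromatin_transitions(same, smk[1:50], bins), "mismatch")
})

test_that("planted transition bias and DMR enrichment are recovered", {
  sim <- small_sim()
  chrom <- sim$chromatin
  tr <- sim$truth$dmrs[sim$truth$dmrs$class == "exposure", ]
  tsum <- chromatin_transitions(chrom$consensus$non_smoking,
                                chrom$consensus$smoking, chrom$bins,
                                masks = list(dmr = tr))
  fa <- tsum$fractions["active"]; fr <- tsum$fractions["repressed"]
  expect_gt(fa / fr, 1.2)  # 2:1 bias planted
  expect_lt(fa / fr, 3.5)
  expect_gt(tsum$masked$dmr$fold_change, 1.5)
  ## label-swap permutation: planted transitions are significant
  tab <- chromatin_state_table()
  P <- as.matrix(tab[, chromatin_marks()])
  seg <- sapply(names(chrom$tracks), function(s) {
    pat <- chrom$tracks[[s]]
    ## noisy per-sample decode by nearest mark pattern (cheap stand-in
    ## for a trained model in this permutation check)
    d <- sapply(seq_len(16), function(k)
      rowSums(abs(pat - matrix(P[k, ], nrow(pat), 4, byrow = TRUE))))
    tab$state[max.col(-d, ties.method = "first")]
  })
  set.seed(77)
  pt <- transition_permutation_test(seg, chrom$groups, n_perm = 20)
  expect_lte(pt$p, 0.2)
  expect_gte(pt$observed, 0)
})
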