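## Synthetic-data generator: complete inputs with the statistical structure
## the analysis assumes -- beta-binomial WGBS counts for an 8-vs-8 design
## with planted exposure DMRs and genotype-linked DMRs (including
## CpG-destroying SNPs), longitudinal shrinkage of exposure effects,
## four-mark chromatin tracks with planted group state transitions, and
## expression coupled to enhancer methylation.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: two groups of 8 individuals,
#' 30x mean CpG coverage, 50 exposure DMRs with a raw methylation shift of
#' 0.2 and 30 meQTL-driven DMRs on a 20-Mb two-chromosome toy genome,
#' timepoints at 0, 1 and 4 years with a small per-year shrinkage of the
#' exposure effect, 200-bp chromatin bins with Bernoulli mark emissions,
#' and enhancer-expression coupling with target Spearman magnitude 0.6.
#'
#' @param n_per_group individuals per exposure group.
#' @param genome named vector of chromosome lengths (bp).
#' @param cpg_density expected CpGs per kb.
#' @param mean_coverage mean reads per CpG.
#' @param coverage_dispersion negative-binomial overdispersion of coverage
#'   (variance = mu + disp * mu^2).
#' @param baseline_meth_profile list with `weights` and `means` for the
#'   low/intermediate/high methylation strata.
#' @param bb_dispersion beta-binomial dispersion of methylation counts.
#' @param n_exposure_dmrs,exposure_effect planted environment-associated
#'   DMRs and their raw group methylation difference.
#' @param n_genotype_dmrs,meqtl_slope planted genotype-driven DMRs and the
#'   methylation shift per alternative allele.
#' @param maf meQTL allele frequency (Hardy-Weinberg dosages).
#' @param n_cpg_destroying_snps CpG-destroying SNPs planted at CpGs inside
#'   genotype DMRs (methylation 0 for homozygous alt carriers, 0.5 for
#'   heterozygous).
#' @param n_null_snps effect-free SNPs scattered on the genome.
#' @param timepoints years at which methylomes are generated.
#' @param stability_decay absolute shrinkage of the exposure delta per year.
#' @param dmr_width planted DMR width (bp); every planted DMR carries at
#'   least 11 CpGs and spans at least 1 kb.
#' @param n_states_planted number of distinct chromatin states used in the
#'   planted consensus (<= 16).
#' @param transition_fraction fraction of bins whose consensus state
#'   differs between groups.
#' @param dmr_transition_fold density of changed bins inside exposure DMRs
#'   relative to the genome-wide rate.
#' @param active_bias ratio of active to repressed destinations among
#'   changed bins.
#' @param p_on,p_off per-sample mark emission probabilities given state.
#' @param bin_size chromatin bin width (bp).
#' @param n_chromatin_per_group samples per group with chromatin tracks.
#' @param n_enhancer_gene_pairs planted enhancer/repressed-element to gene
#'   interactions.
#' @param expr_coupling_rho target absolute correlation of planted pairs.
#' @param seed RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 8L,
                       genome = c(chr1 = 12e6, chr2 = 8e6),
                       cpg_density = 8,
                       mean_coverage = 30,
                       coverage_dispersion = 0.05,
                       baseline_meth_profile = list(
                         weights = c(low = 0.15, mid = 0.10, high = 0.75),
                         means = c(low = 0.08, mid = 0.50, high = 0.85)),
                       bb_dispersion = 0.02,
                       n_exposure_dmrs = 50L,
                       exposure_effect = 0.2,
                       n_genotype_dmrs = 30L,
                       meqtl_slope = 0.2,
                       maf = 0.3,
                       n_cpg_destroying_snps = 10L,
                       n_null_snps = 200L,
                       timepoints = c(0L, 1L, 4L),
                       stability_decay = 0.02,
                       dmr_width = 1500L,
                       n_states_planted = 16L,
                       transition_fraction = 0.05,
                       dmr_transition_fold = 3,
                       active_bias = 2,
                       p_on = 0.9, p_off = 0.05,
                       bin_size = 200L,
                       n_chromatin_per_group = 3L,
                       n_enhancer_gene_pairs = 100L,
                       expr_coupling_rho = 0.6,
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(exposure_effect = exposure_effect, maf = maf,
          transition_fraction = transition_fraction, p_on = p_on,
          p_off = p_off, expr_coupling_rho = expr_coupling_rho,
          stability_decay = stability_decay,
          bb_dispersion = bb_dispersion)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (n_states_planted > 16L) stop("n_states_planted must be <= 16")
  if (is.null(names(genome))) stop("genome must be named")
  structure(cfg, class = "sim_config")
}

## small deterministic per-stage seed derivation (kept below 2^31)
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 1103L + stage * 7919L) %% 2147483647
}

rbetabinom <- function(n_reads, p, rho) {
  m <- integer(length(n_reads))
  interior <- p > 0 & p < 1 & n_reads > 0
  if (any(interior)) {
    nu <- 1 / rho - 1
    q <- stats::rbeta(sum(interior), p[interior] * nu,
                      (1 - p[interior]) * nu)
    m[interior] <- stats::rbinom(sum(interior), n_reads[interior], q)
  }
  m[p >= 1 & n_reads > 0] <- n_reads[p >= 1 & n_reads > 0]
  m
}

## non-overlapping placement of nr intervals of width w, with margin
place_regions <- function(genome, nr, w, margin = 5000, max_tries = 10000L) {
  if (nr == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  chroms <- names(genome)
  gl <- as.numeric(genome)
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  tries <- 0L
  while (nrow(placed) < nr) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("genome too small to place requested regions without overlap")
    ci <- sample(length(chroms), 1L, prob = gl)
    if (gl[ci] < w + 2 * margin) next
    s <- floor(stats::runif(1, margin, gl[ci] - w - margin))
    clash <- placed$chrom == chroms[ci] &
      placed$start < s + w + margin & placed$end > s - margin
    if (any(clash)) next
    placed <- rbind(placed, data.frame(chrom = chroms[ci], start = s,
                                       end = s + w))
  }
  placed$start <- as.integer(placed$start)
  placed$end <- as.integer(placed$end)
  placed[order(placed$chrom, placed$start), , drop = FALSE]
}

#' Simulate WGBS methylomes, genotypes and planted truth
#'
#' Counts are beta-binomial around per-site latent methylation. Exposure
#' DMRs shift the latent level in the smoking group only (half hyper, half
#' hypo; groups sit symmetrically around 0.5 so the planted raw difference
#' equals `exposure_effect`); genotype DMRs shift all carriers by
#' `meqtl_slope` per alternative allele with Hardy-Weinberg dosages;
#' CpG-destroying SNPs force the latent methylation of their CpG to 0
#' (homozygous alt) or 0.5 (heterozygous) in carriers. Later timepoints
#' shrink the planted exposure delta by `stability_decay` per year;
#' genotype effects persist. Deterministic under the config seed.
#'
#' @param cfg [sim_config()].
#' @return list: `methylomes` (named list of MethylomeSet per timepoint),
#'   `genotypes` (GenotypeTable, columns per individual), `truth`
#'   (planted DMR table, CpG-destroying SNP table, site annotations).
#' @export
simulate_methylomes <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  prof <- cfg$baseline_meth_profile
  n_exp <- cfg$n_exposure_dmrs
  n_gen <- cfg$n_genotype_dmrs
  regions <- place_regions(cfg$genome, n_exp + n_gen, cfg$dmr_width)
  regions <- regions[sample(nrow(regions)), , drop = FALSE]
  cls <- c(rep("exposure", n_exp), rep("genotype", n_gen))
  sgn <- c(rep(c(1, -1), length.out = n_exp), rep(1, n_gen))
  ## CpG sites: background positions outside planted regions, plus a
  ## guaranteed ladder of CpGs inside every planted DMR
  n_cpg_dmr <- max(15L, ceiling(cfg$dmr_width * cfg$cpg_density / 1000) + 3L)
  sites <- list()
  for (ch in names(cfg$genome)) {
    nbg <- round(cfg$genome[[ch]] / 1000 * cfg$cpg_density)
    pos <- sort(sample.int(cfg$genome[[ch]] - 2L, nbg))
    rr <- regions[regions$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(rr)))
      pos <- pos[pos < rr$start[k] | pos >= rr$end[k]]
    sites[[ch]] <- data.frame(chrom = ch, pos = pos, region = NA_integer_)
  }
  ridx <- order(regions$chrom, regions$start)  # map back after sorting
  for (k in seq_len(nrow(regions))) {
    p <- unique(as.integer(round(seq(regions$start[k] + 10,
                                     regions$end[k] - 10,
                                     length.out = n_cpg_dmr) +
                                   stats::runif(n_cpg_dmr, -5, 5))))
    sites[[regions$chrom[k]]] <- rbind(
      sites[[regions$chrom[k]]],
      data.frame(chrom = regions$chrom[k], pos = p, region = k))
  }
  sites <- do.call(rbind, sites)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
  rownames(sites) <- NULL
  ns <- nrow(sites)
  ## baseline latent methylation
  stratum <- sample(names(prof$weights), ns, replace = TRUE,
                    prob = prof$weights)
  base <- pmin(pmax(prof$means[stratum] +
                      stats::rnorm(ns, 0, 0.03), 0.02), 0.98)
  in_reg <- sites$region
  for (k in which(cls == "exposure"))
    base[which(in_reg == k)] <- 0.5 - sgn[k] * cfg$exposure_effect / 2
  for (k in which(cls == "genotype"))
    base[which(in_reg == k)] <- 0.25
  ## individuals and genotypes
  n_ind <- 2L * cfg$n_per_group
  ind_ids <- sprintf("I%02d", seq_len(n_ind))
  exposure <- rep(c("smoking", "non_smoking"), each = cfg$n_per_group)
  gen_k <- which(cls == "genotype")
  snp_rows <- list(); dos_rows <- list()
  dmr_snp <- rep(NA_character_, nrow(regions))
  for (j in seq_along(gen_k)) {
    k <- gen_k[j]
    id <- sprintf("meqtl%03d", j)
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      snp_id = id, chrom = regions$chrom[k],
      pos = as.integer((regions$start[k] + regions$end[k]) / 2),
      ref = "A", alt = "G", cpg_destroying = FALSE, effect = "meqtl",
      region = k)
    dos_rows[[length(dos_rows) + 1L]] <- stats::rbinom(n_ind, 2L, cfg$maf)
    dmr_snp[k] <- id
  }
  ## CpG-destroying SNPs at a fully methylated CpG inside genotype DMRs
  destroy_site <- integer(0)
  if (cfg$n_cpg_destroying_snps > 0L && length(gen_k)) {
    host <- rep(gen_k, length.out = cfg$n_cpg_destroying_snps)
    for (j in seq_len(cfg$n_cpg_destroying_snps)) {
      k <- host[j]
      cand <- which(in_reg == k)
      si <- cand[1L + (j %% length(cand))]
      destroy_site <- c(destroy_site, si)
      base[si] <- 0.95  # near-fully methylated when intact
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        snp_id = sprintf("cgd%03d", j), chrom = sites$chrom[si],
        pos = sites$pos[si], ref = "C", alt = "A",
        cpg_destroying = TRUE, effect = "cpg_destroying", region = k)
      dos_rows[[length(dos_rows) + 1L]] <- stats::rbinom(n_ind, 2L,
                                                         cfg$maf)
    }
  }
  if (cfg$n_null_snps > 0L) {
    for (j in seq_len(cfg$n_null_snps)) {
      ch <- sample(names(cfg$genome), 1L, prob = as.numeric(cfg$genome))
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        snp_id = sprintf("null%04d", j), chrom = ch,
        pos = sample.int(cfg$genome[[ch]] - 2L, 1L),
        ref = "T", alt = "C", cpg_destroying = FALSE, effect = "none",
        region = NA_integer_)
      dos_rows[[length(dos_rows) + 1L]] <- stats::rbinom(n_ind, 2L,
                                                         cfg$maf)
    }
  }
  if (length(snp_rows)) {
    snps <- do.call(rbind, snp_rows)
    dosage <- do.call(rbind, dos_rows)
  } else {
    snps <- data.frame(snp_id = character(), chrom = character(),
                       pos = integer(), ref = character(),
                       alt = character(), cpg_destroying = logical(),
                       effect = character(), region = integer())
    dosage <- matrix(integer(), 0L, n_ind)
  }
  colnames(dosage) <- ind_ids
  gt <- GenotypeTable(snps[, c("snp_id", "chrom", "pos", "ref", "alt",
                               "cpg_destroying")], dosage)
  gt$snps$effect <- snps$effect
  ## per-individual latent methylation at timepoint t
  latent_at <- function(t) {
    lat <- matrix(rep(base, n_ind), ns, n_ind)
    eff_t <- max(cfg$exposure_effect - cfg$stability_decay * t, 0)
    for (k in which(cls == "exposure")) {
      ii <- which(in_reg == k)
      smk <- which(exposure == "smoking")
      lat[ii, smk] <- base[ii] + sgn[k] * eff_t
    }
    for (j in seq_along(gen_k)) {
      k <- gen_k[j]
      ii <- which(in_reg == k)
      d <- dosage[j, ]
      lat[ii, ] <- base[ii] + rep(cfg$meqtl_slope * d, each = length(ii))
    }
    ## CpG-destroying overrides (applied after meQTL shifts)
    dj <- which(gt$snps$cpg_destroying)
    for (m in seq_along(destroy_site)) {
      si <- destroy_site[m]
      d <- dosage[dj[m], ]
      lat[si, d == 1L] <- 0.5
      lat[si, d == 2L] <- 0
    }
    pmin(pmax(lat, 0), 1)
  }
  methylomes <- list()
  for (t in cfg$timepoints) {
    lat <- latent_at(t)
    N <- matrix(stats::rnbinom(ns * n_ind, mu = cfg$mean_coverage,
                               size = 1 / cfg$coverage_dispersion),
                ns, n_ind)
    M <- matrix(rbetabinom(as.vector(N), as.vector(lat),
                           cfg$bb_dispersion), ns, n_ind)
    meta <- data.frame(
      sample_id = sprintf("%s_t%d", ind_ids, t),
      individual_id = ind_ids, role = "child", exposure = exposure,
      timepoint_years = t, stringsAsFactors = FALSE)
    methylomes[[paste0("t", t)]] <-
      MethylomeSet(sites[, c("chrom", "pos")], M, N - M, meta)
  }
  truth_dmrs <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    class = cls, sign = sgn,
    delta = ifelse(cls == "exposure", cfg$exposure_effect * sgn, 0),
    snp_id = dmr_snp,
    n_cpgs = vapply(seq_len(nrow(regions)), function(k)
      sum(in_reg == k, na.rm = TRUE), 1L))
  stopifnot(all(truth_dmrs$n_cpgs >= 11L),
            all(truth_dmrs$end - truth_dmrs$start >= 1000L))
  truth <- list(
    dmrs = truth_dmrs[order(truth_dmrs$chrom, truth_dmrs$start), ],
    cpg_destroying = gt$snps[gt$snps$cpg_destroying, , drop = FALSE],
    destroy_sites = data.frame(chrom = sites$chrom[destroy_site],
                               pos = sites$pos[destroy_site],
                               snp_id = gt$snps$snp_id[
                                 gt$snps$cpg_destroying]),
    site_region = sites$region,
    exposure = exposure, individuals = ind_ids)
  list(methylomes = methylomes, genotypes = gt, truth = truth)
}

#' Simulate binarized chromatin tracks with planted group transitions
#'
#' Each group has a consensus state path over fixed-width bins: a random
#' background (mostly Void with short non-void elements), overlaid with
#' planted elements on the exposure DMRs (active states on
#' enhancer-coupled DMRs, repressed states on repressed-coupled ones). The
#' smoking consensus differs from the non-smoking one at a
#' `transition_fraction` of bins, placed inside exposure DMRs at
#' `dmr_transition_fold` times the genomic rate, with destinations biased
#' `active_bias`:1 toward active over repressed. Per-sample tracks emit
#' each mark Bernoulli(`p_on`) when the state carries the mark and
#' Bernoulli(`p_off`) otherwise.
#'
#' @param cfg [sim_config()].
#' @param truth truth list from [simulate_methylomes()] (may be `NULL` for
#'   a background-only simulation).
#' @return list: `bins`, `consensus` (non_smoking / smoking state
#'   vectors), `tracks` (named list of per-sample binary matrices with a
#'   `group` attribute), `groups` (sample indices), `coupling` (per
#'   exposure DMR: enhancer or repressed).
#' @export
simulate_chromatin <- function(cfg, truth = NULL) {
  set.seed(derive_seed(cfg$seed, 2L))
  if (cfg$n_states_planted > 16L) stop("n_states_planted must be <= 16")
  bins <- genome_bins(cfg$genome, cfg$bin_size)
  nb <- nrow(bins)
  tab <- chromatin_state_table()
  usable <- tab$state[seq_len(cfg$n_states_planted)]
  ## background: mostly void, short non-void elements
  cons <- integer(nb)
  b <- 1L
  while (b <= nb) {
    len <- 1L + stats::rgeom(1, 1 / 8)
    st <- if (stats::runif(1) < 0.85 || length(usable) == 1L) 0L
    else sample(setdiff(usable, 0L), 1L)
    cons[b:min(b + len - 1L, nb)] <- st
    b <- b + len
  }
  coupling <- NULL
  if (!is.null(truth)) {
    exp_dmrs <- truth$dmrs[truth$dmrs$class == "exposure", , drop = FALSE]
    if (nrow(exp_dmrs)) {
      coupling <- rep(c("enhancer", "repressed"),
                      length.out = nrow(exp_dmrs))
      active_states <- tab$state[tab$meta == "active"]
      repressed_states <- tab$state[tab$meta == "repressed"]
      for (k in seq_len(nrow(exp_dmrs))) {
        ii <- which(bins$chrom == exp_dmrs$chrom[k] &
                      bins$end > exp_dmrs$start[k] &
                      bins$start < exp_dmrs$end[k])
        cons[ii] <- if (coupling[k] == "enhancer")
          max(active_states) else min(repressed_states)
      }
    }
  }
  cons_ns <- cons
  cons_smk <- cons
  ## planted transitions: higher density inside exposure DMRs
  in_dmr <- rep(FALSE, nb)
  if (!is.null(truth)) {
    exp_dmrs <- truth$dmrs[truth$dmrs$class == "exposure", , drop = FALSE]
    if (nrow(exp_dmrs))
      in_dmr <- overlaps_any(bins, exp_dmrs)
  }
  a <- mean(in_dmr)
  rate_out <- cfg$transition_fraction /
    (1 + a * (cfg$dmr_transition_fold - 1))
  rate_in <- min(1, cfg$dmr_transition_fold * rate_out)
  change <- stats::runif(nb) < ifelse(in_dmr, rate_in, rate_out)
  metas_dest <- c("active", "repressed", "bivalent")
  wts <- c(cfg$active_bias, 1, 1)
  for (i in which(change)) {
    dest <- sample(metas_dest, 1L, prob = wts)
    cand <- setdiff(intersect(tab$state[tab$meta == dest], usable),
                    cons_ns[i])
    if (!length(cand)) next
    cons_smk[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  emit <- function(states) {
    pat <- as.matrix(tab[match(states, tab$state), chromatin_marks()])
    pr <- ifelse(pat == 1, cfg$p_on, cfg$p_off)
    m <- matrix(stats::rbinom(length(pr), 1L, as.vector(pr)), nrow(pr))
    colnames(m) <- chromatin_marks()
    m
  }
  npg <- cfg$n_chromatin_per_group
  tracks <- list()
  for (i in seq_len(npg))
    tracks[[sprintf("smk%02d", i)]] <- emit(cons_smk)
  for (i in seq_len(npg))
    tracks[[sprintf("ns%02d", i)]] <- emit(cons_ns)
  list(bins = bins,
       consensus = list(non_smoking = cons_ns, smoking = cons_smk),
       tracks = tracks,
       groups = list(smoking = seq_len(npg),
                     non_smoking = npg + seq_len(npg)),
       coupling = coupling)
}

#' Simulate expression coupled to planted element methylation
#'
#' Genes linked to planted enhancer-coupled DMRs get expression negatively
#' coupled to the element's realized per-sample mean methylation;
#' repressed-element targets are coupled positively; the coupling strength
#' targets a population correlation of magnitude `expr_coupling_rho`.
#' Unlinked genes are independent noise.
#'
#' @param cfg [sim_config()].
#' @param truth truth list from [simulate_methylomes()].
#' @param ms MethylomeSet supplying realized methylation (timepoint 0).
#' @param coupling per-exposure-DMR coupling labels (from
#'   [simulate_chromatin()]); defaults to alternating enhancer/repressed.
#' @return list: `expr` (genes x samples), `genes` (gene table with bodies
#'   and TSS), `interactions` (region-gene pairs), `pair_truth`.
#' @export
simulate_expression <- function(cfg, truth, ms, coupling = NULL) {
  set.seed(derive_seed(cfg$seed, 3L))
  exp_dmrs <- truth$dmrs[truth$dmrs$class == "exposure", , drop = FALSE]
  if (is.null(coupling))
    coupling <- rep(c("enhancer", "repressed"),
                    length.out = nrow(exp_dmrs))
  n_pairs <- cfg$n_enhancer_gene_pairs
  n_noise <- 100L
  n_genes <- n_pairs + n_noise
  gene_w <- as.integer(min(20000, min(cfg$genome) %/% 20))
  chrom_g <- sample(names(cfg$genome), n_genes, replace = TRUE,
                    prob = as.numeric(cfg$genome))
  start_g <- vapply(chrom_g, function(ch)
    floor(stats::runif(1, 0, cfg$genome[[ch]] - gene_w)), 1.0)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      chrom = chrom_g, start = as.integer(start_g),
                      end = as.integer(start_g) + gene_w,
                      tss = as.integer(start_g),
                      stringsAsFactors = FALSE)
  sample_ids <- ms$samples$sample_id
  nsamp <- length(sample_ids)
  expr <- matrix(stats::rnorm(nrow(genes) * nsamp, 10, 1),
                 nrow(genes), nsamp,
                 dimnames = list(genes$gene_id, sample_ids))
  rho <- cfg$expr_coupling_rho
  pair_rows <- list()
  for (j in seq_len(n_pairs)) {
    k <- 1L + (j - 1L) %% nrow(exp_dmrs)
    g <- j  # first n_pairs genes are linked
    m <- region_mean_meth(ms, exp_dmrs$chrom[k], exp_dmrs$start[k],
                          exp_dmrs$end[k])
    if (all(is.na(m)) || stats::sd(m, na.rm = TRUE) == 0) next
    z <- (m - mean(m, na.rm = TRUE)) / stats::sd(m, na.rm = TRUE)
    z[is.na(z)] <- 0
    s <- if (coupling[k] == "enhancer") -1 else 1
    noise_sd <- if (rho > 0) sqrt(1 / rho^2 - 1) else Inf
    expr[g, ] <- 10 + if (rho > 0)
      s * z + stats::rnorm(nsamp, 0, noise_sd) else stats::rnorm(nsamp)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      chrom = exp_dmrs$chrom[k], start = exp_dmrs$start[k],
      end = exp_dmrs$end[k], gene_id = genes$gene_id[g],
      coupling = coupling[k], stringsAsFactors = FALSE)
  }
  pair_truth <- do.call(rbind, pair_rows)
  interactions <- pair_truth[, c("chrom", "start", "end", "gene_id")]
  interactions <- interactions[order(interactions$chrom,
                                     interactions$start), , drop = FALSE]
  rownames(interactions) <- NULL
  list(expr = expr, genes = genes[order(genes$chrom, genes$start), ],
       interactions = interactions, pair_truth = pair_truth)
}

#' Simulate a complete dataset
#'
#' Runs the methylome/genotype, chromatin and expression generators with
#' per-stage seeds derived from the config seed, so the full dataset is
#' reproducible and individual stages can be regenerated independently.
#'
#' @param cfg [sim_config()].
#' @return list of class `sim_data`: methylomes, genotypes, chromatin,
#'   expression, genes, interactions, truth.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  meth <- simulate_methylomes(cfg)
  chrom <- simulate_chromatin(cfg, meth$truth)
  t0 <- meth$methylomes[[1L]]
  ex <- simulate_expression(cfg, meth$truth, t0, chrom$coupling)
  truth <- meth$truth
  truth$consensus <- chrom$consensus
  truth$coupling <- chrom$coupling
  truth$pairs <- ex$pair_truth
  structure(list(config = cfg,
                 methylomes = meth$methylomes,
                 genotypes = meth$genotypes,
                 chromatin = chrom,
                 expression = ex$expr,
                 genes = ex$genes,
                 interactions = ex$interactions,
                 truth = truth),
            class = "sim_data")
}

#' @method print sim_data
#' @export
print.sim_data <- function(x, ...) {
  cat("Synthetic dataset:", sum(x$config$genome) / 1e6, "Mb genome,",
      nrow(x$methylomes[[1]]$sites), "CpGs,",
      2 * x$config$n_per_group, "individuals,",
      length(x$methylomes), "timepoint(s)\n")
  cat("  planted:", sum(x$truth$dmrs$class == "exposure"), "exposure /",
      sum(x$truth$dmrs$class == "genotype"), "genotype DMRs;",
      nrow(x$truth$cpg_destroying), "CpG-destroying SNPs\n")
  invisible(x)
}

#' Write a simulated dataset to standard-format files
#'
#' Coverage files per sample and timepoint, metadata TSV, genotype site
#' table, per-sample per-mark BED tracks of present bins, gene and
#' interaction tables, expression TSV, genome table and a `truth.json`.
#'
#' @param sim [simulate_dataset()] output.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tp in names(sim$methylomes)) {
    write_methylome(sim$methylomes[[tp]], file.path(dir, paste0("meth_", tp)))
    write_sample_meta(sim$methylomes[[tp]]$samples,
                      file.path(dir, paste0("meta_", tp, ".tsv")))
  }
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  utils::write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$interactions, file.path(dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(names(sim$config$genome), as.integer(sim$config$genome)),
    file.path(dir, "genome.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  trdir <- file.path(dir, "tracks")
  dir.create(trdir, showWarnings = FALSE)
  bins <- sim$chromatin$bins
  for (sid in names(sim$chromatin$tracks)) {
    tr <- sim$chromatin$tracks[[sid]]
    for (m in colnames(tr)) {
      keep <- tr[, m] == 1L
      write_bed(bins[keep, c("chrom", "start", "end")],
                file.path(trdir, paste0(sid, "_", m, ".bed")))
    }
  }
  tr <- sim$truth
  tr$site_region <- NULL  # per-site vector, too large for the manifest
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
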