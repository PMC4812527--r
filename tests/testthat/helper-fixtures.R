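## Shared fixtures, built in code.

## Build a MethylomeSet directly from per-site methylation fractions and a
## constant coverage (counts are exact: M = round(p * cov)).
make_ms <- function(pos, meth, cov = 100L, chrom = "chr1",
                    exposure = NULL, individual = NULL, timepoint = 0L) {
  meth <- as.matrix(meth)
  nsamp <- ncol(meth)
  if (is.null(exposure))
    exposure <- rep(c("smoking", "non_smoking"), each = nsamp / 2)
  if (is.null(individual)) individual <- sprintf("I%02d", seq_len(nsamp))
  M <- round(meth * cov)
  U <- cov - M
  meta <- data.frame(sample_id = sprintf("%s_t%d", individual, timepoint),
                     individual_id = individual, role = "child",
                     exposure = exposure, timepoint_years = timepoint,
                     stringsAsFactors = FALSE)
  MethylomeSet(data.frame(chrom = chrom, pos = as.integer(pos)),
               M, U, meta)
}

## small shared simulated dataset, computed once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome = c(chr1 = 2e6, chr2 = 1e6),
                        n_exposure_dmrs = 12, n_genotype_dmrs = 10,
                        n_cpg_destroying_snps = 4, n_null_snps = 40,
                        timepoints = c(0L, 1L),
                        n_enhancer_gene_pairs = 20, seed = 7L)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

## tricube weight matching the smoother's kernel
tricube <- function(d, denom) (1 - (abs(d) / denom)^3)^3

## independent local weighted least-squares oracle for the smoother:
## quadratic fit on the clamped-logit scale at site i over window radius
## rad, weights coverage * tricube
smooth_oracle <- function(pos, M, U, i, ns, h) {
  d <- abs(pos - pos[i])
  rad <- max(h, sort(d)[ns])
  win <- which(d <= rad)
  p <- pmin(pmax(M[win] / (M[win] + U[win]), 0.005), 0.995)
  y <- log(p / (1 - p))
  x <- (pos[win] - pos[i]) / 1000
  w <- (M[win] + U[win]) * tricube(pos[win] - pos[i], rad + 1)
  fit <- lm(y ~ x + I(x^2), weights = w)
  plogis(unname(predict(fit, newdata = data.frame(x = 0))))
}

## brute-force forward-backward posterior for a Bernoulli-emission HMM
fb_oracle <- function(obs, E, A, pi) {
  S <- nrow(E); Tn <- nrow(obs)
  E <- pmin(pmax(E, 1e-6), 1 - 1e-6)
  B <- sapply(seq_len(S), function(s)
    apply(obs, 1, function(o) prod(E[s, ]^o * (1 - E[s, ])^(1 - o))))
  B <- matrix(B, nrow = Tn)
  alpha <- matrix(0, Tn, S); beta <- matrix(0, Tn, S)
  alpha[1, ] <- pi * B[1, ]
  for (t in 2:Tn) alpha[t, ] <- (alpha[t - 1, ] %*% A) * B[t, ]
  beta[Tn, ] <- 1
  for (t in (Tn - 1):1)
    beta[t, ] <- A %*% (B[t + 1, ] * beta[t + 1, ])
  g <- alpha * beta
  g / rowSums(g)
}
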