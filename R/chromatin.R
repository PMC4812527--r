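## Chromatin segmentation: a 16-state Bernoulli-emission HMM over four
## binarized histone marks (H3K4me1, H3K27ac, H3K27me3, H3K9me3) on a
## 200-bp bin grid, with canonical state labels, per-group consensus and
## smoking vs non-smoking transition analysis.

#' Histone mark names (fixed order)
#' @export
chromatin_marks <- function() c("H3K4me1", "H3K27ac", "H3K27me3", "H3K9me3")

#' Canonical chromatin state table
#'
#' All 16 presence/absence combinations of the four marks, ordered
#' canonically: state 0 is Void (no mark); states 1-3 are the active states
#' (active marks H3K4me1/H3K27ac only); states 4-11 are bivalent (mixing
#' active and repressive marks, excluding the all-marks state); states
#' 12-14 are repressed (repressive marks H3K27me3/H3K9me3 only); state 15,
#' with all four marks, is Amplification.
#'
#' @return data.frame: state, the four mark indicator columns, label,
#'   meta (`void`, `active`, `bivalent`, `repressed`, `amplification`).
#' @export
chromatin_state_table <- function() {
  marks <- chromatin_marks()
  pat <- as.matrix(expand.grid(rep(list(0:1), 4)))[, 4:1]
  colnames(pat) <- marks
  act <- rowSums(pat[, 1:2, drop = FALSE])
  rep_ <- rowSums(pat[, 3:4, drop = FALSE])
  meta <- ifelse(act + rep_ == 0, "void",
          ifelse(act == 2 & rep_ == 2, "amplification",
          ifelse(rep_ == 0, "active",
          ifelse(act == 0, "repressed", "bivalent"))))
  grp_order <- c(void = 0L, active = 1L, bivalent = 2L, repressed = 3L,
                 amplification = 4L)
  key <- pat %*% (2L^(0:3))
  o <- order(grp_order[meta], rowSums(pat), key)
  pat <- pat[o, , drop = FALSE]
  meta <- meta[o]
  lab <- vapply(seq_len(16L), function(i) {
    on <- marks[pat[i, ] == 1]
    if (!length(on)) "Void"
    else if (length(on) == 4L) "Amplification"
    else paste(on, collapse = "+")
  }, "")
  out <- data.frame(state = 0:15, pat, label = lab, meta = meta,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Map state indices to meta-states
#' @param states integer vector of canonical state indices (0-15).
#' @return character vector of meta-states.
#' @export
meta_states <- function(states) {
  tab <- chromatin_state_table()
  if (any(!(states %in% tab$state), na.rm = TRUE))
    stop("unmapped state label")
  tab$meta[match(states, tab$state)]
}

#' Tile a genome into fixed-width bins
#' @param genome named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 200).
#' @return data.frame chrom/start/end (last partial bin dropped).
#' @export
genome_bins <- function(genome, bin_size = 200L) {
  out <- lapply(names(genome), function(ch) {
    n <- genome[[ch]] %/% bin_size
    if (n < 1L) return(NULL)
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * bin_size,
               end = seq_len(n) * bin_size)
  })
  do.call(rbind, out)
}

#' Train the chromatin-state HMM
#'
#' Baum-Welch with independent Bernoulli emissions per mark, run on the
#' concatenated per-sample tracks (each chromosome of each sample is an
#' independent sequence). Convergence when the log-likelihood gain drops
#' below `tol` or after `max_iter` iterations (default 400). Emissions are
#' initialised at the canonical mark patterns (for 16 states) or k-means
#' centroids, plus seeded jitter; after training, states are relabelled
#' canonically by their emission profile so reruns name states identically.
#'
#' @param tracks named list (per sample) of bins x 4 binary matrices, all
#'   on the same bin grid.
#' @param bins bin data.frame from [genome_bins()].
#' @param n_states number of states (default 16).
#' @param max_iter maximum Baum-Welch iterations (default 400).
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param jitter_sd emission initialisation jitter.
#' @return object of class `ChromatinHmm`: emission (state x mark),
#'   transition, initial, mark_names, loglik trace, state_table.
#' @export
train_hmm <- function(tracks, bins, n_states = 16L, max_iter = 400L,
                      tol = 1e-4, jitter_sd = 0.01) {
  nb <- nrow(bins)
  if (nb * length(tracks) < 10L * n_states)
    stop("fewer bins than 10 x n_states")
  seqs <- list()
  for (tr in tracks) {
    stopifnot(nrow(tr) == nb, ncol(tr) == 4L)
    for (ch in unique(bins$chrom)) {
      m <- tr[bins$chrom == ch, , drop = FALSE]
      storage.mode(m) <- "integer"
      seqs[[length(seqs) + 1L]] <- m
    }
  }
  tab <- chromatin_state_table()
  if (n_states == 16L) {
    base <- as.matrix(tab[, chromatin_marks()])
  } else {
    km <- stats::kmeans(do.call(rbind, seqs), centers = n_states,
                        nstart = 3L)
    base <- km$centers
  }
  E0 <- pmin(pmax(base * 0.8 + 0.1 +
                    matrix(abs(stats::rnorm(length(base), 0, jitter_sd)),
                           nrow(base)), 0.02), 0.98)
  A0 <- matrix(0.1 / (n_states - 1), n_states, n_states)
  diag(A0) <- 0.9
  pi0 <- rep(1 / n_states, n_states)
  fit <- bw_train_cpp(seqs, E0, A0, pi0, as.integer(max_iter), tol)
  ## canonical relabelling by emission profile: greedy best match of each
  ## state to a canonical mark pattern
  E <- fit$emission
  if (n_states == 16L) {
    cost <- as.matrix(stats::dist(rbind(E, as.matrix(tab[, chromatin_marks()])),
                                  method = "manhattan"))
    cost <- cost[seq_len(16L), 16L + seq_len(16L)]
    perm <- rep(NA_integer_, 16L)  # perm[canonical slot] = trained state
    cc <- cost
    for (k in seq_len(16L)) {
      ij <- arrayInd(which.min(cc), dim(cc))
      perm[ij[2]] <- ij[1]
      cc[ij[1], ] <- Inf; cc[, ij[2]] <- Inf
    }
  } else {
    perm <- order(-rowSums(E))
    perm <- rev(perm)  # fewest marks first so state 0 is most void-like
  }
  structure(list(emission = fit$emission[perm, , drop = FALSE],
                 transition = fit$transition[perm, perm, drop = FALSE],
                 initial = fit$initial[perm],
                 mark_names = chromatin_marks(),
                 n_states = n_states,
                 loglik = fit$loglik,
                 state_table = if (n_states == 16L) tab else NULL),
            class = "ChromatinHmm")
}

#' @method print ChromatinHmm
#' @export
print.ChromatinHmm <- function(x, ...) {
  cat("ChromatinHmm:", x$n_states, "states,", length(x$mark_names),
      "marks;", length(x$loglik), "Baum-Welch iterations (final loglik",
      format(utils::tail(x$loglik, 1)), ")\n")
  invisible(x)
}

#' Segment one sample's track with a trained model
#'
#' Posterior decoding: each bin gets the state with maximal posterior
#' probability (forward-backward per chromosome), ties broken toward the
#' lower state index. `method = "viterbi"` gives the joint most probable
#' path instead.
#'
#' @param hmm ChromatinHmm.
#' @param track bins x marks binary matrix.
#' @param bins bin grid data.frame.
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @return integer vector of canonical state indices (0-based) per bin.
#' @export
segment_track <- function(hmm, track, bins,
                          method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  if (ncol(track) != length(hmm$mark_names))
    stop("mark count mismatch with model")
  out <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    ii <- which(bins$chrom == ch)
    m <- track[ii, , drop = FALSE]
    storage.mode(m) <- "integer"
    if (method == "posterior") {
      post <- posterior_cpp(m, hmm$emission, hmm$transition,
                            hmm$initial)$posterior
      out[ii] <- max.col(post, ties.method = "first") - 1L
    } else {
      out[ii] <- viterbi_path(m, hmm$emission, hmm$transition,
                              hmm$initial)
    }
  }
  out
}

## log-space Viterbi (R implementation; offered behind a flag)
viterbi_path <- function(obs, E, A, pi) {
  S <- nrow(E); T_ <- nrow(obs)
  E <- pmin(pmax(E, 1e-6), 1 - 1e-6)
  logB <- sapply(seq_len(S), function(s)
    obs %*% log(E[s, ]) + (1 - obs) %*% log(1 - E[s, ]))
  logB <- matrix(logB, nrow = T_)
  lA <- log(pmax(A, 1e-300))
  delta <- matrix(-Inf, T_, S)
  psi <- matrix(0L, T_, S)
  delta[1, ] <- log(pmax(pi, 1e-300)) + logB[1, ]
  for (t in 2:T_) {
    for (s in seq_len(S)) {
      v <- delta[t - 1, ] + lA[, s]
      psi[t, s] <- which.max(v)
      delta[t, s] <- v[psi[t, s]] + logB[t, s]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path - 1L
}

#' Group consensus segmentation
#'
#' A bin is assigned a state in the consensus iff at least `min_samples`
#' of the group's segmentations carry that state there; among qualifying
#' states the one with most supporting samples wins, ties toward the lower
#' state index; bins without a qualifying state are Void (state 0).
#'
#' @param seg matrix bins x samples of state indices.
#' @param min_samples support threshold (default 2).
#' @return integer consensus state per bin.
#' @export
merge_group <- function(seg, min_samples = 2L) {
  seg <- as.matrix(seg)
  if (ncol(seg) < min_samples)
    stop("group smaller than min_samples")
  apply(seg, 1L, function(s) {
    tb <- table(s)
    tb <- tb[tb >= min_samples]
    if (!length(tb)) return(0L)
    st <- as.integer(names(tb))
    cand <- st[tb == max(tb)]
    min(cand)  # tie -> lower state index
  })
}

#' Merge contiguous equal-state bins into elements
#'
#' @param bins bin grid data.frame.
#' @param states integer state (or other label) per bin.
#' @param drop optional label value to omit from the output (e.g. 0 for
#'   Void).
#' @return interval data.frame with a `state` column.
#' @export
segmentation_elements <- function(bins, states, drop = NULL) {
  newrun <- c(TRUE, bins$chrom[-1] != bins$chrom[-nrow(bins)] |
                bins$start[-1] != bins$end[-nrow(bins)] |
                states[-1] != states[-length(states)])
  runid <- cumsum(newrun)
  first <- !duplicated(runid)
  last <- !duplicated(runid, fromLast = TRUE)
  out <- data.frame(chrom = bins$chrom[first], start = bins$start[first],
                    end = bins$end[last], state = states[first])
  if (!is.null(drop)) out <- out[out$state != drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate elements as TSS-associated
#'
#' An element is TSS-associated if it overlaps a TSS, or directly abuts an
#' element that does, or lies within 400 bp of either of those; everything
#' else is not TSS-associated.
#'
#' @param elements interval data.frame.
#' @param tss data.frame with `chrom` and `tss` position columns (or
#'   `gene_id`/`tss` gene table).
#' @param flank_bp chaining distance (default 400).
#' @return logical vector along elements.
#' @export
annotate_tss <- function(elements, tss, flank_bp = 400) {
  if (!nrow(elements)) return(logical(0))
  tss_iv <- data.frame(chrom = tss$chrom, start = tss$tss,
                       end = tss$tss + 1L)
  assoc <- overlaps_any(elements, tss_iv)
  grow <- function(base, dist) {
    ext <- data.frame(chrom = elements$chrom[base],
                      start = pmax(elements$start[base] - dist, 0),
                      end = elements$end[base] + dist)
    overlaps_any(elements, ext)
  }
  if (any(assoc)) {
    neigh <- assoc | grow(assoc, 1)          # directly abutting elements
    assoc <- neigh | grow(neigh, flank_bp + 1)  # gap <= flank_bp
  }
  assoc
}

#' Classify consensus elements into regulatory categories
#'
#' Maps each element's state to its meta-state and splits the active
#' meta-state by TSS association: active and TSS-associated elements are
#' promoters, active non-TSS elements are enhancers.
#'
#' @param elements element data.frame with `state`.
#' @param genes gene table with `chrom` and `tss` (for TSS association).
#' @return elements with added `meta`, `tss_associated`, `category`
#'   (promoter/enhancer/bivalent/repressed/amplification/void).
#' @export
classify_elements <- function(elements, genes) {
  elements$meta <- meta_states(elements$state)
  elements$tss_associated <- annotate_tss(elements, genes)
  elements$category <- ifelse(
    elements$meta == "active",
    ifelse(elements$tss_associated, "promoter", "enhancer"),
    elements$meta)
  elements
}

#' Chromatin-state transitions between condition consensus paths
#'
#' Compares the non-smoking and smoking consensus segmentations bin by bin
#' at the meta-state level, reporting base-pair totals per (from, to)
#' meta-state pair over changed bins, the fractions of changed chromatin
#' entering each destination meta-state, and a two-sided binomial test of
#' the active-versus-repressed destination asymmetry. With masks (named
#' interval sets, e.g. ngDMRs/gDMRs) the same summary is computed
#' restricted to bins overlapping each mask, plus the fold enrichment of
#' changed bins in the mask over the genomic rate.
#'
#' @param cons_ns,cons_smk integer consensus state vectors (non-smoking,
#'   smoking) on the same bin grid.
#' @param bins bin grid data.frame.
#' @param masks named list of interval data.frames.
#' @return list of class `transition_summary`: `matrix` (bp, from x to),
#'   `fractions`, `n_changed_bins`, `p_asymmetry`, `state_matrix`
#'   (16-state bin counts), `masked` (per-mask summaries with
#'   `fold_change`).
#' @export
chromatin_transitions <- function(cons_ns, cons_smk, bins,
                                  masks = list()) {
  if (length(cons_ns) != nrow(bins) || length(cons_smk) != nrow(bins))
    stop("bin grids mismatch")
  metas <- c("void", "active", "bivalent", "repressed", "amplification")
  bp <- bins$end - bins$start
  m_ns <- meta_states(cons_ns); m_smk <- meta_states(cons_smk)
  summarise <- function(sel) {
    changed <- sel & m_ns != m_smk
    mat <- matrix(0, 5, 5, dimnames = list(from = metas, to = metas))
    if (any(changed)) {
      tb <- tapply(bp[changed],
                   list(factor(m_ns[changed], metas),
                        factor(m_smk[changed], metas)), sum)
      tb[is.na(tb)] <- 0
      mat <- mat + tb
    }
    tot <- sum(mat)
    fr <- if (tot > 0) colSums(mat) / tot else
      stats::setNames(rep(NA_real_, 5), metas)
    n_act <- sum(m_smk[changed] == "active")
    n_rep <- sum(m_smk[changed] == "repressed")
    p <- if (n_act + n_rep > 0)
      stats::binom.test(n_act, n_act + n_rep, 0.5)$p.value else NA_real_
    list(matrix = mat, fractions = fr,
         n_changed_bins = sum(changed), p_asymmetry = p)
  }
  out <- summarise(rep(TRUE, nrow(bins)))
  st_changed <- cons_ns != cons_smk
  out$state_matrix <- table(factor(cons_ns[st_changed], 0:15),
                            factor(cons_smk[st_changed], 0:15))
  ## enrichment of variable chromatin (any state change) in each mask,
  ## as fold change over the genome-wide rate
  rate_all <- mean(st_changed)
  out$masked <- lapply(masks, function(mk) {
    sel <- overlaps_any(bins, mk)
    s <- summarise(sel)
    s$fold_change <- if (any(sel) && rate_all > 0)
      mean(st_changed[sel]) / rate_all else NA_real_
    s
  })
  class(out) <- "transition_summary"
  out
}

#' @method print transition_summary
#' @export
print.transition_summary <- function(x, ...) {
  cat("Chromatin transitions:", x$n_changed_bins, "changed bins\n")
  if (x$n_changed_bins > 0) {
    fr <- round(100 * x$fractions, 1)
    cat("  destination fractions (%):",
        paste(names(fr), fr, sep = "=", collapse = ", "), "\n")
    cat("  active-vs-repressed asymmetry p =", format(x$p_asymmetry), "\n")
  }
  invisible(x)
}

#' Permutation test for the amount of changed chromatin
#'
#' Swaps sample-to-group labels, recomputes the two consensus paths and the
#' changed-bin count, and reports the upper-tail permutation p-value for
#' the observed amount of change.
#'
#' @param seg matrix bins x samples of states (all samples).
#' @param groups list of integer column indices `smoking`, `non_smoking`.
#' @param min_samples consensus support threshold.
#' @param n_perm label permutations (default 50).
#' @return list with `observed` changed-bin count and `p`.
#' @export
transition_permutation_test <- function(seg, groups, min_samples = 2L,
                                        n_perm = 50L) {
  count_changed <- function(i1, i2) {
    sum(merge_group(seg[, i1, drop = FALSE], min_samples) !=
          merge_group(seg[, i2, drop = FALSE], min_samples))
  }
  obs <- count_changed(groups$smoking, groups$non_smoking)
  all_idx <- c(groups$smoking, groups$non_smoking)
  n1 <- length(groups$smoking)
  null <- vapply(seq_len(n_perm), function(k) {
    p <- sample(all_idx)
    count_changed(p[seq_len(n1)], p[-seq_len(n1)])
  }, 1L)
  list(observed = obs, p = (1 + sum(null >= obs)) / (1 + n_perm))
}
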