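# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately re-derive results from first principles rather
# than calling the implementation under test.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_enum_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  combs <- utils::combn(m + n, m, simplify = FALSE)
  r <- rank(pooled)
  us <- vapply(combs, function(ix) {
    sum(r[ix]) - m * (m + 1) / 2
  }, numeric(1))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Decoy-counting FDR/q recount: double loop over distinct scores.
fdr_recount_oracle <- function(scores, is_decoy) {
  thr <- sort(unique(scores), decreasing = TRUE)
  fdr <- vapply(thr, function(s) {
    t <- sum(scores >= s & !is_decoy)
    d <- sum(scores >= s & is_decoy)
    if (t > 0) d / t else Inf
  }, numeric(1))
  q <- vapply(seq_along(thr), function(i) min(fdr[i:length(thr)]), numeric(1))
  data.frame(score = thr, fdr = fdr, q_value = q)
}

# Naive UPGMA: merges the closest pair, recomputing average inter-cluster
# distance over all member pairs each step; returns sorted merge heights.
upgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Random peptide->accession instance for parsimony tests.
random_pep_map <- function(n_prot, n_pep) {
  accs <- sprintf("P%02d", seq_len(n_prot))
  repeat {
    m <- lapply(seq_len(n_pep), function(i) {
      sort(sample(accs, sample.int(min(3L, n_prot), 1L)))
    })
    names(m) <- sprintf("pep%02d", seq_len(n_pep))
    if (length(unique(unlist(m))) >= 1L) return(m)
  }
}

# Tiny deterministic PSM table for unit tests of screening/FDR mechanics.
toy_psm_table <- function(scores, is_decoy,
                          mass_error = rep(0, length(scores))) {
  n <- length(scores)
  data.frame(psm_id = sprintf("T%03d", seq_len(n)),
             peptide = replicate(n, paste(sample(LETTERS[1:20], 8,
                                                 replace = TRUE),
                                          collapse = "")),
             accessions = ifelse(is_decoy, sprintf("rev_PR%02d", seq_len(n)),
                                 sprintf("PR%02d", seq_len(n))),
             is_decoy = is_decoy, lda_score = scores,
             mass_error_ppm = mass_error, stringsAsFactors = FALSE)
}
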