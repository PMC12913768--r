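# Independent reference implementations used as oracles. Deliberately
# written as plain loops / enumerations, sharing no code with the package
# internals they check.

# PLINK-style ROH detection by direct enumeration of every window and run.
brute_roh <- function(g, pos, p = roh_params()) {
  n <- length(g)
  w <- p$window_snps
  segs <- data.frame(start = numeric(0), end = numeric(0),
                     n_snps = integer(0), n_het = integer(0))
  if (n < w) return(segs)
  nw <- n - w + 1
  win_ok <- logical(nw)
  for (i in seq_len(nw)) {
    win <- g[i:(i + w - 1)]
    win_ok[i] <- sum(win == 1L, na.rm = TRUE) <= p$max_het_per_window &&
      sum(is.na(win)) <= p$max_missing_per_window
  }
  pass <- logical(n)
  for (j in seq_len(n)) {
    wins <- max(1, j - w + 1):min(j, nw)
    pass[j] <- mean(win_ok[wins]) >= p$hit_threshold
  }
  run_start <- NULL
  flush_run <- function(idx) {
    pieces <- list()
    cur <- idx[1]
    prev <- idx[1]
    members <- c(idx[1])
    for (j in idx[-1]) {
      if (pos[j] - pos[prev] > p$max_gap_kb * 1000) {
        pieces[[length(pieces) + 1]] <- members
        members <- c()
      }
      members <- c(members, j)
      prev <- j
    }
    pieces[[length(pieces) + 1]] <- members
    pieces
  }
  j <- 1
  while (j <= n) {
    if (pass[j]) {
      k <- j
      while (k < n && pass[k + 1]) k <- k + 1
      for (piece in flush_run(j:k)) {
        len <- pos[piece[length(piece)]] - pos[piece[1]] + 1
        if (len >= p$min_length_kb * 1000 &&
              length(piece) >= p$min_snps &&
              len / length(piece) <= p$max_inverse_density_kb_per_snp * 1000) {
          segs <- rbind(segs, data.frame(
            start = pos[piece[1]], end = pos[piece[length(piece)]],
            n_snps = length(piece),
            n_het = sum(g[piece] == 1L, na.rm = TRUE)))
        }
      }
      j <- k + 1
    } else j <- j + 1
  }
  segs
}

# Exact heterozygote-excess p-value by brute-force sum over all genotype
# configurations (nAA, nAa, naa) weighted by their allele-arrangement
# counts, conditional on the allele count.
brute_hwe_het_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  n_a <- n_het + 2 * n_hom_alt
  if (n == 0 || n_a == 0 || n_a == 2 * n) return(1)
  weight <- function(h) {
    n_aa <- (n_a - h) / 2
    n_rr <- n - h - n_aa
    if (n_aa < 0 || n_rr < 0 || n_aa != round(n_aa)) return(0)
    exp(lfactorial(n) - lfactorial(n_aa) - lfactorial(h) -
          lfactorial(n_rr) + h * log(2))
  }
  hs <- 0:min(n_a, n)
  ws <- vapply(hs, weight, numeric(1))
  sum(ws[hs >= n_het]) / sum(ws)
}

# Fully independent small-n oracle: enumerate every arrangement of the
# alt alleles over the 2n ordered allele slots; individuals are
# consecutive slot pairs.
enumerate_hwe_het_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  n_a <- n_het + 2 * n_hom_alt
  if (n == 0 || n_a == 0 || n_a == 2 * n) return(1)
  slots <- utils::combn(2 * n, n_a)
  hets <- apply(slots, 2, function(s) {
    alt <- logical(2 * n)
    alt[s] <- TRUE
    sum(alt[seq(1, 2 * n, 2)] != alt[seq(2, 2 * n, 2)])
  })
  mean(hets >= n_het)
}

# Mean pairwise difference over all haplotype pairs, by direct loops.
brute_pi_site <- function(haplotypes) {
  n <- length(haplotypes)
  tot <- 0
  cnt <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + (haplotypes[i] != haplotypes[j])
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

# Project a true epoched history onto a grid as an interval-averaged
# trajectory (exact integral of m; size at interval midpoint).
history_to_trajectory <- function(history, grid) {
  K <- length(grid) - 1
  m_avg <- numeric(K)
  n1 <- numeric(K)
  n2 <- numeric(K)
  for (k in seq_len(K)) {
    lo <- grid[k]; hi <- grid[k + 1]
    cuts <- sort(unique(c(lo, hi, history$start[history$start > lo &
                                                  history$start < hi])))
    tot <- 0
    for (j in seq_len(length(cuts) - 1)) {
      ep <- findInterval(cuts[j], history$start)
      tot <- tot + history$m[ep] * (cuts[j + 1] - cuts[j])
    }
    m_avg[k] <- tot / (hi - lo)
    ep_mid <- findInterval((lo + hi) / 2, history$start)
    n1[k] <- history$N1[ep_mid]
    n2[k] <- history$N2[ep_mid]
  }
  im_trajectory(grid, m = m_avg, N1 = n1, N2 = n2)
}
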