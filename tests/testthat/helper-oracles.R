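# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

# DTW by exhaustive enumeration of every monotone warping path from (1,1)
# to (n,m) with steps right/down/diagonal; returns the minimal total |x-y|
# cost. Exponential, so only for tiny series.
dtw_brute_force <- function(x, y) {
  n <- length(x); m <- length(y)
  walk <- function(i, j) {
    cost <- abs(x[i] - y[j])
    if (i == n && j == m) return(cost)
    nxt <- Inf
    if (i < n) nxt <- min(nxt, walk(i + 1, j))
    if (j < m) nxt <- min(nxt, walk(i, j + 1))
    if (i < n && j < m) nxt <- min(nxt, walk(i + 1, j + 1))
    cost + nxt
  }
  walk(1, 1)
}

# Definitional XCRD: term-by-term squared lagged Pearson correlations.
xcrd_definitional <- function(x, y, max_lag) {
  n <- length(x)
  r <- function(k) stats::cor(x[1:(n - k)], y[(1 + k):n])
  num <- 1 - r(0)^2
  den <- 0
  for (k in 1:max_lag) den <- den + (1 - r(k)^2)
  num / den
}

# Mutual information (bits) via entropies H(A) + H(B) - H(A,B).
mi_entropy <- function(a, b) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  pa <- table(a) / length(a)
  pb <- table(b) / length(b)
  pab <- table(paste(a, b)) / length(a)
  H(pa) + H(pb) - H(pab)
}

# Equal-frequency binning mirrored from the documented contract
# (rank-based, ties share a bin).
bin3 <- function(x) ceiling(3 * rank(x, ties.method = "average") / length(x))

# Greedy MID mRMR re-derived from first principles on discretized features.
mrmr_oracle <- function(features, labels) {
  disc <- lapply(features, bin3)
  rel <- vapply(disc, mi_entropy, numeric(1), b = labels)
  ranked <- character(0)
  remaining <- names(features)
  while (length(remaining) > 0) {
    score <- vapply(remaining, function(f) {
      if (length(unique(disc[[f]])) == 1) return(-Inf)
      if (length(ranked) == 0) return(rel[[f]])
      rel[[f]] - mean(vapply(ranked, function(g) {
        mi_entropy(disc[[f]], disc[[g]])
      }, numeric(1)))
    }, numeric(1))
    ord <- order(-round(score, 10), -round(unlist(rel[remaining]), 10),
                 remaining)
    ranked <- c(ranked, remaining[ord[1]])
    remaining <- setdiff(remaining, ranked)
  }
  ranked
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_exact_enumeration <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  obs <- u_stat(seq_len(na))
  combos <- utils::combn(n, na)
  r <- rank(pooled)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

# Small deterministic two-patient cohort for IO and identity checks.
toy_cohort_table <- function(sessions = c("train_1", "train_2")) {
  mk <- function(p, s, v, lab) {
    data.frame(patient_id = p, session = s,
               stride_index = seq_along(v) - 1L, mfc_mm = v, label = lab)
  }
  rbind(
    mk("P1", "baseline", c(20, 22, 19, 21, 23), "improved"),
    do.call(rbind, lapply(sessions, function(s)
      mk("P1", s, c(24, 26, 23, 25, 27), "improved"))),
    mk("P2", "baseline", c(18, 20, 17, 19, 21), "unimproved"),
    do.call(rbind, lapply(sessions, function(s)
      mk("P2", s, c(18.5, 20.2, 17.4, 19.1, 20.8), "unimproved")))
  )
}

# Tiny fast synthetic config for property tests.
small_synth <- function(seed = 11L, missing_rate = 0, ...) {
  synthetic_config(n_improved = 6L, n_unimproved = 4L, strides = 60L,
                   missing_rate = missing_rate, seed = seed, ...)
}
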