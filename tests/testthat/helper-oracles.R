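# Independent brute-force oracles used to validate the package's metrics.
# These are deliberately naive re-derivations from the definitions (explicit
# scalar loops, exhaustive enumeration) and share no code with the package.

# WNODF: pair-by-pair evaluation with explicit loops over both axes
wnodf_oracle <- function(m) {
  score_pairs <- function(mm) {
    n <- nrow(mm)
    tot <- sapply(seq_len(n), function(i) sum(mm[i, ]))
    out <- 0
    for (u in seq_len(n)) for (v in seq_len(n)) {
      if (u >= v) next
      if (tot[u] == tot[v]) next
      hi <- if (tot[u] > tot[v]) u else v
      lo <- u + v - hi
      num <- 0; den <- 0
      for (j in seq_len(ncol(mm))) {
        if (mm[lo, j] > 0) {
          den <- den + 1
          if (mm[lo, j] < mm[hi, j]) num <- num + 1
        }
      }
      out <- out + 100 * num / den
    }
    out
  }
  P <- nrow(m); B <- ncol(m)
  (score_pairs(m) + score_pairs(t(m))) / (P * (P - 1) / 2 + B * (B - 1) / 2)
}

# All set partitions of n items as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    k <- length(labels) + 1L
    if (k > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_max + 1L)) {
      recurse(c(labels, lab), max(next_max, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Global maximum Barber Q by exhaustive enumeration over joint partitions
best_q_exhaustive <- function(m) {
  P <- nrow(m); B <- ncol(m)
  F <- sum(m)
  excess <- m - outer(rowSums(m), colSums(m)) / F
  best <- -Inf
  for (labels in all_partitions(P + B)) {
    delta <- outer(labels[seq_len(P)], labels[P + seq_len(B)], "==")
    q <- sum(excess[delta]) / F
    if (q > best) best <- q
  }
  best
}

# G statistic recomputed cell by cell
g_oracle <- function(ct) {
  N <- sum(ct)
  g <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    e <- sum(ct[i, ]) * sum(ct[, j]) / N
    if (ct[i, j] > 0) g <- g + ct[i, j] * log(ct[i, j] / e)
  }
  2 * g
}

# Exact distribution of the top-left cell of a 2x2 table with fixed margins
# (multivariate hypergeometric)
exact_2x2_probs <- function(r, s) {
  N <- sum(r)
  lo <- max(0L, r[1] - s[2]); hi <- min(r[1], s[1])
  x <- lo:hi
  p <- choose(s[1], x) * choose(s[2], r[1] - x) / choose(N, r[1])
  stats::setNames(p, x)
}

# Normalized mutual information between two labelings
nmi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  if (h(pa) == 0 && h(pb) == 0) return(1)
  unname(mi / sqrt(h(pa) * h(pb)))
}

# Random small web with positive margins, for oracle comparisons
random_web <- function(P, B, lambda = 1.5) {
  repeat {
    m <- matrix(stats::rpois(P * B, lambda), P, B)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
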