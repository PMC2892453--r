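# Independent brute-force oracles. These deliberately share no code with the
# package implementation paths they check.

# Complete-linkage agglomeration on Manhattan distances, done naively; the
# pairwise cophenetic heights characterize the tree regardless of node order.
bf_complete_cophenetic <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best_h <- Inf
    best <- c(NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    for (a in clusters[[best[1]]]) {
      for (b in clusters[[best[2]]]) {
        coph[a, b] <- coph[b, a] <- best_h
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Benjamini-Hochberg step-up written out longhand.
bh_manual <- function(p) {
  m <- length(p)
  if (!m) return(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(q))))
  adj[order(o)]
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws; the first K of N items are the set members.
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Welch two-tailed p straight from the textbook formulas.
welch_manual <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(abs(tt), df, lower.tail = FALSE)
}
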