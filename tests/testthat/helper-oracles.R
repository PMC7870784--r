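# Independent oracles used to cross-check the package implementations.
# They deliberately avoid the code paths they verify.

# Exact binomial coefficients by Pascal's recurrence (integer arithmetic,
# exact for all values below 2^53 — comfortably true for m <= 60).
pascal_table <- local({
  cache <- NULL
  function(m) {
    if (!is.null(cache) && nrow(cache) >= m + 1) return(cache[seq_len(m + 1), , drop = FALSE])
    tab <- matrix(0, m + 1, m + 1)
    tab[, 1] <- 1
    for (r in 2:(m + 1)) {
      for (c in 2:r) tab[r, c] <- tab[r - 1, c - 1] + tab[r - 1, c]
    }
    cache <<- tab
    tab
  }
})

pascal_choose <- function(a, b) {
  if (b < 0 || b > a) return(0)
  pascal_table(max(a, 1))[a + 1, b + 1]
}

# Exact-rational tail probabilities: ratio of exact integer counts.
oracle_hyper_upper <- function(m, j, n, x) {
  hi <- min(j, n)
  if (x > hi) return(0)
  num <- sum(vapply(x:hi, function(i) pascal_choose(j, i) * pascal_choose(m - j, n - i),
                    numeric(1)))
  num / pascal_choose(m, n)
}

oracle_hyper_lower <- function(m, j, n, x) {
  num <- sum(vapply(0:x, function(i) pascal_choose(j, i) * pascal_choose(m - j, n - i),
                    numeric(1)))
  num / pascal_choose(m, n)
}

# Brute-force draw enumeration: walk every size-n subset of 1..m and count
# those sharing >= x elements with the reference set 1..j.
enumeration_hyper_upper <- function(m, j, n, x) {
  draws <- utils::combn(m, n)
  hits <- colSums(draws <= j)
  mean(hits >= x)
}

# Reference BH step-up, written directly from the procedure definition.
oracle_bh <- function(p) {
  nn <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * nn / seq_len(nn))))
  pmin(1, adj_sorted)[order(o)]
}

# Brute-force betweenness by shortest-path counting over BFS layers.
# adj: symmetric logical/0-1 adjacency matrix. Returns normalized values.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n <= 2) return(rep(0, n))
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (!is.finite(dist[s, w])) {
            dist[s, w] <- d
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    btw[v] <- acc
  }
  btw / ((n - 1) * (n - 2) / 2)
}

random_bipartite_adj <- function(n_left, n_right, p_edge) {
  n <- n_left + n_right
  adj <- matrix(0, n, n)
  for (i in seq_len(n_left)) {
    for (jj in (n_left + seq_len(n_right))) {
      if (stats::runif(1) < p_edge) adj[i, jj] <- adj[jj, i] <- 1
    }
  }
  adj
}
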