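# Independent brute-force oracles used to validate the analytic
# implementations. These deliberately use naive, slow formulations.

# Ledoit-Wolf shrinkage intensity by direct per-pair summation.
oracle_lambda <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  xs <- apply(x, 2, function(col) (col - mean(col)) / sd(col))
  num <- 0
  den <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      w <- xs[, i] * xs[, j]
      r <- sum(w) / (n - 1)
      num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
      den <- den + r^2
    }
  }
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

# Partial correlation of columns i and j as the correlation of the
# residuals from regressing each on all remaining columns.
oracle_pcor_residual <- function(x, i, j) {
  others <- setdiff(seq_len(ncol(x)), c(i, j))
  if (length(others) == 0) return(cor(x[, i], x[, j]))
  ri <- resid(lm(x[, i] ~ x[, others]))
  rj <- resid(lm(x[, j] ~ x[, others]))
  cor(ri, rj)
}

# Closed-form 3-variable partial correlation.
oracle_pcor3 <- function(r12, r13, r23) {
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

# Two-sided tail probability of the null density (1-r^2)^((k-3)/2) on
# [-1, 1], by numerical integration.
oracle_null_tail <- function(r, kappa) {
  f <- function(t) (1 - t^2)^((kappa - 3) / 2)
  z <- integrate(f, -1, 1, rel.tol = 1e-10)$value
  2 * integrate(f, abs(r), 1, rel.tol = 1e-10)$value / z
}

# Freeman betweenness by exhaustive enumeration of all shortest paths,
# from an adjacency matrix; each unordered pair counted once.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    # BFS distances from s
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    if (is.infinite(dist[t])) return(list())
    # enumerate shortest paths backwards from t
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) {
        paths[[length(paths) + 1]] <<- rev(acc)
        return(invisible(NULL))
      }
      for (u in which(adj[v, ] > 0)) {
        if (dist[u] == dist[v] - 1) walk(u, c(acc, u))
      }
    }
    walk(t, t)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- all_paths(s, t)
      np <- length(paths)
      if (np == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / np
      }
    }
  }
  btw
}

# Least-squares slope via the normal equations.
oracle_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Random undirected graph as an assoc_network-like edge frame.
random_network <- function(n_nodes, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- t(combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
               pcor = round(runif(sum(keep), -1, 1), 3),
               p_value = round(runif(sum(keep)), 4)),
    directed = FALSE, vertices = data.frame(name = nodes)
  )
  g
}

# Small deterministic two-group dataset helper.
toy_dataset <- function(n_a = 30, n_b = 30, m = 4, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm((n_a + n_b) * m), ncol = m,
                 dimnames = list(NULL, paste0("V", seq_len(m))))
  grouped_dataset(vals, rep(c("A", "B"), c(n_a, n_b)))
}
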