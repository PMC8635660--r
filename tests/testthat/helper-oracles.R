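# Brute-force oracles, independent of the package's igraph-based
# implementations. Everything works on a plain 0/1 adjacency matrix.

adj_from_igraph <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

igraph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# all-pairs shortest-path distances by breadth-first search
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer()
      for (v in frontier) {
        for (u in which(A[v, ] == 1)) {
          if (D[s, u] == Inf && u != s) {
            D[s, u] <- depth
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# number of shortest paths between every pair (row = source)
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    reach <- which(is.finite(D[s, ]))
    for (v in reach[order(D[s, reach])]) {
      if (v == s) next
      preds <- which(A[v, ] == 1 & D[s, ] == D[s, v] - 1)
      S[s, v] <- sum(S[s, preds])
    }
  }
  S
}

# normalized betweenness via explicit shortest-path counting: a pair
# (s, t) routes through v iff d(s,v) + d(v,t) = d(s,t), contributing the
# fraction of s-t geodesics passing v
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  S <- oracle_path_counts(A, D)
  bc <- numeric(n)
  upper <- upper.tri(D)
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], "+") == D & is.finite(D) & upper
    through[v, ] <- FALSE
    through[, v] <- FALSE
    paths <- outer(S[, v], S[v, ])
    bc[v] <- sum(paths[through] / S[through])
  }
  denom <- (n - 1) * (n - 2) / 2
  if (denom > 0) bc / denom else bc
}

oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  vapply(seq_len(nrow(A)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, numeric(1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

oracle_topological_coefficient <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    k <- sum(A[i, ])
    if (k < 2) return(0)
    vals <- c()
    for (m in seq_len(n)) {
      if (m == i) next
      shared <- sum(A[i, ] == 1 & A[m, ] == 1)
      if (shared > 0) vals <- c(vals, (shared + A[i, m]) / k)
    }
    if (!length(vals)) 0 else mean(vals)
  }, numeric(1))
}

oracle_nc <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  dens <- sum(A) / (n * (n - 1))
  (n / (n - 2)) * (max(deg) / (n - 1) - dens)
}

oracle_cpl <- function(A) {
  D <- oracle_distances(A)
  v <- D[upper.tri(D)]
  mean(v[is.finite(v)])
}

oracle_nh <- function(A) {
  deg <- rowSums(A)
  sqrt(mean((deg - mean(deg))^2)) / mean(deg)
}

# largest-component size by union-find
oracle_largest_component <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in which(A[i, ] == 1)) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  max(table(roots))
}

# direct-summation entropy-weight oracle (loops, no vectorization shared
# with the implementation)
oracle_entropy <- function(zmat) {
  n <- nrow(zmat); m <- ncol(zmat)
  k <- 1 / log(n)
  e <- numeric(m); b <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    tot <- 0
    for (i in seq_len(n)) tot <- tot + zmat[i, j]
    if (tot == 0) { e[j] <- 1; next }
    acc <- 0
    for (i in seq_len(n)) {
      bij <- zmat[i, j] / tot
      b[i, j] <- bij
      if (bij > 0) acc <- acc + bij * log(bij)
    }
    e[j] <- -k * acc
  }
  d <- 1 - e
  list(b = b, e = e, d = d, w = d / sum(d))
}

# random G(n, p) adjacency matrix
random_adj <- function(n, p) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1L
  }
  A
}

random_connected_adj <- function(n, p) {
  repeat {
    A <- random_adj(n, p)
    if (oracle_largest_component(A) == n) return(A)
  }
}

# all connected labeled graphs on n nodes (feasible for n <= 5)
all_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    A <- matrix(0L, n, n)
    bits <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    for (b in bits) {
      A[pairs[b, 1], pairs[b, 2]] <- 1L
      A[pairs[b, 2], pairs[b, 1]] <- 1L
    }
    if (n == 1 || oracle_largest_component(A) == n) out[[length(out) + 1]] <- A
  }
  out
}
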