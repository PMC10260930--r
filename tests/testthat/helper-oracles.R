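# Independent brute-force oracles used across the suite. These stay
# deliberately naive (adjacency-matrix BFS, all-pairs enumeration, direct
# formulas) so they share no code path with the package implementation.

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# BFS from s on adjacency A: distances and shortest-path counts
bfs_sigma <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in which(A[u, ] > 0)) {
        if (is.infinite(dist[w])) { dist[w] <- dist[u] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[u] + 1) sigma[w] <- sigma[w] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = dist, s = sigma)
}

oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    b <- bfs_sigma(A, s)
    D[s, ] <- b$d; S[s, ] <- b$s
  }
  list(D = D, S = S)
}

# unnormalized pair-count betweenness from the path-count identity
oracle_betweenness <- function(A) {
  sp <- oracle_shortest_paths(A)
  D <- sp$D; S <- sp$S; n <- nrow(A)
  bet <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bet[v] <- bet[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  bet
}

# closeness under the package's stated convention
oracle_closeness <- function(A) {
  D <- oracle_shortest_paths(A)$D
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    reach <- is.finite(di)
    nc <- sum(reach) + 1L
    if (nc == 1L) return(0)
    (nc - 1) / sum(di[reach]) * (nc - 1) / (n - 1)
  }, 0)
}

# k-core numbers by iterative peeling
oracle_kcore <- function(A) {
  n <- nrow(A)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      low <- which(deg <= k)
      if (length(low) == 0L) break
      idx <- which(alive)[low]
      core[idx] <- k
      alive[idx] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1L
  }
  core
}

# Burt's constraint from the proportional-tie formula
oracle_constraint <- function(A) {
  deg <- rowSums(A)
  P <- A / ifelse(deg == 0, 1, deg)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    if (deg[i] == 0) return(NaN)
    nb <- which(A[i, ] > 0)
    sum(vapply(nb, function(j) (P[i, j] + sum(P[i, ] * P[, j]))^2, 0))
  }, 0)
}

# PageRank by plain power iteration (graphs without isolated nodes)
oracle_pagerank <- function(A, damping = 0.85, tol = 1e-13) {
  n <- nrow(A)
  deg <- rowSums(A)
  stopifnot(all(deg > 0))
  M <- t(A / deg)
  x <- rep(1 / n, n)
  repeat {
    x_new <- (1 - damping) / n + damping * as.numeric(M %*% x)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
}

# principal-eigenvector authority score via eigen decomposition
oracle_authority <- function(A) {
  v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1L])
  v / max(v)
}

# O(n^2) pairwise strict-dominance Pareto front (maximization), chunked
oracle_pareto <- function(m) {
  n <- nrow(m)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    ge <- m[, 1] >= m[i, 1] & m[, 2] >= m[i, 2] & m[, 3] >= m[i, 3]
    gt <- m[, 1] > m[i, 1] | m[, 2] > m[i, 2] | m[, 3] > m[i, 3]
    dominated[i] <- any(ge & gt)
  }
  which(!dominated)
}

# direct interval-membership bin assignment under (lo, hi]
oracle_bin <- function(x, edges) {
  vapply(x, function(v) {
    for (b in seq_len(length(edges) - 1L)) {
      if (v > edges[b] && v <= edges[b + 1L]) return(b)
    }
    NA_integer_
  }, 1L)
}

# Mann-Whitney rank formula AUC (average ranks for ties)
oracle_auc <- function(y, score) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# rank-then-Pearson Spearman with tie correction (average ranks)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random-graph fixture without isolated vertices (for the pagerank oracle)
seeded_test_graph <- function(n, p, seed) {
  g <- generate_random_graph(n, "erdos_renyi", p = p, seed = seed)
  iso <- which(igraph::degree(g) == 0)
  if (length(iso) > 0L) g <- igraph::delete_vertices(g, iso)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(igraph::vcount(g))))
}

# brute-force contact-edge oracle: all residue pairs x all atom pairs
oracle_contacts <- function(s, rule) {
  a <- s$atoms
  if (rule$heavy_atoms_only) a <- a[a$element != "H", , drop = FALSE]
  key <- residue_key(a$chain, a$seqnum, a$icode)
  res <- unique(key)
  rad <- unname(rule$vdw_table[a$element])
  edges <- character(0)
  for (i in seq_along(res)) {
    for (j in seq_along(res)) {
      if (j <= i) next
      if (abs(i - j) < rule$min_seq_separation) next  # single-chain fixtures
      ii <- which(key == res[i]); jj <- which(key == res[j])
      hit <- FALSE
      for (u in ii) for (v in jj) {
        d <- sqrt((a$x[u] - a$x[v])^2 + (a$y[u] - a$y[v])^2 + (a$z[u] - a$z[v])^2)
        if (d <= rad[u] + rad[v] + 2 * rule$probe_radius) { hit <- TRUE; break }
      }
      if (hit) {
        pr <- sort(c(res[i], res[j]))
        edges <- c(edges, paste(pr[1], pr[2]))
      }
    }
  }
  sort(edges)
}

graph_edge_strings <- function(g) {
  el <- igraph::as_edgelist(g)
  sort(apply(el, 1L, function(e) paste(sort(e)[1], sort(e)[2])))
}
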