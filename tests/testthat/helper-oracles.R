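# Brute-force reference implementations, deliberately naive and independent
# of the package internals: plain loops over edge lists and node triples.

# Erdos-Renyi edge table on nodes n01..nXX.
oracle_random_graph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(protein_a = pairs[keep, 1], protein_b = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

oracle_nodes <- function(edges) sort(unique(c(edges[[1]], edges[[2]])))

oracle_neighbors <- function(edges, v) {
  sort(unique(c(edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v])))
}

oracle_degree <- function(edges, v) length(oracle_neighbors(edges, v))

oracle_is_edge <- function(edges, a, b) {
  any((edges[[1]] == a & edges[[2]] == b) |
      (edges[[1]] == b & edges[[2]] == a))
}

# Triangle count through edge (i, j) by enumerating all node triples.
oracle_triangles <- function(edges, i, j) {
  count <- 0
  for (w in oracle_nodes(edges)) {
    if (w == i || w == j) next
    if (oracle_is_edge(edges, i, w) && oracle_is_edge(edges, j, w)) {
      count <- count + 1
    }
  }
  count
}

# Clustering coefficient by counting edges inside the neighbor subgraph.
oracle_clustering <- function(edges, j) {
  nb <- oracle_neighbors(edges, j)
  d <- length(nb)
  if (d <= 1) return(0)
  e_j <- 0
  if (d >= 2) {
    for (a in seq_len(d - 1)) {
      for (b in seq.int(a + 1, d)) {
        if (oracle_is_edge(edges, nb[a], nb[b])) e_j <- e_j + 1
      }
    }
  }
  2 * e_j / (d * (d - 1))
}

oracle_ecc <- function(edges, i, j) {
  denom <- min(oracle_degree(edges, i), oracle_degree(edges, j)) - 1
  if (denom <= 0) return(0)
  oracle_triangles(edges, i, j) / denom
}

oracle_necc <- function(edges, i, j, exponent = 3) {
  di <- oracle_degree(edges, i)
  dj <- oracle_degree(edges, j)
  if (di <= 1 || dj <= 1) return(0)
  oracle_triangles(edges, i, j)^exponent * oracle_clustering(edges, j) /
    ((di - 1) * (dj - 1))
}

oracle_nnec <- function(edges, i, exponent = 3) {
  sum(vapply(oracle_neighbors(edges, i),
             function(j) oracle_necc(edges, i, j, exponent), 0))
}

oracle_nc <- function(edges, i) {
  sum(vapply(oracle_neighbors(edges, i), function(j) oracle_ecc(edges, i, j),
             0))
}

oracle_nnc <- function(edges) {
  nodes <- oracle_nodes(edges)
  nc <- vapply(nodes, function(v) oracle_nc(edges, v), 0)
  if (max(nc) > 0) nc / max(nc) else nc
}

# Two-pass textbook Pearson correlation.
oracle_pcc <- function(x, y) {
  s <- length(x)
  mx <- sum(x) / s
  my <- sum(y) / s
  sx <- sqrt(sum((x - mx)^2) / (s - 1))
  sy <- sqrt(sum((y - my)^2) / (s - 1))
  if (sx == 0 || sy == 0) return(0)
  sum((x - mx) * (y - my)) / ((s - 1) * sx * sy)
}

oracle_pec <- function(edges, expr, i) {
  total <- 0
  for (j in oracle_neighbors(edges, i)) {
    pcc <- if (i %in% rownames(expr) && j %in% rownames(expr)) {
      oracle_pcc(expr[i, ], expr[j, ])
    } else 0
    total <- total + oracle_ecc(edges, i, j) * pcc
  }
  total
}

# SLCC by the stated branch-and-substitution rule, one location at a time.
oracle_slcc <- function(t_counts, b_counts) {
  stopifnot(length(t_counts) == length(b_counts))
  base <- rep(NA_real_, length(t_counts))
  for (l in seq_along(t_counts)) {
    T <- t_counts[l]; B <- b_counts[l]
    if (T > 0 && B > 0) {
      base[l] <- if (T < B) 1 - B / T else T / B - 1
    }
  }
  neg_pool <- (1 - b_counts / t_counts)[t_counts > 0]
  pos_pool <- (t_counts / b_counts - 1)[b_counts > 0]
  for (l in seq_along(t_counts)) {
    T <- t_counts[l]; B <- b_counts[l]
    if (T == 0 && B > 0) {
      base[l] <- if (length(neg_pool)) max(neg_pool) else 0
    } else if (B == 0 && T > 0) {
      base[l] <- if (length(pos_pool)) max(pos_pool) else 0
    } else if (T == 0 && B == 0) {
      base[l] <- 0
    }
  }
  base
}

# BFS distances and shortest-path counts from one source (no igraph).
oracle_bfs <- function(adj, src) {
  nodes <- names(adj)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  sigma <- stats::setNames(rep(0, length(nodes)), nodes)
  dist[src] <- 0
  sigma[src] <- 1
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    nxt <- unique(nxt)
    for (w in nxt) {
      for (v in adj[[w]]) {
        if (dist[v] == dist[w] - 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- nxt
  }
  list(dist = dist, sigma = sigma)
}

# Normalized betweenness via explicit shortest-path counting per pair.
oracle_betweenness <- function(edges) {
  nodes <- oracle_nodes(edges)
  adj <- lapply(stats::setNames(nodes, nodes),
                function(v) oracle_neighbors(edges, v))
  bfs <- lapply(stats::setNames(nodes, nodes),
                function(s) oracle_bfs(adj, s))
  bc <- stats::setNames(rep(0, length(nodes)), nodes)
  for (a in seq_along(nodes)) {
    for (b in seq_along(nodes)) {
      if (a >= b) next
      s <- nodes[a]; t <- nodes[b]
      if (is.infinite(bfs[[s]]$dist[t])) next
      for (v in nodes) {
        if (v == s || v == t) next
        # paths through v: sigma(s,v) * sigma(v,t) when on a shortest path
        if (bfs[[s]]$dist[v] + bfs[[v]]$dist[t] == bfs[[s]]$dist[t]) {
          bc[v] <- bc[v] +
            bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t] / bfs[[s]]$sigma[t]
        }
      }
    }
  }
  n <- length(nodes)
  bc / ((n - 1) * (n - 2) / 2)
}

# Random expression matrix for a node set.
oracle_random_expression <- function(ids, s, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(length(ids) * s), length(ids), s)
  rownames(m) <- ids
  m
}
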