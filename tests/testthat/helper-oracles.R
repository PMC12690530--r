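# Independent oracles and fixture builders for the graph, screen and
# mechanics tests. Everything here is deliberately naive (enumeration,
# Floyd-Warshall, exhaustive partition search) and never shares code with
# the implementation it checks.

# --- graph fixtures -------------------------------------------------------

net_from_adj <- function(adj) {
  n <- nrow(adj)
  labels <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(labels, labels)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(network_from_edges(
      data.frame(source = character(), target = character()),
      nodes = labels
    ))
  }
  network_from_edges(
    data.frame(source = labels[idx[, 1]], target = labels[idx[, 2]]),
    nodes = labels
  )
}

random_adj <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n) < p, n, n)
    a[lower.tri(a, diag = TRUE)] <- FALSE
    a | t(a)
  })
}

path_net <- function(labels) {
  network_from_edges(data.frame(source = labels[-length(labels)],
                                target = labels[-1]))
}

cycle_net <- function(labels) {
  network_from_edges(data.frame(source = labels,
                                target = c(labels[-1], labels[1])))
}

complete_net <- function(labels) {
  e <- t(combn(labels, 2))
  network_from_edges(data.frame(source = e[, 1], target = e[, 2]))
}

two_triangles <- function() {
  network_from_edges(data.frame(
    source = c("a", "b", "c", "d", "e", "f"),
    target = c("b", "c", "a", "e", "f", "d")
  ))
}

# --- graph oracles --------------------------------------------------------

oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# All shortest paths between two nodes by depth-first enumeration guided by
# a distance map from the oracle above.
enumerate_shortest_paths <- function(adj, s, t, dist) {
  if (!is.finite(dist[s, t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    for (w in which(adj[v, ])) {
      if (dist[w, t] == dist[v, t] - 1) walk(w, c(acc, w))
    }
  }
  walk(s, s)
  paths
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- oracle_floyd_warshall(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enumerate_shortest_paths(adj, s, t, dist)
      if (length(paths) == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(paths)
      }
    }
  }
  bc
}

# k-hop reachability by per-node breadth-first search (no matrix algebra).
oracle_khop_bfs <- function(adj, k) {
  n <- nrow(adj)
  reach <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0 && d < k) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    reach[s, dist <= k & seq_len(n) != s] <- 1
  }
  reach
}

# Exhaustive maximum modularity over all partitions (restricted-growth
# enumeration; feasible to ~8 nodes).
oracle_max_modularity <- function(net) {
  n <- length(net$nodes)
  stopifnot(n <= 8)
  best <- -Inf
  rgs <- function(prefix, maxval) {
    if (length(prefix) == n) {
      q <- modularity_q(net, prefix)
      if (q > best) best <<- q
      return(invisible())
    }
    for (v in seq_len(maxval + 1)) {
      rgs(c(prefix, v), max(maxval, v))
    }
  }
  rgs(1L, 1L)
  best
}

# --- misc fixtures --------------------------------------------------------

two_block_structure <- function(n_per_block = 10, within = 0.9, between = 0,
                                ...) {
  cyt <- sprintf("C%02d", seq_len(2 * n_per_block))
  correlation_structure(
    blocks = list(A = cyt[seq_len(n_per_block)],
                  B = cyt[n_per_block + seq_len(n_per_block)]),
    within_block_r = within, between_block_r = between, ...
  )
}

independent_structure <- function(n_cyt = 45, ...) {
  correlation_structure(
    blocks = as.list(sprintf("C%02d", seq_len(n_cyt))),
    within_block_r = 0, between_block_r = 0, ...
  )
}

small_phantom_spec <- function(noise_sd = 0, np_semiaxes = c(8, 10, 10),
                               grid = 64) {
  disc_phantom_spec(
    grid_shape = rep(grid, 3),
    disc_geometry = list(center = rep((grid + 1) / 2, 3),
                         radius = grid * 0.38, half_height = grid * 0.33),
    np_geometry = list(center = rep((grid + 1) / 2, 3), semiaxes = np_semiaxes),
    noise_sd = noise_sd
  )
}
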