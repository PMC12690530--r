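# Unweighted graph algorithms on logical adjacency matrices. These are the
# analytical core of the network module and are cross-checked in the test
# suite against naive enumeration oracles and igraph.

# All-pairs shortest-path hop counts by vectorized BFS (one frontier sweep
# per distance level, all sources at once). Inf marks unreachable pairs.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  a <- matrix(as.numeric(adj), n, n)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  reached <- diag(n) > 0
  frontier <- diag(n) > 0
  d <- 0
  while (any(frontier)) {
    d <- d + 1
    nxt <- (frontier %*% a) > 0
    nxt <- nxt & !reached
    dist[nxt] <- d
    reached <- reached | nxt
    frontier <- nxt
  }
  dimnames(dist) <- dimnames(adj)
  dist
}

# Connected component id per node (integer vector).
components_of <- function(adj) {
  d <- bfs_distances(adj)
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cur <- cur + 1
      comp[is.finite(d[i, ])] <- cur
    }
  }
  comp
}

# Brandes betweenness for unweighted undirected graphs: fractional credit
# for tied shortest paths, unnormalized, summed over unordered pairs
# (accumulation over ordered pairs halved at the end).
brandes_betweenness <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, rownames(adj))
}

# Dominant eigenvector of the adjacency by power iteration on A + I (the
# shift removes the bipartite +/- eigenvalue tie without changing
# eigenvectors), started uniform positive, L2-normalized.
power_eigenvector <- function(adj, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(adj)
  a <- matrix(as.numeric(adj), n, n)
  if (sum(a) == 0) {
    # Edgeless graph: centrality is uniform by symmetry.
    return(stats::setNames(rep(1 / sqrt(n), n), rownames(adj)))
  }
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    nv <- a %*% v + v
    nv <- nv / sqrt(sum(nv^2))
    if (sqrt(sum((nv - v)^2)) < tol) {
      v <- nv
      break
    }
    v <- nv
  }
  v <- pmax(as.numeric(v), 0)
  v <- v / sqrt(sum(v^2))
  stats::setNames(v, rownames(adj))
}

#' Eigenvector and betweenness centrality of a cytokine network
#'
#' Eigenvector centrality is the dominant eigenvector of the 0/1 adjacency
#' (power iteration, non-negative, L2-normalized to unit length per graph);
#' on disconnected graphs components not carrying the dominant eigenvalue
#' receive ~0. Betweenness counts shortest paths through each node over
#' unordered pairs, splitting credit across tied shortest paths (Brandes
#' convention), unnormalized. Both treat edges as unweighted.
#'
#' @param net A `cytokine_network`.
#'
#' @return A `centrality_table` tibble: `cytokine`, `eigenvector`,
#'   `betweenness`, `degree`.
#' @export
#' @examples
#' net <- network_from_edges(data.frame(source = c("a", "b"), target = c("b", "c")))
#' centralities(net) # betweenness 1 for the middle node
centralities <- function(net) {
  stopifnot(inherits(net, "cytokine_network"))
  if (length(net$nodes) == 0) stop_ivd("Network has no nodes.", "empty_graph")
  ev <- power_eigenvector(net$adjacency)
  bc <- brandes_betweenness(net$adjacency)
  out <- tibble(
    cytokine = net$nodes,
    eigenvector = unname(ev),
    betweenness = unname(bc),
    degree = unname(rowSums(net$adjacency))
  )
  class(out) <- c("centrality_table", class(out))
  out
}

#' Average shortest finite path length of a network
#'
#' Mean shortest-path hop count over unordered node pairs at finite
#' distance; disconnected pairs are excluded from both numerator and
#' denominator. An edgeless graph (no finite pair) is an error.
#'
#' @param net A `cytokine_network` with at least 2 nodes.
#' @return A non-negative number.
#' @export
average_path_length <- function(net) {
  stopifnot(inherits(net, "cytokine_network"))
  if (length(net$nodes) < 2) stop_ivd("Need at least 2 nodes.", "empty_graph")
  d <- bfs_distances(net$adjacency)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    stop_ivd("No finite node pair: the graph is edgeless.", "empty_graph")
  }
  mean(vals)
}

#' k-hop reachability matrix
#'
#' Binary symmetric matrix with `R_k[i, j] = 1` exactly when a path of at
#' most `k` edges joins i and j (diagonal excluded). Computed by boolean
#' matrix powers; the test suite verifies agreement with a BFS route.
#'
#' @param net A `cytokine_network`.
#' @param k Hop count (>= 1); k = 1 is the adjacency itself.
#'
#' @return A `reachability_matrix`: list with binary `R` and `k`.
#' @export
khop_reachability <- function(net, k) {
  stopifnot(inherits(net, "cytokine_network"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop_ivd("`k` must be an integer >= 1.", "bad_k")
  }
  a <- matrix(as.numeric(net$adjacency), length(net$nodes),
              dimnames = dimnames(net$adjacency))
  reach <- a
  if (k > 1) {
    for (i in 2:k) reach <- 1 * ((reach + reach %*% a) > 0)
  }
  diag(reach) <- 0
  structure(list(R = reach, k = as.integer(k), nodes = net$nodes),
            class = "reachability_matrix")
}

#' @export
print.reachability_matrix <- function(x, ...) {
  cat(sprintf("<reachability_matrix> k = %d, %d nodes, %d reachable pairs\n",
              x$k, length(x$nodes), sum(x$R) / 2))
  invisible(x)
}
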