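# Louvain modularity maximization (resolution 1) on the unweighted network,
# with seeded node-visit order. Aggregated levels use the standard weighted
# formulation; the diagonal of an aggregated weight matrix holds twice the
# internal loop weight so node strength is the plain row sum.

louvain_one_level <- function(w, order_fn) {
  n <- nrow(w)
  two_m <- sum(w)
  strength <- rowSums(w)
  comm <- seq_len(n)
  sigma_tot <- strength  # community strength totals
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order_fn(n)) {
      ci <- comm[i]
      # weights from i to each community (self-loop excluded from links)
      wi <- w[i, ]
      wi[i] <- 0
      nbr <- which(wi > 0)
      links <- tapply(wi[nbr], comm[nbr], sum)
      sigma_tot[ci] <- sigma_tot[ci] - strength[i]
      cand <- unique(c(ci, as.integer(names(links))))
      gain <- vapply(cand, function(cc) {
        l <- if (as.character(cc) %in% names(links)) links[[as.character(cc)]] else 0
        l - strength[i] * sigma_tot[cc] / two_m
      }, numeric(1))
      best <- cand[which.max(gain)]  # ties: first candidate in visit order
      sigma_tot[best] <- sigma_tot[best] + strength[i]
      if (best != ci) {
        comm[i] <- best
        moved <- TRUE
        improved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = match(comm, unique(comm)), improved = improved_any)
}

louvain_aggregate <- function(w, membership) {
  k <- max(membership)
  agg <- matrix(0, k, k)
  for (a in seq_len(k)) {
    ra <- membership == a
    for (b in a:k) {
      rb <- membership == b
      agg[a, b] <- agg[b, a] <- sum(w[ra, rb, drop = FALSE])
    }
  }
  agg
}

#' Louvain community detection on a cytokine network
#'
#' Greedy modularity maximization (Newman-Girvan modularity, resolution 1):
#' repeated local-move passes over the nodes in a seeded shuffled order,
#' followed by community aggregation, until no pass improves modularity.
#' Ties in modularity gain are broken by the first candidate encountered in
#' visit order. The returned Q is the modularity of the returned partition
#' on the original unweighted graph.
#'
#' @param net A `cytokine_network` with at least one edge.
#' @param seed Integer seed controlling the node visit order.
#'
#' @return A `community_partition`: list with `membership` tibble
#'   (`cytokine`, `community`) and `modularity`.
#' @export
#' @examples
#' tri2 <- network_from_edges(data.frame(
#'   source = c("a", "b", "c", "d", "e", "f"),
#'   target = c("b", "c", "a", "e", "f", "d")))
#' louvain_communities(tri2, seed = 1)$modularity # 0.5
louvain_communities <- function(net, seed) {
  stopifnot(inherits(net, "cytokine_network"))
  if (sum(net$adjacency) == 0) {
    stop_ivd("Louvain requires at least one edge.", "empty_graph")
  }
  w <- matrix(as.numeric(net$adjacency), length(net$nodes))
  membership <- seq_along(net$nodes)
  with_seed(seed, {
    repeat {
      lev <- louvain_one_level(w, function(n) sample.int(n))
      if (!lev$improved) break
      membership <- lev$membership[membership]
      w <- louvain_aggregate(w, lev$membership)
      if (nrow(w) == 1) break
    }
  })
  membership <- match(membership, unique(membership))
  q <- modularity_q(net, membership)
  structure(
    list(
      membership = tibble(cytokine = net$nodes, community = membership),
      modularity = q, n_communities = max(membership), seed = seed
    ),
    class = "community_partition"
  )
}

#' Newman-Girvan modularity of a node partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `m` is the edge count, `e_c`
#' the number of intra-community edges and `d_c` the degree sum of
#' community c.
#'
#' @param net A `cytokine_network` with at least one edge.
#' @param membership Integer community id per node (in node order).
#' @return Modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(net, membership) {
  stopifnot(inherits(net, "cytokine_network"),
            length(membership) == length(net$nodes))
  adj <- net$adjacency
  m <- sum(adj) / 2
  if (m == 0) stop_ivd("Modularity undefined on an edgeless graph.", "empty_graph")
  deg <- rowSums(adj)
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' @export
tidy.community_partition <- function(x, ...) x$membership

#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_communities = x$n_communities, modularity = x$modularity)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes; 1
#' for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of planted co-regulation blocks.
#'
#' @param a,b Vectors of community labels of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
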