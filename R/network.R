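#' Threshold a correlation matrix into a cytokine interaction network
#'
#' An undirected, unweighted graph over the cytokines: an edge joins i and
#' j exactly when `|r_ij| > tau` (strict). Negative correlations produce
#' edges because the criterion is the absolute value; undefined
#' correlations never do. Isolated nodes are retained in the node set. The
#' underlying r is kept as an edge attribute only — all graph metrics treat
#' edges as unweighted.
#'
#' @param corr A [correlation_matrix()], or a plain symmetric numeric
#'   matrix with dimnames.
#' @param tau Threshold in \[0, 1) (default 0.7).
#'
#' @return A `cytokine_network`: list with `nodes`, logical `adjacency`,
#'   numeric `r`, and `tau`.
#' @export
threshold_network <- function(corr, tau = 0.7) {
  check_scalar_number(tau, "tau", 0, 1, strict_upper = TRUE)
  r <- if (inherits(corr, "correlation_matrix")) corr$r else corr
  stopifnot(is.matrix(r), nrow(r) == ncol(r), !is.null(rownames(r)))
  adj <- !is.na(r) & abs(r) > tau
  diag(adj) <- FALSE
  adj <- adj & t(adj)  # defensive symmetrization
  structure(
    list(nodes = rownames(r), adjacency = adj, r = r, tau = tau,
         group = if (inherits(corr, "correlation_matrix")) corr$group else NA_character_),
    class = "cytokine_network"
  )
}

#' Build a cytokine network directly from an edge list
#'
#' Convenience constructor used for tests, worked examples and reading
#' exported edge lists.
#'
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `r` (defaults to 1).
#' @param nodes Node label superset (defaults to the labels in `edges`).
#' @param tau Threshold to record (default 0.7).
#'
#' @return A `cytokine_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL, tau = 0.7) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (is.null(edges$r)) edges$r <- rep(1, nrow(edges))
  nodes <- union(nodes, union(edges$source, edges$target))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  r <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  diag(r) <- 1
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    if (a == b) stop_ivd("Self-loops are not allowed.", "bad_edge")
    adj[a, b] <- adj[b, a] <- TRUE
    r[a, b] <- r[b, a] <- edges$r[i]
  }
  structure(list(nodes = nodes, adjacency = adj, r = r, tau = tau,
                 group = NA_character_),
            class = "cytokine_network")
}

#' Edge table of a cytokine network
#'
#' @param net A `cytokine_network`.
#' @return Tibble `source`, `target`, `r` (one row per unordered edge).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "cytokine_network"))
  idx <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
  tibble(source = net$nodes[idx[, 1]], target = net$nodes[idx[, 2]],
         r = net$r[idx])
}

#' @export
print.cytokine_network <- function(x, ...) {
  cat(sprintf("<cytokine_network> %d nodes, %d edges (|r| > %g)%s\n",
              length(x$nodes), sum(x$adjacency) / 2, x$tau,
              if (!is.na(x$group)) paste0(", group '", x$group, "'") else ""))
  invisible(x)
}

#' Convert a cytokine network to an igraph object
#'
#' Used for layout and GraphML export; all analysis metrics are computed
#' natively on the adjacency matrix.
#'
#' @param net A `cytokine_network`.
#' @return An undirected `igraph` graph with edge attribute `r`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cytokine_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency * 1, mode = "undirected")
  ed <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(ed) > 0) {
    igraph::E(g)$r <- net$r[cbind(ed[, 1], ed[, 2])]
  }
  g
}

#' Number of nodes and edges, density, and components of a network
#'
#' @param x A `cytokine_network`.
#' @param ... Unused.
#' @return One-row tibble of summary statistics.
#' @export
glance.cytokine_network <- function(x, ...) {
  n <- length(x$nodes)
  m <- sum(x$adjacency) / 2
  comp <- components_of(x$adjacency)
  tibble(
    nodes = n, edges = m,
    density = if (n > 1) m / (n * (n - 1) / 2) else NA_real_,
    n_components = length(unique(comp)),
    n_isolated = sum(rowSums(x$adjacency) == 0),
    tau = x$tau
  )
}
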