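#' Shared and unique top-ranking hub cytokines across models
#'
#' For each centrality metric, ranks cytokines per model by (value
#' descending, name ascending — the deterministic tie-break), takes the top
#' `top_k`, and reports the intersection across all models (`shared`) plus,
#' per model, the cytokines in its top set and no other model's
#' (`unique`).
#'
#' @param tables Named list of [centralities()] tables, one per model.
#' @param top_k Number of top cytokines per metric and model (default 5).
#' @param metrics Centrality columns to rank on.
#'
#' @return A tibble: `metric`, `set` ("shared" or "unique"), `model`
#'   (`NA` for shared rows), `cytokine`.
#' @export
rank_hubs <- function(tables, top_k = 5,
                      metrics = c("eigenvector", "betweenness")) {
  if (!is.list(tables) || is.null(names(tables)) || length(tables) < 2) {
    stop_ivd("`tables` must be a named list of at least 2 centrality tables.",
             "bad_argument")
  }
  if (top_k < 1) stop_ivd("`top_k` must be >= 1.", "bad_argument")
  purrr::map_dfr(metrics, function(metric) {
    tops <- lapply(tables, function(tab) {
      stopifnot(all(c("cytokine", metric) %in% names(tab)))
      ord <- order(-tab[[metric]], tab$cytokine)
      tab$cytokine[ord][seq_len(min(top_k, nrow(tab)))]
    })
    shared <- Reduce(intersect, tops)
    shared_rows <- if (length(shared) > 0) {
      tibble(metric = metric, set = "shared", model = NA_character_,
             cytokine = sort(shared))
    } else tibble()
    uniq_rows <- purrr::imap_dfr(tops, function(top, model) {
      others <- unique(unlist(tops[setdiff(names(tops), model)]))
      u <- setdiff(top, others)
      if (length(u) == 0) return(tibble())
      tibble(metric = metric, set = "unique", model = model, cytokine = sort(u))
    })
    bind_rows(shared_rows, uniq_rows)
  })
}

#' Jaccard similarity between two reachability matrices
#'
#' Node sets are aligned by label union (a node absent from one network
#' contributes all-zero rows and columns there); the index is computed over
#' unordered off-diagonal pairs:
#' `J = |pairs reachable in both| / |pairs reachable in either|`.
#' Two all-zero matrices over identical node sets compare as J = 1
#' (identical empty relations).
#'
#' @param a,b `reachability_matrix` objects with the same `k`.
#'
#' @return A one-row tibble: `k`, `jaccard`, `n_both`, `n_either`,
#'   `n_nodes`.
#' @export
#' @examples
#' net1 <- network_from_edges(data.frame(source = c("a", "b"), target = c("b", "c")))
#' net2 <- network_from_edges(data.frame(source = c("b", "c"), target = c("c", "d")))
#' jaccard_similarity(khop_reachability(net1, 1), khop_reachability(net2, 1))
jaccard_similarity <- function(a, b) {
  stopifnot(inherits(a, "reachability_matrix"), inherits(b, "reachability_matrix"))
  if (a$k != b$k) stop_ivd("Reachability matrices have different k.", "mismatched_k")
  nodes <- union(a$nodes, b$nodes)
  expand <- function(rm) {
    m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    m[rm$nodes, rm$nodes] <- rm$R
    m
  }
  ra <- expand(a); rb <- expand(b)
  ut <- upper.tri(ra)
  both <- sum(ra[ut] > 0 & rb[ut] > 0)
  either <- sum(ra[ut] > 0 | rb[ut] > 0)
  j <- if (either == 0) {
    if (setequal(a$nodes, b$nodes)) 1 else NaN
  } else {
    both / either
  }
  tibble(k = a$k, jaccard = j, n_both = both, n_either = either,
         n_nodes = length(nodes))
}

#' Force-directed layout and styling tables for network plots
#'
#' Seeded Fruchterman-Reingold layout with nodes coloured by eigenvector
#' centrality and sized by betweenness centrality, exported as plain
#' node/edge tables consumable by any plotting tool.
#'
#' @param net A `cytokine_network`.
#' @param centrality A [centralities()] table computed on the same network.
#' @param seed Integer seed; identical seeds give identical coordinates.
#'
#' @return A list of tibbles: `nodes` (`cytokine`, `x`, `y`,
#'   `color_value` = eigenvector, `size_value` = betweenness) and `edges`
#'   (`source`, `target`, `r`, plus endpoint coordinates).
#' @export
layout_export <- function(net, centrality = centralities(net), seed = 1) {
  stopifnot(inherits(net, "cytokine_network"))
  if (!setequal(centrality$cytokine, net$nodes)) {
    stop_ivd("Centrality table does not match the network's nodes.",
             "node_mismatch")
  }
  g <- as_igraph(net)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(
    cytokine = net$nodes, x = xy[, 1], y = xy[, 2]
  ) %>%
    left_join(centrality %>%
                select("cytokine", color_value = "eigenvector",
                       size_value = "betweenness"),
              by = "cytokine")
  edges <- network_edges(net) %>%
    left_join(nodes %>% select("cytokine", x_source = "x", y_source = "y"),
              by = c(source = "cytokine")) %>%
    left_join(nodes %>% select("cytokine", x_target = "x", y_target = "y"),
              by = c(target = "cytokine"))
  list(nodes = nodes, edges = edges)
}
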