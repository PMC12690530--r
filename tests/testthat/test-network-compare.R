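test_that("Jaccard similarity satisfies its contract", {
  net <- net_from_adj(random_adj(6, 0.4, seed = 2))
  r1 <- khop_reachability(net, 1)
  expect_equal(jaccard_similarity(r1, r1)$jaccard, 1)

  # hand case: {ab, bc} vs {bc, cd} over {a, b, c, d} -> 1/3
  n1 <- network_from_edges(data.frame(source = c("a", "b"), target = c("b", "c")),
                           nodes = letters[1:4])
  n2 <- network_from_edges(data.frame(source = c("b", "c"), target = c("c", "d")),
                           nodes = letters[1:4])
  expect_equal(
    jaccard_similarity(khop_reachability(n1, 1), khop_reachability(n2, 1))$jaccard,
    1 / 3
  )

  # disjoint non-empty reach sets -> 0
  d1 <- network_from_edges(data.frame(source = "a", target = "b"),
                           nodes = letters[1:4])
  d2 <- network_from_edges(data.frame(source = "c", target = "d"),
                           nodes = letters[1:4])
  expect_equal(
    jaccard_similarity(khop_reachability(d1, 1), khop_reachability(d2, 1))$jaccard,
    0
  )

  # mismatched k is an error
  expect_error(jaccard_similarity(khop_reachability(n1, 1), khop_reachability(n2, 2)),
               class = "ivdnet_mismatched_k")
})

test_that("Jaccard is symmetric and bounded over random matrix pairs", {
  for (i in 1:100) {
    na <- net_from_adj(random_adj(6, 0.35, seed = 9000 + i))
    nb <- net_from_adj(random_adj(6, 0.35, seed = 9500 + i))
    k <- 1 + i %% 2
    ra <- khop_reachability(na, k)
    rb <- khop_reachability(nb, k)
    ja <- jaccard_similarity(ra, rb)$jaccard
    jb <- jaccard_similarity(rb, ra)$jaccard
    if (is.nan(ja)) {
      expect_true(is.nan(jb))
    } else {
      expect_equal(ja, jb)
      expect_gte(ja, 0)
      expect_lte(ja, 1)
    }
  }
})

test_that("Jaccard aligns node sets by label union", {
  # same edge {a-b}, but one network knows an extra isolated node
  n1 <- network_from_edges(data.frame(source = "a", target = "b"))
  n2 <- network_from_edges(data.frame(source = "a", target = "b"),
                           nodes = c("a", "b", "zzz"))
  j <- jaccard_similarity(khop_reachability(n1, 1), khop_reachability(n2, 1))
  expect_equal(j$jaccard, 1)
  expect_equal(j$n_nodes, 3)
})

test_that("hub ranking reports shared and unique top cytokines deterministically", {
  tab <- function(vals) {
    tibble::tibble(cytokine = names(vals), eigenvector = unname(vals),
                   betweenness = unname(vals))
  }
  t1 <- tab(c(A = 5, B = 4, C = 3, D = 2, E = 1))
  hubs_same <- rank_hubs(list(m1 = t1, m2 = t1), top_k = 3)
  ev <- hubs_same[hubs_same$metric == "eigenvector", ]
  expect_setequal(ev$cytokine[ev$set == "shared"], c("A", "B", "C"))
  expect_equal(sum(ev$set == "unique"), 0)

  t2 <- tab(c(A = 0, B = 0, C = 0, X = 9, Y = 8, Z = 7))
  hubs_disjoint <- rank_hubs(list(m1 = t1, m2 = t2), top_k = 3)
  ev2 <- hubs_disjoint[hubs_disjoint$metric == "eigenvector", ]
  expect_equal(sum(ev2$set == "shared"), 0)
  expect_setequal(ev2$cytokine[ev2$model %in% "m1"], c("A", "B", "C"))
  expect_setequal(ev2$cytokine[ev2$model %in% "m2"], c("X", "Y", "Z"))

  # engineered tie at rank k: lexicographic name order decides inclusion
  t3 <- tab(c(M = 5, Z = 3, B = 3, Q = 1))
  hubs_tie <- rank_hubs(list(m1 = t3, m2 = t3), top_k = 2)
  ev3 <- hubs_tie[hubs_tie$metric == "eigenvector", ]
  expect_setequal(ev3$cytokine[ev3$set == "shared"], c("B", "M"))

  expect_error(rank_hubs(list(m1 = t1, m2 = t2), top_k = 0),
               class = "ivdnet_bad_argument")
})

test_that("layout export is seeded-deterministic and styles by centrality", {
  k3 <- complete_net(c("a", "b", "c"))
  l1 <- layout_export(k3, seed = 11)
  l2 <- layout_export(k3, seed = 11)
  expect_identical(l1$nodes, l2$nodes)
  expect_equal(length(unique(round(l1$nodes$color_value, 12))), 1)  # K3 symmetry
  l3 <- layout_export(k3, seed = 12)
  expect_false(identical(l1$nodes$x, l3$nodes$x))

  # empty edge set: nodes still placed
  edgeless <- net_from_adj(matrix(FALSE, 4, 4))
  le <- layout_export(edgeless, seed = 1)
  expect_equal(nrow(le$nodes), 4)
  expect_equal(nrow(le$edges), 0)
  expect_true(all(is.finite(le$nodes$x)))

  bad_cent <- centralities(k3)
  bad_cent$cytokine <- c("x", "y", "z")
  expect_error(layout_export(k3, bad_cent), class = "ivdnet_node_mismatch")
})
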