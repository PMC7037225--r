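chain_net <- function() {
  signaling_network(data.frame(source = c("a", "b"),
                               target = c("b", "c")),
                    tf_nodes = "c")
}

test_that("upstream reach: radius bound, self distance, igraph oracle", {
  net <- chain_net()
  d2 <- upstream_reach(net, "c", radius = 2)
  expect_equal(d2["a", "c"], 2)
  expect_equal(d2["b", "c"], 1)
  expect_equal(d2["c", "c"], 0)   # a TF reaches itself at distance 0
  d1 <- upstream_reach(net, "c", radius = 1)
  expect_equal(d1["a", "c"], Inf)

  expect_error(upstream_reach(net, character(0)), "empty tf_set")

  skip_if_not_installed("igraph")
  sim <- simulate_network(n_nodes = 100, n_tfs = 15, edge_density = 0.03,
                          n_active_tfs = 8, seed = 3)
  net2 <- sim$network
  D <- upstream_reach(net2, net2$tf_nodes, radius = 12)
  g <- igraph::graph_from_data_frame(net2$edges, directed = TRUE,
                                     vertices = net2$nodes)
  ref <- igraph::distances(g, v = net2$nodes, to = net2$tf_nodes,
                           mode = "out")
  ref[ref > 12] <- Inf
  expect_equal(unname(D), unname(ref[net2$nodes, net2$tf_nodes]))
})

test_that("key-node score closed forms and monotonicity", {
  D <- matrix(Inf, 2, 1, dimnames = list(c("u", "v"), "t"))
  deg <- c(u = 0L, v = 0L, t = 0L)
  expect_equal(unname(key_node_score(D, deg)["u"]), 0)

  D["v", "t"] <- 1
  expect_equal(unname(key_node_score(D, deg, beta = 0.5)["v"]), 0.5)

  # reaching a superset of TFs at equal distances never lowers S
  set.seed(19)
  for (i in 1:20) {
    ntf <- sample(3:8, 1)
    d1 <- sample(c(1:4, Inf), ntf, TRUE)
    d2 <- d1
    unreached <- which(is.infinite(d1))
    if (length(unreached) > 0)
      d2[unreached[[1]]] <- sample(1:4, 1)
    DD <- rbind(u = d1, w = d2)
    colnames(DD) <- paste0("t", seq_len(ntf))
    s <- key_node_score(DD, c(u = 3L, w = 3L))
    expect_gte(s[["w"]], s[["u"]])
  }

  # increasing the radius never decreases any node's score
  sim <- simulate_network(seed = 8)
  net <- sim$network
  tfs <- sim$truth$active_tfs
  deg <- setNames(rep(0L, length(net$nodes)), net$nodes)
  for (r in c(2, 6, 12)) {
    s_lo <- key_node_score(upstream_reach(net, tfs, r), deg)
    s_hi <- key_node_score(upstream_reach(net, tfs, r + 1), deg)
    expect_true(all(s_hi >= s_lo - 1e-12))
  }
})

test_that("scores are invariant under node relabeling", {
  sim <- simulate_network(n_nodes = 30, n_tfs = 6, edge_density = 0.08,
                          n_active_tfs = 4, seed = 12)
  net <- sim$network
  tfs <- sim$truth$active_tfs
  s1 <- key_node_score(upstream_reach(net, tfs, 12),
                       setNames(rep(0L, 30), net$nodes))
  perm <- setNames(sprintf("x%02d", sample(30)), net$nodes)
  net2 <- signaling_network(
    data.frame(source = unname(perm[net$edges$source]),
               target = unname(perm[net$edges$target])),
    tf_nodes = unname(perm[net$tf_nodes]),
    nodes = unname(perm[net$nodes]))
  s2 <- key_node_score(upstream_reach(net2, unname(perm[tfs]), 12),
                       setNames(rep(0L, 30), net2$nodes))
  expect_equal(unname(s2[perm[names(s1)]]), unname(s1))
})

test_that("permutation null is seed-stable and self-consistent", {
  sim <- simulate_network(seed = 2)
  net <- sim$network
  tfs <- sim$truth$active_tfs
  # distances-to-subset equal the column subset of distances-to-all, so
  # an injected observed set reproduces the observed scores exactly
  D_all <- upstream_reach(net, net$tf_nodes, 12)
  D_sub <- upstream_reach(net, tfs, 12)
  expect_equal(D_all[, tfs], D_sub)
  deg <- setNames(rep(0L, length(net$nodes)), net$nodes)
  expect_equal(key_node_score(D_all[, tfs], deg),
               key_node_score(D_sub, deg))

  # a symmetric-TF null: distribution stable across disjoint seeds
  null1 <- permutation_null(net, length(tfs),
                            mr_params(n_permutations = 150, seed = 1))
  null2 <- permutation_null(net, length(tfs),
                            mr_params(n_permutations = 150, seed = 2))
  ks <- suppressWarnings(stats::ks.test(as.numeric(null1),
                                        as.numeric(null2)))
  expect_gt(ks$p.value, 0.01)

  expect_error(permutation_null(net, length(net$tf_nodes) + 1),
               "set_size")
})

test_that("ranking: FDR guard, sentinels, empty selection", {
  scores <- c(a = 2, b = 1, c = 0)
  null1 <- matrix(c(0.5, 0.2, 0), 3, 1,
                  dimnames = list(c("a", "b", "c"), NULL))
  res <- rank_and_select(scores, null1, mr_params(n_permutations = 1))
  # FDR output refused below 100 permutations; z falls back to sentinel
  expect_true(all(is.na(res$fdr)))
  expect_equal(res$z_score, c(Inf, Inf))
  expect_equal(res$rank, 1:2)          # c has S = 0 and is not reported
  expect_false(any(res$selected))

  # all-zero scores: nothing reported, nothing selected
  null2 <- matrix(0, 3, 120, dimnames = list(c("a", "b", "c"), NULL))
  res0 <- rank_and_select(c(a = 0, b = 0, c = 0), null2, mr_params())
  expect_equal(nrow(res0), 0L)
})

test_that("planted regulator is recovered; null stays calibrated", {
  sim <- simulate_network(seed = 2)
  pl <- unique(sim$truth$planted_regulators$node)
  mr <- find_master_regulators(sim$network, sim$truth$active_tfs,
                               mr_params(n_permutations = 200, seed = 5))
  expect_lte(mr$rank[mr$node == pl], 3L)
  expect_lt(mr$fdr[mr$node == pl], 0.05)
  expect_true(all(diff(mr$fdr) >= -1e-12))   # monotone down the ranking
  expect_equal(mr$rank, seq_len(nrow(mr)))

  # a random TF set as "observed": false selections at most nominal
  set.seed(77)
  sel_rates <- replicate(10, {
    tfs <- sample(sim$network$tf_nodes, 12)
    res <- find_master_regulators(sim$network, tfs,
                                  mr_params(n_permutations = 120,
                                            seed = sample.int(1e6, 1)))
    sum(res$selected) / max(1, nrow(res))
  })
  expect_lte(mean(sel_rates), 0.05)
})
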