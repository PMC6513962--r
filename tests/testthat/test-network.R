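make_dce_fixture <- function() {
  tibble::tibble(
    gene_i = c("a", "a", "b", "c", "d"),
    gene_j = c("b", "c", "c", "d", "e"),
    r_a = c(0.5, 0.1, -0.45, 0.2, 0.9),
    r_b = c(0.2, 0.1, -0.1, 0.19, 0.89),
    n_a = 200, n_b = 200,
    p_a = c(1e-6, 0.3, 1e-5, 0.2, 1e-20),
    p_b = c(0.2, 0.3, 0.4, 0.2, 1e-19),
    Z = c(3, 0.1, -4, 0.1, 0.2),
    p = c(0.001, 0.9, 1e-5, 0.9, 0.8),
    p_adj = c(0.005, 1, 1e-4, 1, 1),
    class = classify_pair(c(0.5, 0.1, -0.45, 0.2, 0.9),
                          c(1e-6, 0.3, 1e-5, 0.2, 1e-20),
                          c(0.2, 0.1, -0.1, 0.19, 0.89),
                          c(0.2, 0.3, 0.4, 0.2, 1e-19))
  )
}

test_that("core network applies edge rules and removes islands", {
  dce <- make_dce_fixture()
  net <- build_core_network(c("a", "b", "c", "f"), dce)
  # a-b: |r_a| = 0.5 > 0.3 AND p_adj < 0.01 -> both types
  ab <- net$edges[net$edges$gene_i == "a" & net$edges$gene_j == "b", ]
  expect_true(ab$coexpression && ab$dce)
  # b-c: |r_a| = 0.45 -> coexpression; p_adj 1e-4 -> dce
  bc <- net$edges[net$edges$gene_i == "b" & net$edges$gene_j == "c", ]
  expect_true(bc$coexpression && bc$dce)
  # a-c: r_a = 0.1, p_adj = 1 -> no edge; but c connects through b
  expect_equal(nrow(net$edges), 2)
  # f never qualifies: island, absent from nodes
  expect_equal(net$islands, "f")
  expect_false("f" %in% net$nodes$gene)
  # conservation: islands + connected = selection
  expect_setequal(c(net$nodes$gene, net$islands), c("a", "b", "c", "f"))

  # dce-only edge when correlation is weak
  dce2 <- dce
  dce2$r_a[1] <- 0.1
  net2 <- build_core_network(c("a", "b"), dce2)
  expect_true(net2$edges$dce && !net2$edges$coexpression)

  # coexpression-only edge when the pair never changed
  dce3 <- dce
  dce3$p_adj[1] <- 0.5
  net3 <- build_core_network(c("a", "b"), dce3)
  expect_true(net3$edges$coexpression && !net3$edges$dce)

  # input order does not matter
  net4 <- build_core_network(c("a", "b", "c", "f"), dce[sample(5), ])
  expect_equal(net4$edges, net$edges)
  expect_error(build_core_network(character(0), dce), "empty")
})

test_that("edge direction annotation summarizes change classes", {
  dce <- make_dce_fixture()
  net <- annotate_edge_directions(build_core_network(c("a", "b", "c"), dce))
  s <- net$edge_summary
  expect_equal(s$n_dce, 2)
  # a-b is A_only (sig only in A); b-c reversed? r_b not significant -> A_only
  expect_equal(s$n_increased, 2)
  expect_equal(s$n_condition_specific, 2)
  # one of the two coexpression edges has negative disease-state r
  expect_equal(s$negative_fraction, 0.5)
  gl <- glance(net)
  expect_equal(gl$n_nodes, 3)
  expect_equal(gl$n_islands, 0)
  expect_equal(gl$negative_fraction, 0.5)
})

test_that("subnetworks carry the hub's partners and their classes", {
  dce <- make_dce_fixture()
  sub <- extract_subnetwork("c", dce, cutoff = 0.01)
  expect_equal(sub$members$gene, "b")
  expect_equal(as.character(sub$members$class), "A_only")
  expect_error(extract_subnetwork("e", dce), "no DCE partners")
  td <- tidy(sub)
  expect_equal(td$hub, "c")

  # planted hub: nearly all members strengthened in condition A
  spec <- sim_spec(150, c(500, 500), hubs = list(hub_spec(1, 2:101, 0.7, 0)),
                   seed = 17)
  ds <- simulate_dataset(spec)
  dce_sim <- dce_table(coexpression_table(ds$expr_a),
                       coexpression_table(ds$expr_b))
  sub2 <- extract_subnetwork("g00001", dce_sim)
  expect_gte(nrow(sub2$members), 95)
  frac_gain <- mean(sub2$members$class %in% c("increased", "A_only"))
  expect_gte(frac_gain, 0.95)
})

test_that("subnetwork enrichment ranks planted sets first", {
  members <- sprintf("g%03d", 1:100)
  universe <- sprintf("g%03d", 1:1000)
  hit_set <- c(sprintf("g%03d", 1:60), sprintf("g%03d", 900:939))  # 60% of members
  null_set <- sprintf("g%03d", 500:599)
  sub <- structure(list(hub = "hub",
                        members = tibble::tibble(gene = members)),
                   class = "subnetwork")
  enr <- subnetwork_enrichment(sub, list(hit = hit_set, none = sprintf("x%d", 1:5),
                                         null = null_set), universe)
  expect_equal(enr$set[1], "hit")
  expect_lt(enr$p[enr$set == "hit"], 1e-6)
  # a member-disjoint set gives x = 0 and p = 1
  expect_equal(enr$x[enr$set == "null"], 0)
  expect_equal(enr$p[enr$set == "null"], 1)
  # a set entirely outside the universe is untestable
  expect_true(is.na(enr$p[enr$set == "none"]))
})

test_that("TF ranking sorts by signed correlation with rank bookkeeping", {
  pairs <- tibble::tibble(
    gene_i = c("tgt", "tgt", "b", "tgt"),
    gene_j = c("tf1", "tf2", "tf3", "tf3"),
    r = c(-0.62, 0.4, 0.9, -0.1)
  )
  rk <- rank_tf_coexpression("tgt", c("tf1", "tf2", "tf3"), pairs)
  expect_equal(rk$tf, c("tf1", "tf3", "tf2"))
  expect_equal(rk$rank_negative, 1:3)
  expect_setequal(rk$rank_abs, 1:3)
  expect_equal(rk$rank_abs[rk$tf == "tf1"], 1)
  expect_warning(rank_tf_coexpression("tgt", c("tgt", "tf1"), pairs), "removed")
  expect_error(rank_tf_coexpression("tgt", c("tf9"), pairs), "lacks")

  # a TF planted at rho = -0.6 among null TFs ranks first
  spec <- sim_spec(30, c(400, 10), blocks = list(block_spec(1:2, -0.6, 0)),
                   seed = 19)
  ds <- simulate_dataset(spec)
  pa <- spearman_all_pairs(ds$expr_a)
  tfs <- sprintf("g%05d", c(2, 10:20))
  rk2 <- rank_tf_coexpression("g00001", tfs, pa)
  expect_equal(rk2$tf[1], "g00002")
})

test_that("two planted hub communities come out as the network components", {
  spec <- sim_spec(300, c(500, 500),
                   hubs = list(hub_spec(1, 2:30, 0.7, 0),
                               hub_spec(31, 32:60, 0.7, 0)),
                   seed = 23)
  ds <- simulate_dataset(spec)
  dce <- dce_table(coexpression_table(ds$expr_a),
                   coexpression_table(ds$expr_b))
  selected <- sprintf("g%05d", 1:60)
  net <- build_core_network(selected, dce)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  truth_comm <- rep(1:2, each = 30)
  names(truth_comm) <- selected
  found <- comp$membership[selected]
  # perfect recovery up to label swap
  tab <- table(truth_comm, found)
  expect_equal(sort(apply(tab, 1, max)), c(30, 30), ignore_attr = TRUE)

  # GraphML + edge list round trip
  dir <- withr::local_tempdir()
  write_core_network(net, graphml = file.path(dir, "net.graphml"),
                     edges_tsv = file.path(dir, "edges.tsv"))
  g2 <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g2), igraph::gorder(g))
  expect_equal(igraph::gsize(g2), igraph::gsize(g))
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"), show_col_types = FALSE)
  expect_equal(nrow(edges), nrow(net$edges))
})
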