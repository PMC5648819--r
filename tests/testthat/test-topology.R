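make_net <- function(edges, kinds = NULL) {
  ids <- sort(unique(c(edges$node_a, edges$node_b)))
  kinds <- kinds %||% stats::setNames(rep("mRNA", length(ids)), ids)
  mi_network(
    nodes = tibble::tibble(node = ids, kind = unname(kinds[ids])),
    edges = dplyr::mutate(edges, mi = 0.5,
                          class = mapply(function(a, b) {
                            mirnet:::edge_class_of(kinds[[a]], kinds[[b]])
                          }, edges$node_a, edges$node_b))
  )
}

test_that("largest component picks the biggest, with lexicographic tie-break", {
  e <- tibble::tibble(node_a = c("a", "b", "c", "f", "g"),
                      node_b = c("b", "c", "d", "g", "h"))
  net <- make_net(e)  # components {a,b,c,d} and {f,g,h}
  lc <- largest_component(net)
  expect_setequal(lc$nodes$node, c("a", "b", "c", "d"))
  # connected network returns itself
  conn <- make_net(tibble::tibble(node_a = c("a", "b"), node_b = c("b", "c")))
  expect_setequal(largest_component(conn)$nodes$node, c("a", "b", "c"))
  # 4 vs 4 tie: component holding the smallest id wins
  tie <- make_net(tibble::tibble(node_a = c("z1", "z2", "z3", "a1", "a2", "a3"),
                                 node_b = c("z2", "z3", "z4", "a2", "a3", "a4")))
  expect_setequal(largest_component(tie)$nodes$node, c("a1", "a2", "a3", "a4"))
})

test_that("degree table ranks hubs and reports family member degrees", {
  star <- make_net(tibble::tibble(node_a = rep("hub", 7),
                                  node_b = sprintf("leaf%d", 1:7)))
  dt <- degree_table(star)
  expect_identical(dt$node[1], "hub")
  expect_identical(dt$degree[1], 7L)

  fam <- tibble::tibble(feature_id = c("hub", "leaf1"), family = "famX")
  dtf <- degree_table(star, family_map = fam)
  expect_identical(dtf$families$max_degree, 7L)
  expect_identical(dtf$families$n_members, 2L)
  expect_setequal(names(dtf$families$member_degrees[[1]]), c("hub", "leaf1"))
})

test_that("degrees equal a brute-force incidence recount on random graphs", {
  for (seed in 1:10) {
    net <- random_network(n_nodes = 20, p_edge = 0.25, seed = seed)
    dt <- degree_table(net)
    e <- net$edges
    manual <- vapply(dt$node,
                     function(v) sum(e$node_a == v) + sum(e$node_b == v),
                     numeric(1))
    expect_identical(dt$degree, as.integer(manual))
  }
})

test_that("first neighbours form an induced subgraph", {
  path <- make_net(tibble::tibble(node_a = c("a", "b"), node_b = c("b", "c")))
  expect_setequal(first_neighbors(path, "b")$nodes$node, c("a", "b", "c"))
  fn_a <- first_neighbors(path, "a")
  expect_setequal(fn_a$nodes$node, c("a", "b"))
  expect_identical(nrow(fn_a$edges), 1L)
  # triangle + pendant: seeding a vertex of the triangle captures all
  # three triangle edges (induced), not only the seed-incident ones
  tri <- make_net(tibble::tibble(node_a = c("a", "a", "b", "c"),
                                 node_b = c("b", "c", "c", "d")))
  fn <- first_neighbors(tri, "a")
  expect_setequal(fn$nodes$node, c("a", "b", "c"))
  expect_identical(nrow(fn$edges), 3L)
  fn_inc <- first_neighbors(tri, "a", seed_incident_only = TRUE)
  expect_identical(nrow(fn_inc$edges), 2L)
  # missing seeds: skipped with warning; all missing -> empty with warning
  expect_warning(first_neighbors(tri, c("a", "zz")), "skipped")
  w <- testthat::capture_warnings(empty <- first_neighbors(tri, "zz"))
  expect_true(any(grepl("no seeds", w)))
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("first_neighbors is monotone in the seed set", {
  for (seed in 1:8) {
    net <- random_network(n_nodes = 15, p_edge = 0.2, seed = seed)
    seeds <- sample(net$nodes$node, 3)
    small <- suppressWarnings(first_neighbors(net, seeds[1:2]))
    big <- suppressWarnings(first_neighbors(net, seeds))
    expect_true(all(small$nodes$node %in% big$nodes$node))
    expect_gte(nrow(big$edges), nrow(small$edges))
  }
})

test_that("removing the miR hub of a bipartite star shatters it into singletons", {
  kinds <- stats::setNames(c("miR", rep("mRNA", 5)),
                           c("hub", sprintf("g%d", 1:5)))
  star <- make_net(tibble::tibble(node_a = rep("hub", 5),
                                  node_b = sprintf("g%d", 1:5)), kinds)
  res <- remove_kind(star, "miR")
  expect_identical(res$report$components_before, 1L)
  expect_identical(res$report$components_after, 5L)
  expect_identical(res$report$singletons_created, 5L)
  expect_identical(res$report$nodes_removed, 1L)
  expect_identical(res$report$edges_removed, 5L)
  # a pure mRNA clique is untouched
  clique_edges <- tidyr::expand_grid(node_a = sprintf("g%d", 1:4),
                                     node_b = sprintf("g%d", 1:4)) |>
    dplyr::filter(node_a < node_b)
  clique <- make_net(clique_edges)
  res2 <- remove_kind(clique, "miR")
  expect_identical(nrow(res2$network$nodes), 4L)
  expect_identical(res2$report$edges_removed, 0L)
  # idempotence
  res3 <- remove_kind(res$network, "miR")
  expect_identical(res3$network$nodes, res$network$nodes)
})

test_that("component counts after kind removal match a traversal oracle", {
  for (seed in 1:20) {
    net <- random_network(n_nodes = 25, p_edge = 0.12, mir_frac = 0.4,
                          seed = 100 + seed)
    res <- remove_kind(net, "miR")
    keep <- net$nodes$node[net$nodes$kind != "miR"]
    e <- net$edges[net$edges$node_a %in% keep & net$edges$node_b %in% keep, ]
    comp <- components_oracle(keep, e$node_a, e$node_b)
    expect_identical(res$report$components_after, max(c(comp, 0L)))
    sizes <- table(comp)
    expect_identical(res$report$singletons_after, sum(sizes == 1))
  }
})

test_that("network intersection keeps shared topology and annotates DE", {
  net <- random_network(n_nodes = 20, p_edge = 0.3, seed = 55)
  expect_identical(
    sort(paste(intersect_networks(net, net)$edges$node_a,
               intersect_networks(net, net)$edges$node_b)),
    sort(paste(net$edges$node_a, net$edges$node_b))
  )
  # disjoint edge sets: nodes only
  e1 <- net$edges[seq(1, nrow(net$edges), 2), ]
  e2 <- net$edges[seq(2, nrow(net$edges), 2), ]
  na <- mi_network(net$nodes, e1)
  nb <- mi_network(net$nodes, e2)
  inter <- intersect_networks(na, nb)
  expect_identical(nrow(inter$edges), 0L)
  expect_gt(nrow(inter$nodes), 0L)
  # DE overlay with a missing record
  de <- tibble::tibble(feature_id = net$nodes$node[-1],
                       log2fc = rnorm(nrow(net$nodes) - 1),
                       flag = "ns")
  inter2 <- intersect_networks(net, net, de)
  expect_true(is.na(inter2$nodes$log2fc[inter2$nodes$node == net$nodes$node[1]]))
  expect_false(anyNA(inter2$nodes$log2fc[-match(net$nodes$node[1],
                                                inter2$nodes$node)]))
})

test_that("edge-class summary counts and histograms conserve edges", {
  kinds <- stats::setNames(c("miR", "miR", "miR", "mRNA"),
                           c("m1", "m2", "m3", "g1"))
  net <- make_net(tibble::tibble(node_a = c("m1", "m1", "m1", "m2", "m2"),
                                 node_b = c("m2", "m3", "g1", "g1", "m3")),
                  kinds)
  net$edges$mi <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  s <- edge_class_summary(net)
  expect_identical(s$counts$n_edges[s$counts$class == "miR-miR"], 3L)
  expect_identical(s$counts$n_edges[s$counts$class == "miR-mRNA"], 2L)
  expect_identical(s$counts$n_edges[s$counts$class == "mRNA-mRNA"], 0L)
  agg <- tapply(s$histogram$n, s$histogram$class, sum)
  expect_identical(as.integer(agg[["miR-miR"]]), 3L)
  expect_identical(as.integer(agg[["miR-mRNA"]]), 2L)
})

test_that("positional table maps miRs to regions and buckets unknowns", {
  kinds <- stats::setNames(c("miR", "miR", "miR", "miR"),
                           c("m1", "m2", "m3", "m4"))
  net <- make_net(tibble::tibble(node_a = c("m1", "m2", "m3"),
                                 node_b = c("m2", "m3", "m4")), kinds)
  ann <- tibble::tibble(
    feature_id = c("m1", "m2", "m3"),
    kind = "miR", chromosome = c("chrS1", "chrS1", "chrS1"),
    start = c(1L, 100L, 200L), end = c(50L, 150L, 250L), strand = "+",
    family = NA_character_,
    cluster = c("clusterA", "clusterA", "clusterA")
  )
  expect_warning(pt <- positional_table(net, ann), "unknown")
  expect_identical(
    pt$regions$n_mirs[pt$regions$cluster == "clusterA" &
                        !is.na(pt$regions$cluster)], 3L)
  expect_identical(pt$mirs$chromosome[pt$mirs$node == "m4"], "unknown")
  # empty network -> empty tables
  empty <- mi_network(tibble::tibble(node = character(), kind = character()),
                      net$edges[0, ])
  expect_identical(nrow(positional_table(empty, ann)$mirs), 0L)
})
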