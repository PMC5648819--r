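#' Largest connected component
#'
#' Induced subnetwork on the maximum-cardinality connected node set; a tie
#' between equally sized components is broken toward the component
#' containing the lexicographically smallest node id.
#'
#' @param network an [mi_network()] (DPI-removed edges are ignored).
#' @return The induced [mi_network()] (empty network for empty input).
#' @export
largest_component <- function(network) {
  stopifnot(inherits(network, "mi_network"))
  if (nrow(network$nodes) == 0) return(network)
  g <- as_igraph(network)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  induced_network(network, keep)
}

# induced subnetwork on a node id set (live edges only)
induced_network <- function(network, node_ids) {
  nodes <- dplyr::filter(network$nodes, .data$node %in% node_ids)
  edges <- dplyr::filter(live_edges(network),
                         .data$node_a %in% node_ids & .data$node_b %in% node_ids)
  mi_network(nodes = nodes, edges = edges)
}

#' Node and family degree ranking
#'
#' Node degree is the incident live-edge count. When a family map is
#' supplied, the family table reports each family's member degrees and
#' their maximum (families are a grouping over mature miRs, not merged
#' nodes). Sorting is by degree descending, stable by id.
#'
#' @param network an [mi_network()].
#' @param family_map optional tibble `feature_id`, `family` (or an
#'   annotation table with those columns).
#' @return List of tibbles: `nodes` (`node`, `kind`, `degree`, `family`) and
#'   `families` (`family`, `max_degree`, `n_members`, `member_degrees`),
#'   or just the `nodes` tibble if `family_map` is `NULL`.
#' @export
degree_table <- function(network, family_map = NULL) {
  stopifnot(inherits(network, "mi_network"))
  e <- live_edges(network)
  deg <- table(factor(c(e$node_a, e$node_b), levels = network$nodes$node))
  nodes <- tibble(node = network$nodes$node, kind = network$nodes$kind,
                  degree = as.integer(deg[network$nodes$node]))
  nodes <- arrange(nodes, desc(.data$degree), .data$node)
  if (is.null(family_map)) return(nodes)
  fm <- as_tibble(family_map)
  if ("family" %in% names(fm) && "feature_id" %in% names(fm)) {
    fm <- fm[, c("feature_id", "family")]
  }
  nodes <- left_join(nodes, fm, by = c(node = "feature_id"))
  fams <- nodes |>
    filter(!is.na(.data$family)) |>
    group_by(.data$family) |>
    summarise(max_degree = max(.data$degree), n_members = n(),
              member_degrees = list(setNames(.data$degree, .data$node)),
              .groups = "drop") |>
    arrange(desc(.data$max_degree), .data$family)
  list(nodes = nodes, families = fams)
}

#' First-neighbour subnetwork
#'
#' Induced subgraph on the seed nodes plus all nodes adjacent to a seed.
#' Being induced, it includes neighbour-neighbour edges;
#' `seed_incident_only = TRUE` restricts edges to those touching a seed.
#'
#' @param network an [mi_network()].
#' @param seed_nodes character vector of node ids; missing seeds are
#'   skipped with a warning.
#' @param seed_incident_only drop neighbour-neighbour edges?
#' @return The first-neighbour [mi_network()].
#' @export
first_neighbors <- function(network, seed_nodes, seed_incident_only = FALSE) {
  stopifnot(inherits(network, "mi_network"))
  present <- intersect(seed_nodes, network$nodes$node)
  missing <- setdiff(seed_nodes, present)
  if (length(missing) > 0) {
    warn(sprintf("%d seed(s) absent from network, skipped.", length(missing)))
  }
  if (length(present) == 0) {
    warn("no seeds present; returning empty network.")
    return(mi_network(nodes = tibble(node = character(), kind = character()),
                      edges = network$edges[0, ]))
  }
  e <- live_edges(network)
  nbr <- unique(c(e$node_b[e$node_a %in% present], e$node_a[e$node_b %in% present]))
  keep <- union(present, nbr)
  out <- induced_network(network, keep)
  if (seed_incident_only) {
    out$edges <- dplyr::filter(out$edges,
                               .data$node_a %in% present | .data$node_b %in% present)
  }
  out
}

#' Remove all nodes of a kind and report the disintegration
#'
#' Deletes every node of the given kind together with its incident edges,
#' and reports how the component structure changes — the observable the
#' miR-ablation experiment measures: removing the miRs of a miR-centred
#' network shatters it into many singletons.
#'
#' @param network an [mi_network()].
#' @param kind `"miR"` (default) or `"mRNA"`.
#' @return List: `network` (the stripped [mi_network()]) and `report`, a
#'   one-row tibble with `components_before`, `components_after`,
#'   `singletons_before`, `singletons_after`, `singletons_created`,
#'   `nodes_removed`, `edges_removed`.
#' @export
remove_kind <- function(network, kind = "miR") {
  stopifnot(inherits(network, "mi_network"), kind %in% c("miR", "mRNA"))
  g <- as_igraph(network)
  comp_before <- igraph::components(g)
  singletons_before <- sum(comp_before$csize == 1)
  keep_ids <- network$nodes$node[network$nodes$kind != kind]
  stripped <- induced_network(network, keep_ids)
  g2 <- as_igraph(stripped)
  comp_after <- igraph::components(g2)
  singletons_after <- sum(comp_after$csize == 1)
  report <- tibble(
    components_before = as.integer(comp_before$no),
    components_after = as.integer(comp_after$no),
    singletons_before = as.integer(singletons_before),
    singletons_after = as.integer(singletons_after),
    singletons_created = as.integer(singletons_after - singletons_before),
    nodes_removed = nrow(network$nodes) - nrow(stripped$nodes),
    edges_removed = nrow(live_edges(network)) - nrow(live_edges(stripped))
  )
  list(network = stripped, report = report)
}

#' Intersect two networks, with optional expression overlay
#'
#' Nodes present in both inputs; edges whose unordered pair is present
#' (live) in both. Edge presence, not MI equality, defines the
#' intersection — MI magnitudes differ between conditions by construction.
#' When DE results are supplied each node is annotated with its log2FC and
#' DE flag (`NA` and a log message when missing).
#'
#' @param net_a,net_b [mi_network()] objects.
#' @param de_results optional [differential_expression()] tibble.
#' @return An [mi_network()]; edges carry `mi_a` and `mi_b`; nodes gain
#'   `log2fc` and `de_flag` columns when `de_results` is given.
#' @export
intersect_networks <- function(net_a, net_b, de_results = NULL) {
  stopifnot(inherits(net_a, "mi_network"), inherits(net_b, "mi_network"))
  nodes <- inner_join(net_a$nodes[, c("node", "kind")],
                      net_b$nodes[, "node", drop = FALSE], by = "node")
  ea <- live_edges(net_a)
  eb <- live_edges(net_b)
  common <- inner_join(
    ea[, c("node_a", "node_b", "mi", "class")],
    eb[, c("node_a", "node_b", "mi")],
    by = c("node_a", "node_b"), suffix = c("_a", "_b")
  )
  edges <- tibble(node_a = common$node_a, node_b = common$node_b,
                  mi = pmin(common$mi_a, common$mi_b), class = common$class,
                  mi_a = common$mi_a, mi_b = common$mi_b)
  if (!is.null(de_results)) {
    idx <- match(nodes$node, de_results$feature_id)
    if (anyNA(idx)) {
      inform(sprintf("%d node(s) without DE record annotated NA.", sum(is.na(idx))))
    }
    nodes$log2fc <- de_results$log2fc[idx]
    nodes$de_flag <- de_results$flag[idx]
  }
  mi_network(nodes = nodes, edges = edges)
}

#' Edge-class counts and MI histograms
#'
#' @param network an [mi_network()].
#' @param breaks histogram breaks (default 30 equal bins over the observed
#'   MI range).
#' @return List: `counts` (tibble `class`, `n_edges`, `mi_median`) and
#'   `histogram` (tibble `class`, `bin_lo`, `bin_hi`, `n`).
#' @export
edge_class_summary <- function(network, breaks = 30) {
  stopifnot(inherits(network, "mi_network"))
  e <- live_edges(network)
  classes <- c("miR-miR", "miR-mRNA", "mRNA-mRNA")
  counts <- tibble(class = classes) |>
    left_join(
      e |> group_by(.data$class) |>
        summarise(n_edges = n(), mi_median = median(.data$mi), .groups = "drop"),
      by = "class"
    ) |>
    mutate(n_edges = ifelse(is.na(.data$n_edges), 0L, .data$n_edges))
  if (nrow(e) == 0) {
    return(list(counts = counts,
                histogram = tibble(class = character(), bin_lo = numeric(),
                                   bin_hi = numeric(), n = integer())))
  }
  brk <- if (length(breaks) == 1) {
    seq(min(e$mi), max(e$mi), length.out = breaks + 1)
  } else breaks
  hist_tbl <- e |>
    group_by(.data$class) |>
    dplyr::reframe({
      h <- hist(.data$mi, breaks = brk, plot = FALSE, include.lowest = TRUE)
      tibble(bin_lo = h$breaks[-length(h$breaks)], bin_hi = h$breaks[-1],
             n = h$counts)
    })
  list(counts = counts, histogram = hist_tbl)
}

#' Chromosomal membership of network miRs
#'
#' Maps every miR node to its chromosome and genomic-cluster label and
#' counts nodes per region. Unannotated miRs fall into an `"unknown"`
#' bucket with a warning.
#'
#' @param network an [mi_network()].
#' @param annotation annotation tibble (see [read_annotation_tsv()]).
#' @return List: `mirs` (tibble `node`, `chromosome`, `cluster`) and
#'   `regions` (tibble `chromosome`, `cluster`, `n_mirs`).
#' @export
positional_table <- function(network, annotation) {
  stopifnot(inherits(network, "mi_network"))
  mirs <- network$nodes$node[network$nodes$kind == "miR"]
  if (length(mirs) == 0) {
    return(list(mirs = tibble(node = character(), chromosome = character(),
                              cluster = character()),
                regions = tibble(chromosome = character(), cluster = character(),
                                 n_mirs = integer())))
  }
  idx <- match(mirs, annotation$feature_id)
  if (anyNA(idx)) warn(sprintf("%d unannotated miR(s) bucketed as 'unknown'.",
                               sum(is.na(idx))))
  tab <- tibble(
    node = mirs,
    chromosome = ifelse(is.na(idx), "unknown", annotation$chromosome[idx]),
    cluster = ifelse(is.na(idx), "unknown", annotation$cluster[idx])
  )
  regions <- tab |>
    group_by(.data$chromosome, .data$cluster) |>
    summarise(n_mirs = n(), .groups = "drop") |>
    arrange(desc(.data$n_mirs))
  list(mirs = tab, regions = regions)
}
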