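#' Hypergeometric gene-set over-representation
#'
#' For each set, with universe size N, annotated-in-universe K, query size
#' n and overlap k, computes the one-sided over-representation p-value
#' `P(X >= k)` for X hypergeometric(N, K, n), BH-adjusts across all tested
#' sets, and flags sets passing the FDR and set-size filters
#' (`FDR < fdr_max` and raw set size `< max_set_size`).
#'
#' @param query_genes character vector; members outside the universe are
#'   dropped with a warning.
#' @param sets gene-set collection as from [read_gmt()].
#' @param universe character vector of testable gene ids (typically all
#'   mRNAs surviving preprocessing).
#' @param fdr_max,max_set_size filter thresholds (defaults 0.01 / 1000).
#' @return Tibble of class `mirnet_enrichment`, sorted by FDR: `set_id`,
#'   `name`, `set_size`, `N`, `K`, `n`, `k`, `p_value`, `fdr`,
#'   `passes_filters`.
#' @export
hypergeometric_enrichment <- function(query_genes, sets, universe,
                                      fdr_max = 0.01, max_set_size = 1000) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe.", class = "mirnet_usage_error")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe dropped.",
                 length(outside)))
    query <- setdiff(query, outside)
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::pmap(list(sets$set_id, sets$name, sets$members), function(id, nm, mem) {
    ann <- intersect(mem, universe)
    K <- length(ann)
    k <- length(intersect(ann, query))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_id = id, name = nm, set_size = length(mem),
           N = N, K = K, n = n, k = k, p_value = p)
  })
  out <- bind_rows(rows)
  out$fdr <- bh_adjust(out$p_value)
  out$passes_filters <- out$fdr < fdr_max & out$set_size < max_set_size
  out <- arrange(out, .data$fdr, .data$p_value, .data$set_id)
  class(out) <- c("mirnet_enrichment", class(out))
  out
}

#' Positional (genomic-region) enrichment of network miRs
#'
#' Tests whether the miR nodes of a network over-represent a genomic
#' cluster: hypergeometric with universe = all miRs that survived
#' preprocessing, K = miRs annotated to the region, n = miR nodes in the
#' network, k = their overlap.
#'
#' @param mir_nodes character vector of miR node ids in the network.
#' @param annotation annotation tibble with `feature_id` and `cluster` (or
#'   `chromosome`) columns.
#' @param region_label the cluster (or chromosome) label to test.
#' @param mir_universe all miR ids surviving preprocessing.
#' @param by `"cluster"` (default) or `"chromosome"` — the column matched
#'   against `region_label`.
#' @return One-row tibble: `region`, `N`, `K`, `n`, `k`, `p_value`.
#' @export
positional_enrichment <- function(mir_nodes, annotation, region_label,
                                  mir_universe, by = c("cluster", "chromosome")) {
  by <- match.arg(by)
  region_vals <- annotation[[by]]
  if (!region_label %in% region_vals) {
    abort(sprintf("region '%s' absent from annotation.", region_label),
          class = "mirnet_usage_error")
  }
  universe <- unique(mir_universe)
  region_mirs <- annotation$feature_id[!is.na(region_vals) &
                                         region_vals == region_label]
  K_set <- intersect(region_mirs, universe)
  n_set <- intersect(unique(mir_nodes), universe)
  k <- length(intersect(K_set, n_set))
  N <- length(universe)
  K <- length(K_set)
  n <- length(n_set)
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(region = region_label, N = N, K = K, n = n, k = k, p_value = p)
}

#' Overlap between inferred miR-mRNA edges and an interaction table
#'
#' An inferred miR-mRNA edge matches iff its (miR, gene) pair is recorded
#' in the interaction table; with `family_level = TRUE` both sides are
#' collapsed to miR families first.
#'
#' @param network an [mi_network()].
#' @param db interaction tibble (`mir_id`, `gene_id`, `source`).
#' @param family_map optional tibble `feature_id`, `family` for
#'   family-level matching.
#' @param family_level match at family rather than mature-miR level.
#' @return List: `summary` (tibble per source: `source`, `n_db`,
#'   `n_network_edges`, `n_matched`, `fraction_matched`) and `matched`
#'   (the matched edge tibble with its source tag).
#' @export
db_overlap <- function(network, db, family_map = NULL, family_level = FALSE) {
  stopifnot(inherits(network, "mi_network"))
  db <- validate_interactions(db)
  e <- dplyr::filter(live_edges(network), .data$class == "miR-mRNA")
  kinds <- setNames(network$nodes$kind, network$nodes$node)
  mir_first <- kinds[e$node_a] == "miR"
  edges <- tibble(
    mir_id = ifelse(mir_first, e$node_a, e$node_b),
    gene_id = ifelse(mir_first, e$node_b, e$node_a),
    mi = e$mi
  )
  map_id <- function(ids) {
    if (!family_level) return(ids)
    if (is.null(family_map)) {
      abort("family_level matching needs a family_map.",
            class = "mirnet_usage_error")
    }
    fm <- as_tibble(family_map)
    fam <- fm$family[match(ids, fm$feature_id)]
    ifelse(is.na(fam), ids, fam)
  }
  edges$match_key <- paste(map_id(edges$mir_id), edges$gene_id)
  db$match_key <- paste(map_id(db$mir_id), db$gene_id)
  matched <- inner_join(edges, db[, c("match_key", "source")], by = "match_key")
  summary <- db |>
    group_by(.data$source) |>
    summarise(n_db = n(), .groups = "drop") |>
    left_join(
      matched |> group_by(.data$source) |>
        summarise(n_matched = dplyr::n_distinct(.data$match_key), .groups = "drop"),
      by = "source"
    ) |>
    mutate(
      n_network_edges = nrow(edges),
      n_matched = ifelse(is.na(.data$n_matched), 0L, .data$n_matched),
      fraction_matched = ifelse(nrow(edges) > 0,
                                .data$n_matched / nrow(edges), NA_real_)
    )
  list(summary = summary, matched = matched[, c("mir_id", "gene_id", "mi", "source")])
}
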