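#' Study configuration for the synthetic benchmark scale
#'
#' [default_config()] carries the percentile thresholds used at real-data
#' scale (thousands of features, millions of pairs). At the planted
#' benchmark's scale (hundreds of features, tens of thousands of pairs)
#' those quantiles would retain fewer edges than the planted structure
#' contains, so the benchmark configuration widens them so that the
#' retained edge count is sized to the planted edge count plus a small
#' null margin (`q_mi = 0.9955`, `q_mm = 0.992`), with a lighter
#' permutation budget.
#'
#' @return Named list, same keys as [default_config()].
#' @export
synthetic_run_config <- function() {
  modifyList(default_config(), list(
    q_mm = 0.992, q_mi = 0.9955, n_perm = 300
  ))
}

#' Run the full study pipeline on a dataset
#'
#' Orchestrates, per condition: preprocessing (count filter, TMM/CPM,
#' upper-quartile, TPM filter, join), MI network inference with
#' class-specific thresholds and DPI, largest component, degree and family
#' ranking, first-neighbour subnetwork of the top-degree miR family; then
#' across conditions: full-network and first-neighbour intersection with DE
#' overlay, paired differential expression, gene-set and positional
#' enrichment, principal-curve pathway deregulation scores, and
#' interaction-table overlap. When the dataset carries planted ground
#' truth, a recovery scorecard is attached.
#'
#' @param dataset a `mirnet_synth` object (see [synthetic_dataset()]) or a
#'   directory written by [write_synthetic_dataset()].
#' @param config named list of thresholds (default
#'   [synthetic_run_config()]).
#' @param seed integer seed for the stochastic stages (permutation nulls).
#' @param out_dir optional directory; when given, every artifact is written
#'   through the package's writers and a manifest with md5 digests is
#'   included.
#' @param top_family optional named character vector (e.g.
#'   `c(tumour = "mirfam-tum")`) forcing the first-neighbour family instead
#'   of the automatic top-degree choice.
#' @return List of class `mirnet_run` with elements `preprocess`,
#'   `networks`, `components`, `degrees`, `neighbors`, `intersection`,
#'   `neighbor_intersection`, `de`, `enrichment`, `positional`, `pds`,
#'   `pds_separation`, `db_overlap`, `scorecard` (when truth available) and
#'   `manifest`.
#' @export
run_study <- function(dataset, config = synthetic_run_config(), seed = 1,
                      out_dir = NULL, top_family = NULL) {
  cfg <- modifyList(synthetic_run_config(), config)
  t0 <- Sys.time()
  if (is.character(dataset)) dataset <- read_synthetic_dataset(dataset)
  stopifnot(inherits(dataset, "mirnet_synth"))
  ann <- dataset$annotation
  truth <- dataset$truth
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  # ---- preprocessing ----
  st <- tic()
  prep <- lapply(c(tumour = "tumour", control = "control"), function(cond) {
    preprocess_condition(dataset[[cond]]$mir_counts, dataset[[cond]]$mrna_tpm,
                         config = cfg)
  })
  toc(st, "preprocess")

  # ---- network inference per condition ----
  st <- tic()
  networks <- lapply(prep, function(p) {
    build_network(p$joint, q_mm = cfg$q_mm, q_mi = cfg$q_mi,
                  dpi_tolerance = cfg$dpi_tolerance, n_perm = cfg$n_perm,
                  seed = seed, tail_fit = cfg$tail_fit,
                  w_loo = cfg$mi_loo_weight,
                  bandwidth_const = cfg$mi_bandwidth_const)
  })
  toc(st, "infer")

  # ---- topology ----
  st <- tic()
  components <- lapply(networks, largest_component)
  fam_map <- ann[, c("feature_id", "family")]
  degrees <- lapply(networks, degree_table, family_map = fam_map)
  pick_family <- function(cond) {
    if (!is.null(top_family) && !is.na(top_family[cond])) {
      return(unname(top_family[cond]))
    }
    fams <- degrees[[cond]]$families
    if (nrow(fams) == 0) return(NA_character_)
    fams$family[1]
  }
  neighbors <- lapply(c(tumour = "tumour", control = "control"), function(cond) {
    fam <- pick_family(cond)
    if (is.na(fam)) return(NULL)
    seeds <- ann$feature_id[!is.na(ann$family) & ann$family == fam]
    list(family = fam,
         network = first_neighbors(networks[[cond]], seeds))
  })
  toc(st, "topology")

  # ---- differential expression ----
  st <- tic()
  de <- bind_rows(
    differential_expression(dataset$tumour$mir_counts,
                            dataset$control$mir_counts,
                            paired = cfg$de_paired, fc_min = cfg$de_fc_min,
                            fdr_max = cfg$de_fdr_max),
    differential_expression(dataset$tumour$mrna_counts,
                            dataset$control$mrna_counts,
                            paired = cfg$de_paired, fc_min = cfg$de_fc_min,
                            fdr_max = cfg$de_fdr_max)
  )
  class(de) <- c("mirnet_de", class(tibble()))
  toc(st, "de")

  # ---- intersections (full networks and first-neighbour networks) ----
  st <- tic()
  intersection <- intersect_networks(networks$tumour, networks$control, de)
  neighbor_intersection <-
    if (!is.null(neighbors$tumour) && !is.null(neighbors$control)) {
      intersect_networks(neighbors$tumour$network, neighbors$control$network, de)
    } else NULL
  toc(st, "intersect")

  # ---- enrichment ----
  st <- tic()
  sets <- dataset$gene_sets %||% synthetic_gene_sets(dataset)
  mrna_universe <- prep$tumour$mrna$features$feature_id
  tumour_mrnas <- components$tumour$nodes$node[
    components$tumour$nodes$kind == "mRNA"]
  enrichment <- hypergeometric_enrichment(
    tumour_mrnas, sets$go, mrna_universe,
    fdr_max = cfg$enrich_fdr_max, max_set_size = cfg$enrich_max_set_size)
  mir_universe <- prep$tumour$mir$features$feature_id
  tumour_mirs <- networks$tumour$nodes$node[networks$tumour$nodes$kind == "miR"]
  positional <- positional_enrichment(
    tumour_mirs, ann, truth$cluster_label %||% stats::na.omit(ann$cluster)[1],
    mir_universe)
  toc(st, "enrichment")

  # ---- PDS ----
  st <- tic()
  mrna_common <- intersect(prep$tumour$mrna$features$feature_id,
                           prep$control$mrna$features$feature_id)
  mrna_joint <- expr_matrix(
    cbind(log2(prep$tumour$mrna$values[mrna_common, , drop = FALSE] + 1),
          log2(prep$control$mrna$values[mrna_common, , drop = FALSE] + 1)),
    tibble(feature_id = mrna_common, kind = "mRNA"),
    bind_rows(prep$tumour$mrna$samples, prep$control$mrna$samples),
    value_space = "log2")
  required <- unique(c(
    tumour_mrnas,
    if (!is.null(neighbors$tumour)) {
      neighbors$tumour$network$nodes$node[
        neighbors$tumour$network$nodes$kind == "mRNA"]
    }
  ))
  control_ids <- mrna_joint$samples$sample_id[
    mrna_joint$samples$condition == "control"]
  pds <- pds_matrix(mrna_joint, sets$pathways, required, control_ids,
                    variance_target = cfg$pds_variance_target,
                    span = cfg$pds_span)
  pds_sep <- pds_separation(pds)
  toc(st, "pds")

  # ---- interaction-table overlap ----
  st <- tic()
  db <- dataset$interactions %||% synthetic_interaction_db(dataset)
  dbov <- db_overlap(networks$tumour, db, family_map = fam_map)
  toc(st, "db_overlap")

  results <- structure(list(
    preprocess = prep, networks = networks, components = components,
    degrees = degrees, neighbors = neighbors,
    intersection = intersection, neighbor_intersection = neighbor_intersection,
    de = de, enrichment = enrichment, positional = positional,
    pds = pds, pds_separation = pds_sep, db_overlap = dbov,
    config = cfg, seed = seed
  ), class = "mirnet_run")

  if (!is.null(truth)) {
    results$scorecard <- score_recovery(results, truth,
                                        top_k = cfg$top_k_degree)
  }

  manifest <- list(
    seed = seed, config = cfg,
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("mirnet"))
  )
  if (!is.null(out_dir)) {
    manifest$files <- write_run_bundle(results, out_dir)
  }
  results$manifest <- manifest
  results
}

#' @export
print.mirnet_run <- function(x, ...) {
  cat("<mirnet_run>\n")
  for (cond in c("tumour", "control")) {
    g <- glance(x$networks[[cond]])
    cat(sprintf("  %s network: %d nodes, %d edges\n", cond,
                g$n_nodes, g$n_edges))
  }
  cat(sprintf("  intersection: %d edges; DE flagged: %d; pathways scored: %d\n",
              nrow(live_edges(x$intersection)),
              sum(x$de$flag != "ns"), nrow(x$pds$scores)))
  if (!is.null(x$scorecard)) {
    print(x$scorecard)
  }
  invisible(x)
}

# write every artifact of a run and return an md5 digest table
write_run_bundle <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  for (cond in c("tumour", "control")) {
    write_network(results$networks[[cond]], fp(paste0("network_", cond, ".tsv")))
    write_network(results$networks[[cond]], fp(paste0("network_", cond, ".sif")),
                  format = "sif")
    readr::write_tsv(results$degrees[[cond]]$nodes,
                     fp(paste0("degrees_", cond, ".tsv")), progress = FALSE)
    if (!is.null(results$neighbors[[cond]])) {
      write_network(results$neighbors[[cond]]$network,
                    fp(paste0("neighbors_", cond, ".tsv")))
    }
    readr::write_tsv(results$preprocess[[cond]]$report,
                     fp(paste0("preprocess_report_", cond, ".tsv")),
                     progress = FALSE)
  }
  write_network(results$intersection, fp("intersection.tsv"))
  readr::write_tsv(results$de, fp("differential_expression.tsv"), progress = FALSE)
  readr::write_tsv(results$enrichment, fp("enrichment.tsv"), progress = FALSE)
  readr::write_tsv(results$positional, fp("positional_enrichment.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(results$pds), fp("pds_matrix.tsv"), progress = FALSE)
  readr::write_tsv(results$pds_separation, fp("pds_separation.tsv"),
                   progress = FALSE)
  readr::write_tsv(results$db_overlap$summary, fp("db_overlap.tsv"),
                   progress = FALSE)
  if (!is.null(results$scorecard)) {
    readr::write_tsv(tidy(results$scorecard), fp("scorecard.tsv"),
                     progress = FALSE)
  }
  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  tibble(file = basename(files), md5 = unname(tools::md5sum(files)))
}

#' Score a pipeline run against planted ground truth
#'
#' Computes the recovery scorecard: per-condition hub flags (does the
#' planted hub family intersect the top-k degree nodes of its condition's
#' network?), conserved-core edge precision/recall of the full-network
#' intersection against the planted "both"-condition edges, the planted
#' cluster's positional enrichment p, DE sensitivity (flagged with the
#' correct sign among planted DE features) and empirical FDR, and the
#' planted pathway's condition-separation p.
#'
#' @param results a `mirnet_run`.
#' @param truth the `truth` element of a `mirnet_synth` dataset.
#' @param top_k hub window (default 10).
#' @return A list of class `mirnet_scorecard`.
#' @export
score_recovery <- function(results, truth, top_k = 10) {
  missing_nodes <- setdiff(unique(c(truth$planted_edges$node_a,
                                    truth$planted_edges$node_b)),
                           c(results$de$feature_id))
  if (length(missing_nodes) > 0 && length(missing_nodes) ==
      length(unique(c(truth$planted_edges$node_a, truth$planted_edges$node_b)))) {
    abort("truth/result feature ids do not overlap.", class = "mirnet_usage_error")
  }
  hub_flags <- vapply(c(tumour = "tumour", control = "control"), function(cond) {
    topk <- head(results$degrees[[cond]]$nodes$node, top_k)
    length(intersect(truth$hub_members[[cond]], topk)) > 0
  }, logical(1))

  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  both <- dplyr::filter(truth$planted_edges, .data$condition == "both")
  truth_keys <- key(both$node_a, both$node_b)
  ie <- live_edges(results$intersection)
  inter_keys <- key(ie$node_a, ie$node_b)
  tp <- length(intersect(inter_keys, truth_keys))
  precision <- if (length(inter_keys) == 0) NA_real_ else tp / length(inter_keys)
  recall <- if (length(truth_keys) == 0) NA_real_ else tp / length(truth_keys)

  de <- results$de
  idx <- match(truth$de_features$feature_id, de$feature_id)
  found <- !is.na(idx)
  ok_sign <- found & de$flag[idx] != "ns" &
    sign(de$log2fc[idx]) == sign(truth$de_features$true_log2fc)
  sensitivity <- mean(ok_sign)
  flagged <- de$feature_id[de$flag != "ns"]
  false_flags <- setdiff(flagged, truth$de_features$feature_id)
  empirical_fdr <- if (length(flagged) == 0) 0 else
    length(false_flags) / length(flagged)

  pds_p <- NA_real_
  sep <- results$pds_separation
  if (!is.null(sep) && "pw_dereg" %in% sep$set_id) {
    pds_p <- sep$p_value[sep$set_id == "pw_dereg"]
  }

  structure(list(
    hub_recovered = as.list(hub_flags),
    core_precision = precision,
    core_recall = recall,
    cluster_positional_p = results$positional$p_value,
    de_sensitivity = sensitivity,
    de_empirical_fdr = empirical_fdr,
    pds_separation_p = pds_p,
    top_k = top_k
  ), class = "mirnet_scorecard")
}

#' @export
print.mirnet_scorecard <- function(x, ...) {
  cat("<mirnet_scorecard>\n")
  cat(sprintf("  hub recovered: tumour %s, control %s (top-%d degree)\n",
              x$hub_recovered$tumour, x$hub_recovered$control, x$top_k))
  cat(sprintf("  conserved core: precision %.3f, recall %.3f\n",
              x$core_precision, x$core_recall))
  cat(sprintf("  cluster positional p: %.3g\n", x$cluster_positional_p))
  cat(sprintf("  DE sensitivity %.3f, empirical FDR %.3f\n",
              x$de_sensitivity, x$de_empirical_fdr))
  cat(sprintf("  planted pathway separation p: %.3g\n", x$pds_separation_p))
  invisible(x)
}

#' @export
tidy.mirnet_scorecard <- function(x, ...) {
  tibble(
    metric = c("hub_recovered_tumour", "hub_recovered_control",
               "core_precision", "core_recall", "cluster_positional_p",
               "de_sensitivity", "de_empirical_fdr", "pds_separation_p"),
    value = c(as.numeric(x$hub_recovered$tumour),
              as.numeric(x$hub_recovered$control),
              x$core_precision, x$core_recall, x$cluster_positional_p,
              x$de_sensitivity, x$de_empirical_fdr, x$pds_separation_p)
  )
}

#' Read a dataset directory written by [write_synthetic_dataset()]
#'
#' @param dir dataset directory.
#' @return A `mirnet_synth`-shaped list (without the generator config).
#' @export
read_synthetic_dataset <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  ann <- read_annotation_tsv(fp("annotation.tsv"))
  read_cond <- function(cond) {
    list(
      mir_counts = read_expression_tsv(
        fp(paste0("mir_counts_", cond, ".tsv")),
        samples = fp(paste0("mir_counts_", cond, ".tsv.samples.tsv")),
        annotation = ann, value_space = "raw_counts"),
      mrna_counts = read_expression_tsv(
        fp(paste0("mrna_counts_", cond, ".tsv")),
        samples = fp(paste0("mrna_counts_", cond, ".tsv.samples.tsv")),
        annotation = ann, value_space = "raw_counts"),
      mrna_tpm = read_expression_tsv(
        fp(paste0("mrna_tpm_", cond, ".tsv")),
        samples = fp(paste0("mrna_tpm_", cond, ".tsv.samples.tsv")),
        annotation = ann, value_space = "normalized")
    )
  }
  truth <- NULL
  if (file.exists(fp("truth_edges.tsv"))) {
    edges <- readr::read_tsv(fp("truth_edges.tsv"), show_col_types = FALSE,
                             progress = FALSE)
    de <- readr::read_tsv(fp("truth_de.tsv"), show_col_types = FALSE,
                          progress = FALSE)
    fam <- ann[!is.na(ann$family), ]
    cluster_mirs <- ann$feature_id[!is.na(ann$cluster)]
    # hub membership per condition is recoverable from the planted edge roles
    hub_of <- function(role) {
      e <- edges[edges$role == role, ]
      ids <- unique(c(e$node_a, e$node_b))
      intersect(ids, fam$feature_id)
    }
    truth <- list(planted_edges = edges, de_features = de,
                  cluster_members = cluster_mirs,
                  cluster_label = stats::na.omit(unique(ann$cluster))[1],
                  hub_members = list(control = hub_of("hub_control"),
                                     tumour = hub_of("hub_tumour")))
  }
  gene_sets <- NULL
  if (file.exists(fp("go_like.gmt"))) {
    gene_sets <- list(go = read_gmt(fp("go_like.gmt"), category = "GO-like"),
                      pathways = read_gmt(fp("pathways.gmt"),
                                          category = "pathway-like"))
  }
  interactions <- if (file.exists(fp("interactions.tsv"))) {
    read_interactions_tsv(fp("interactions.tsv"))
  } else NULL
  structure(list(tumour = read_cond("tumour"), control = read_cond("control"),
                 annotation = ann, truth = truth, gene_sets = gene_sets,
                 interactions = interactions,
                 config = synthetic_config()),
            class = "mirnet_synth")
}
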