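#' Mutual-information network
#'
#' A typed, undirected, MI-weighted graph: a node table (`node`, `kind`) and
#' an edge table (`node_a`, `node_b`, `mi`, `class`, optionally `p_value`,
#' `p_adj`, `dpi_removed`). Edges are stored with `node_a < node_b` so each
#' unordered pair appears once; self-loops are rejected.
#'
#' @param nodes data frame with columns `node`, `kind`.
#' @param edges data frame with at least `node_a`, `node_b`, `mi`, `class`.
#' @return An object of class `mi_network`.
#' @export
mi_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("node", "kind") %in% names(nodes)),
            all(c("node_a", "node_b", "mi", "class") %in% names(edges)))
  if (anyDuplicated(nodes$node)) {
    abort("duplicate node ids.", class = "mirnet_format_error")
  }
  if (nrow(edges) > 0) {
    if (any(edges$node_a == edges$node_b)) {
      abort("self-loops are not allowed.", class = "mirnet_validation_error")
    }
    swap <- edges$node_a > edges$node_b
    if (any(swap)) {
      tmp <- edges$node_a[swap]
      edges$node_a[swap] <- edges$node_b[swap]
      edges$node_b[swap] <- tmp
    }
    if (anyDuplicated(edges[, c("node_a", "node_b")])) {
      abort("duplicate edges.", class = "mirnet_validation_error")
    }
    missing <- setdiff(c(edges$node_a, edges$node_b), nodes$node)
    if (length(missing) > 0) {
      abort("edge endpoints absent from node table.",
            class = "mirnet_validation_error")
    }
  }
  if (!"dpi_removed" %in% names(edges)) {
    edges$dpi_removed <- rep(FALSE, nrow(edges))
  }
  structure(list(nodes = nodes, edges = edges), class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  live <- sum(!x$edges$dpi_removed)
  cat(sprintf("<mi_network> %d nodes (%d miR, %d mRNA), %d edges (%d after DPI)\n",
              nrow(x$nodes), sum(x$nodes$kind == "miR"),
              sum(x$nodes$kind == "mRNA"), nrow(x$edges), live))
  invisible(x)
}

#' @export
tidy.mi_network <- function(x, ...) x$edges

#' @export
glance.mi_network <- function(x, ...) {
  e <- live_edges(x)
  tibble(
    n_nodes = nrow(x$nodes),
    n_mir = sum(x$nodes$kind == "miR"),
    n_mrna = sum(x$nodes$kind == "mRNA"),
    n_edges = nrow(e),
    n_mir_mir = sum(e$class == "miR-miR"),
    n_mir_mrna = sum(e$class == "miR-mRNA"),
    n_mrna_mrna = sum(e$class == "mRNA-mRNA"),
    n_dpi_removed = sum(x$edges$dpi_removed)
  )
}

# edges that survived DPI (or all, when DPI has not run)
live_edges <- function(network) {
  dplyr::filter(network$edges, !.data$dpi_removed)
}

# drop dpi-removed edges and prune isolated nodes optionally
as_igraph <- function(network, keep_removed = FALSE) {
  e <- if (keep_removed) network$edges else live_edges(network)
  g <- igraph::graph_from_data_frame(
    d = e[, c("node_a", "node_b", setdiff(names(e), c("node_a", "node_b")))],
    directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
  g
}

from_igraph <- function(g) {
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- tibble(node = vd$name, kind = vd$kind)
  if (nrow(ed) > 0) {
    names(ed)[1:2] <- c("node_a", "node_b")
  } else {
    ed <- tibble(node_a = character(), node_b = character(),
                 mi = numeric(), class = character())
  }
  mi_network(nodes = nodes, edges = ed)
}

#' Class-specific percentile thresholds
#'
#' Computes per-class MI cutoffs as empirical quantiles of the class's MI
#' values (linear interpolation between order statistics). The miR-miR and
#' miR-mRNA classes are pooled under one threshold (`q_mi`); mRNA-mRNA edges
#' use `q_mm`. Ties at the cutoff are all retained.
#'
#' @param mi an `mi_matrix` (from [mi_matrix()]) or a pair tibble as from
#'   [tidy.mi_matrix()].
#' @param q_mm quantile for mRNA-mRNA pairs (default 0.99987).
#' @param q_mi pooled quantile for miR-miR and miR-mRNA pairs
#'   (default 0.99741).
#' @return Tibble with one row per class: `class`, `q`, `cutoff`, `n_pairs`,
#'   `n_retained`.
#' @export
class_thresholds <- function(mi, q_mm = 0.99987, q_mi = 0.99741) {
  stopifnot(q_mm >= 0, q_mm < 1, q_mi >= 0, q_mi < 1)
  pairs <- if (inherits(mi, "mi_matrix")) tidy(mi) else as_tibble(mi)
  if (nrow(pairs) == 0) abort("no pairs to threshold.", class = "mirnet_usage_error")
  mm <- pairs$mi[pairs$class == "mRNA-mRNA"]
  mir <- pairs$mi[pairs$class != "mRNA-mRNA"]
  rows <- list()
  if (length(mm) > 0) {
    cut_mm <- unname(quantile(mm, q_mm, type = 7))
    rows$mm <- tibble(class = "mRNA-mRNA", q = q_mm, cutoff = cut_mm,
                      n_pairs = length(mm), n_retained = sum(mm >= cut_mm))
  } else {
    warn("no mRNA-mRNA pairs; class skipped.")
  }
  if (length(mir) > 0) {
    cut_mi <- unname(quantile(mir, q_mi, type = 7))
    for (cl in c("miR-miR", "miR-mRNA")) {
      v <- pairs$mi[pairs$class == cl]
      rows[[cl]] <- tibble(class = cl, q = q_mi, cutoff = cut_mi,
                           n_pairs = length(v), n_retained = sum(v >= cut_mi))
    }
  } else {
    warn("no miR-involving pairs; classes skipped.")
  }
  bind_rows(rows)
}

#' Permutation p-values for MI edges
#'
#' Builds a class-pooled permutation null: for `n_perm` randomly chosen
#' feature pairs, one member is permuted across samples and the MI
#' recomputed. The per-pair p-value is `(1 + #null >= MI) / (1 + n_perm)`;
#' with `tail_fit = TRUE` an exponential tail fitted to the top decile of
#' the null extrapolates p below `1/n_perm`. Bonferroni correction
#' multiplies by the number of pairs tested in the pair's class (miR-miR and
#' miR-mRNA pooled, as for thresholds).
#'
#' @param mi an `mi_matrix`.
#' @param ranks the rank matrix the MI matrix was computed from
#'   (features x samples).
#' @param n_perm number of permutation draws (>= 100).
#' @param seed integer seed for the permutations.
#' @param tail_fit extrapolate small p with an exponential tail fit?
#' @return Tibble `node_a`, `node_b`, `mi`, `class`, `p_value`, `p_adj`.
#' @export
edge_pvalues <- function(mi, ranks, n_perm = 1000, seed = 1, tail_fit = TRUE) {
  stopifnot(inherits(mi, "mi_matrix"))
  if (n_perm < 100) abort("n_perm must be >= 100.", class = "mirnet_usage_error")
  pairs <- tidy(mi)
  ranks <- ranks[mi$feature_ids, , drop = FALSE]
  n <- ncol(ranks)
  p <- nrow(ranks)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  pa <- sample.int(p, n_perm, replace = TRUE)
  pb <- sample.int(p, n_perm, replace = TRUE)
  same <- pa == pb
  pb[same] <- (pb[same] %% p) + 1L
  nperms <- min(n_perm, 256L)
  perm <- vapply(seq_len(nperms), function(i) sample.int(n) - 1L, integer(n))
  null_mi <- .mi_null_cpp(t(ranks), mi$h, mi$w_loo, pa - 1L, pb - 1L, perm)
  null_mi <- pmax(null_mi - (mi$offset %||% 0), 0)
  emp_p <- (1 + vapply(pairs$mi, function(v) sum(null_mi >= v), numeric(1))) /
    (1 + n_perm)
  if (tail_fit) {
    u <- unname(quantile(null_mi, 0.9, type = 7))
    excess <- null_mi[null_mi > u] - u
    if (length(excess) >= 5 && mean(excess) > 0) {
      beta <- mean(excess)
      tail_p <- 0.1 * exp(-(pairs$mi - u) / beta)
      use_tail <- pairs$mi > u
      emp_p[use_tail] <- pmin(emp_p[use_tail], tail_p[use_tail])
    }
  }
  n_class <- ifelse(pairs$class == "mRNA-mRNA",
                    sum(pairs$class == "mRNA-mRNA"),
                    sum(pairs$class != "mRNA-mRNA"))
  pairs$p_value <- emp_p
  pairs$p_adj <- pmin(1, emp_p * n_class)
  pairs
}

#' Data processing inequality pruning
#'
#' For every triangle (i, j, k) in the thresholded network, the edge (i, j)
#' is marked for removal iff `MI(i,j) < (1 - tolerance) * min(MI(i,k),
#' MI(j,k))` — the strictly weakest edge of the triangle, beyond tolerance.
#' All marks are computed on the input network and removals applied
#' simultaneously, so the result is independent of edge order. Removed edges
#' stay in the edge table with `dpi_removed = TRUE` for audit.
#'
#' @param network an [mi_network()].
#' @param tolerance DPI tolerance in \[0, 1); default 0.10 (10%).
#' @return The network with `dpi_removed` flags set.
#' @export
apply_dpi <- function(network, tolerance = 0.10) {
  stopifnot(inherits(network, "mi_network"))
  if (tolerance < 0 || tolerance >= 1) {
    abort("tolerance must be in [0, 1).", class = "mirnet_usage_error")
  }
  e <- network$edges
  if (nrow(e) == 0) return(network)
  live <- which(!e$dpi_removed)
  ids <- sort(unique(c(e$node_a[live], e$node_b[live])))
  idx <- setNames(seq_along(ids), ids)
  a <- idx[e$node_a[live]]
  b <- idx[e$node_b[live]]
  w <- e$mi[live]
  p <- length(ids)
  # adjacency with MI weights; 0 = absent
  adj <- matrix(0, p, p)
  adj[cbind(a, b)] <- w
  adj[cbind(b, a)] <- w
  mark <- logical(length(live))
  for (t in seq_along(live)) {
    i <- a[t]; j <- b[t]
    ks <- which(adj[i, ] > 0 & adj[j, ] > 0)
    if (length(ks) == 0) next
    lim <- (1 - tolerance) * pmin(adj[i, ks], adj[j, ks])
    if (any(w[t] < lim)) mark[t] <- TRUE
  }
  network$edges$dpi_removed[live[mark]] <- TRUE
  network
}

#' Build the inferred MI network from a preprocessed joint matrix
#'
#' Runs the full inference chain: rank transform, pairwise Gaussian-kernel
#' MI, class-specific percentile thresholds, permutation significance
#' annotation, and DPI pruning.
#'
#' @param expr a network-ready [expr_matrix()] (both kinds, normalized or
#'   log2 space — the rank transform makes the choice immaterial).
#' @param q_mm,q_mi percentile thresholds, see [class_thresholds()].
#' @param dpi_tolerance DPI tolerance, see [apply_dpi()].
#' @param n_perm,seed,tail_fit see [edge_pvalues()]; `n_perm = 0` skips
#'   significance annotation.
#' @param w_loo,bandwidth_const estimator knobs, see [estimate_mi()].
#' @param pair_filter see [mi_matrix()].
#' @return An [mi_network()] whose nodes are the endpoints of retained
#'   edges. Attributes `thresholds` (the [class_thresholds()] table) and
#'   `n_edges_pre_dpi` carry provenance.
#' @export
build_network <- function(expr, q_mm = 0.99987, q_mi = 0.99741,
                          dpi_tolerance = 0.10, n_perm = 1000, seed = 1,
                          tail_fit = TRUE, w_loo = 0.6,
                          bandwidth_const = NULL,
                          pair_filter = "all") {
  stopifnot(inherits(expr, "expr_matrix"))
  ranks <- rank_transform(expr)
  mim <- mi_matrix(ranks, kinds = expr$features$kind,
                   pair_filter = pair_filter, w_loo = w_loo,
                   bandwidth_const = bandwidth_const)
  thr <- class_thresholds(mim, q_mm = q_mm, q_mi = q_mi)
  pairs <- if (n_perm > 0) {
    edge_pvalues(mim, ranks, n_perm = n_perm, seed = seed, tail_fit = tail_fit)
  } else {
    dplyr::mutate(tidy(mim), p_value = NA_real_, p_adj = NA_real_)
  }
  pairs <- left_join(pairs, thr[, c("class", "cutoff")], by = "class")
  edges <- dplyr::filter(pairs, !is.na(.data$cutoff), .data$mi >= .data$cutoff)
  edges$cutoff <- NULL
  node_ids <- sort(unique(c(edges$node_a, edges$node_b)))
  nodes <- tibble(node = node_ids,
                  kind = unname(mim$kinds[node_ids]))
  net <- mi_network(nodes = nodes, edges = edges)
  net <- apply_dpi(net, tolerance = dpi_tolerance)
  attr(net, "thresholds") <- thr
  attr(net, "n_edges_pre_dpi") <- nrow(edges)
  net
}
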