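# shared fixture builders and independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_expr <- function(values, kind = "mRNA", condition = NULL, pair_id = NULL,
                     value_space = "raw_counts", paired = FALSE) {
  p <- nrow(values)
  n <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("f%02d", seq_len(p))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(n))
  if (length(kind) == 1) kind <- rep(kind, p)
  condition <- condition %||% rep("tumour", n)
  pair_id <- pair_id %||% sprintf("p%02d", seq_len(n))
  expr_matrix(values,
              features = tibble::tibble(feature_id = rownames(values), kind = kind),
              samples = tibble::tibble(sample_id = colnames(values),
                                       condition = condition, pair_id = pair_id),
              value_space = value_space, paired = paired)
}

frac_rank <- function(v) rank(v, ties.method = "average") / (length(v) + 1)

# random typed network with MI weights
random_network <- function(n_nodes = 30, p_edge = 0.2, mir_frac = 0.3,
                           seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  kind <- ifelse(runif(n_nodes) < mir_frac, "miR", "mRNA")
  cmb <- t(combn(ids, 2))
  keep <- runif(nrow(cmb)) < p_edge
  e <- cmb[keep, , drop = FALSE]
  kmap <- stats::setNames(kind, ids)
  edges <- tibble::tibble(
    node_a = e[, 1], node_b = e[, 2],
    mi = runif(nrow(e), 0.05, 1),
    class = mapply(function(a, b) {
      nm <- sum(c(kmap[[a]], kmap[[b]]) == "miR")
      c("mRNA-mRNA", "miR-mRNA", "miR-miR")[nm + 1]
    }, e[, 1], e[, 2])
  )
  mi_network(nodes = tibble::tibble(node = ids, kind = kind), edges = edges)
}

# brute-force DPI oracle: enumerate all triangles, mark weakest-beyond-
# tolerance edges on the original graph, remove simultaneously
dpi_oracle <- function(network, tolerance) {
  e <- network$edges
  key <- paste(e$node_a, e$node_b)
  w <- stats::setNames(e$mi, key)
  get_w <- function(a, b) {
    k1 <- paste(a, b); k2 <- paste(b, a)
    if (k1 %in% names(w)) w[[k1]] else if (k2 %in% names(w)) w[[k2]] else NA
  }
  ids <- network$nodes$node
  marked <- character()
  if (length(ids) >= 3) {
    tri <- combn(ids, 3)
    for (t in seq_len(ncol(tri))) {
      a <- tri[1, t]; b <- tri[2, t]; c_ <- tri[3, t]
      wab <- get_w(a, b); wac <- get_w(a, c_); wbc <- get_w(b, c_)
      if (anyNA(c(wab, wac, wbc))) next
      if (wab < (1 - tolerance) * min(wac, wbc)) marked <- c(marked, paste(a, b))
      if (wac < (1 - tolerance) * min(wab, wbc)) marked <- c(marked, paste(a, c_))
      if (wbc < (1 - tolerance) * min(wab, wac)) marked <- c(marked, paste(b, c_))
    }
  }
  sort(unique(marked))
}

# traversal (BFS) component oracle on an edge list + node set
components_oracle <- function(nodes, edges_a, edges_b) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  adj <- split(c(edges_b, edges_a), c(edges_a, edges_b))
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[[start]])) next
    cid <- cid + 1L
    queue <- start
    comp[[start]] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(comp[[u]])) {
          comp[[u]] <- cid
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

# direct combinatorial summation for the hypergeometric upper tail
hyper_tail_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# cache for the expensive end-to-end run shared across test files
run_cache <- new.env(parent = emptyenv())

default_synth <- function(seed = 1) {
  key <- paste0("synth", seed)
  if (is.null(run_cache[[key]])) {
    run_cache[[key]] <- synthetic_dataset(synthetic_config(seed = seed))
  }
  run_cache[[key]]
}

default_run <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(run_cache[[key]])) {
    run_cache[[key]] <- suppressWarnings(
      run_study(default_synth(seed), seed = seed))
  }
  run_cache[[key]]
}
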