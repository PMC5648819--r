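test_that("class thresholds follow the interpolated-quantile convention", {
  set.seed(13)
  pairs <- tibble::tibble(
    node_a = "a", node_b = "b",
    mi = c(rexp(100000, 10)),
    class = "mRNA-mRNA"
  )
  thr <- suppressWarnings(class_thresholds(pairs, q_mm = 0.99987))
  # independent order-statistic interpolation (type-7 definition by hand)
  v <- sort(pairs$mi)
  nn <- length(v)
  hpos <- (nn - 1) * 0.99987 + 1
  lo <- floor(hpos)
  cutoff <- v[lo] + (hpos - lo) * (v[lo + 1] - v[lo])
  expect_equal(thr$cutoff[thr$class == "mRNA-mRNA"], cutoff, tolerance = 1e-12)
  n_ret <- thr$n_retained[thr$class == "mRNA-mRNA"]
  expect_lte(abs(n_ret - floor((1 - 0.99987) * nn)), 1)
})

test_that("threshold edge cases: q = 0 keeps all; constant MI keeps all ties", {
  pairs <- tibble::tibble(node_a = "a", node_b = "b",
                          mi = runif(50), class = "miR-miR")
  thr <- suppressWarnings(class_thresholds(pairs, q_mi = 0))
  expect_identical(thr$n_retained[thr$class == "miR-miR"], 50L)
  const <- tibble::tibble(node_a = "a", node_b = "b",
                          mi = rep(0.3, 40), class = "miR-mRNA")
  thr2 <- suppressWarnings(class_thresholds(const, q_mi = 0.99))
  expect_identical(thr2$n_retained[thr2$class == "miR-mRNA"], 40L)
})

test_that("miR-miR and miR-mRNA share one pooled cutoff", {
  set.seed(14)
  pairs <- tibble::tibble(
    node_a = "a", node_b = "b",
    mi = runif(3000),
    class = sample(c("miR-miR", "miR-mRNA", "mRNA-mRNA"), 3000, replace = TRUE)
  )
  thr <- class_thresholds(pairs, q_mm = 0.9, q_mi = 0.8)
  cut_mi <- thr$cutoff[thr$class != "mRNA-mRNA"]
  expect_identical(cut_mi[1], cut_mi[2])
  pooled <- pairs$mi[pairs$class != "mRNA-mRNA"]
  expect_equal(cut_mi[1], unname(quantile(pooled, 0.8, type = 7)),
               tolerance = 1e-12)
})

test_that("DPI hand-evaluated triangles behave as documented", {
  tri <- function(w) {
    mi_network(
      nodes = tibble::tibble(node = c("a", "b", "c"), kind = "mRNA"),
      edges = tibble::tibble(node_a = c("a", "a", "b"),
                             node_b = c("b", "c", "c"),
                             mi = w, class = "mRNA-mRNA")
    )
  }
  # weakest edge 0.2 < 0.9 * 0.4 -> removed
  out <- apply_dpi(tri(c(0.5, 0.4, 0.2)), tolerance = 0.1)
  expect_identical(out$edges$dpi_removed, c(FALSE, FALSE, TRUE))
  # 0.38 >= 0.9 * 0.4 -> conserved
  out2 <- apply_dpi(tri(c(0.5, 0.4, 0.38)), tolerance = 0.1)
  expect_false(any(out2$edges$dpi_removed))
  # tie at tolerance 0: strict < conserves the tie
  out3 <- apply_dpi(tri(c(0.5, 0.4, 0.4)), tolerance = 0)
  expect_false(any(out3$edges$dpi_removed))
  # tolerance outside [0, 1) rejected
  expect_error(apply_dpi(tri(c(0.5, 0.4, 0.2)), tolerance = 1),
               class = "mirnet_usage_error")
})

test_that("DPI equals the brute-force all-triangles oracle on random graphs", {
  for (seed in 1:25) {
    net <- random_network(n_nodes = 18, p_edge = 0.3, seed = seed)
    for (tol in c(0, 0.1, 0.2)) {
      out <- apply_dpi(net, tolerance = tol)
      got <- sort(paste(out$edges$node_a, out$edges$node_b)[out$edges$dpi_removed])
      expect_identical(got, dpi_oracle(net, tol))
    }
  }
})

test_that("DPI never removes the strict-maximum edge of a triangle", {
  for (seed in 26:40) {
    net <- random_network(n_nodes = 15, p_edge = 0.4, seed = seed)
    out <- apply_dpi(net, tolerance = 0.1)
    e <- out$edges
    key <- paste(e$node_a, e$node_b)
    w <- stats::setNames(e$mi, key)
    removed <- key[e$dpi_removed]
    # for every removed edge there must exist a triangle where it is the
    # strict minimum; equivalently, no removed edge is the strict maximum
    # of every triangle it belongs to
    for (k in removed) {
      ab <- strsplit(k, " ")[[1]]
      others <- setdiff(net$nodes$node, ab)
      in_tri <- vapply(others, function(c_) {
        k1 <- paste(pmin(ab[1], c_), pmax(ab[1], c_))
        k2 <- paste(pmin(ab[2], c_), pmax(ab[2], c_))
        all(c(k1, k2) %in% key)
      }, logical(1))
      mins <- vapply(others[in_tri], function(c_) {
        k1 <- paste(pmin(ab[1], c_), pmax(ab[1], c_))
        k2 <- paste(pmin(ab[2], c_), pmax(ab[2], c_))
        min(w[[k1]], w[[k2]])
      }, numeric(1))
      expect_true(any(w[[k]] < mins))
    }
  }
})

test_that("permutation p-values behave at the extremes", {
  set.seed(15)
  n <- 40
  m <- matrix(rnorm(12 * n), 12, n, dimnames = list(sprintf("f%02d", 1:12), NULL))
  shared <- rnorm(n)
  m[1, ] <- 0.97 * shared + sqrt(1 - 0.97^2) * rnorm(n)
  m[2, ] <- 0.97 * shared + sqrt(1 - 0.97^2) * rnorm(n)
  ranks <- rank_transform(m)
  mm <- mi_matrix(ranks)
  pv <- edge_pvalues(mm, ranks, n_perm = 1000, seed = 1, tail_fit = FALSE)
  # pairs whose MI clips to zero sit at the bottom of the null: p = 1
  expect_true(all(pv$p_value[pv$mi == 0] == 1))
  # and the bulk of null pairs cannot look significant (pairs share
  # features, so the mean is the stable summary here)
  expect_gte(mean(pv$p_value), 0.4)
  # the planted pair exceeds every null draw: plus-one rule floor
  strong <- pv[pv$node_a == "f01" & pv$node_b == "f02", ]
  expect_equal(strong$p_value, 1 / 1001, tolerance = 1e-12)
  # Bonferroni never exceeds 1 and scales by the class pair count
  expect_true(all(pv$p_adj <= 1))
  expect_error(edge_pvalues(mm, ranks, n_perm = 50), class = "mirnet_usage_error")
})

test_that("permutation p-values are uniform under the global null", {
  set.seed(16)
  n <- 40
  m <- matrix(rnorm(35 * n), 35, n, dimnames = list(sprintf("f%02d", 1:35), NULL))
  ranks <- rank_transform(m)
  mm <- mi_matrix(ranks)
  pv <- edge_pvalues(mm, ranks, n_perm = 1000, seed = 2, tail_fit = FALSE)
  # the zero-clipped estimator puts an atom of MI ties at zero, which maps
  # to an atom of p-values at 1; the null is therefore super-uniform
  # rather than uniform, and significance is never overstated
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pv$p_value <= a),
               a + 3 * sqrt(a * (1 - a) / nrow(pv)))
  }
  expect_gt(mean(pv$p_value), 0.5)
})

test_that("build_network bookkeeping, thresholds and determinism", {
  synth <- default_synth()
  prep <- suppressWarnings(
    preprocess_condition(synth$tumour$mir_counts, synth$tumour$mrna_tpm))
  small <- subset_expr(prep$joint,
                       features = prep$joint$features$feature_id[
                         prep$joint$features$kind == "miR" |
                           seq_len(nrow(prep$joint$values)) <= 200])
  cfg <- synthetic_run_config()
  net1 <- build_network(small, q_mm = cfg$q_mm, q_mi = cfg$q_mi, n_perm = 0)
  thr <- attr(net1, "thresholds")
  # edges before DPI equal the per-class retained counts
  expect_identical(attr(net1, "n_edges_pre_dpi"),
                   as.integer(sum(thr$n_retained)))
  # every surviving edge is at or above its class cutoff
  e <- mirnet:::live_edges(net1)
  cuts <- stats::setNames(thr$cutoff, thr$class)
  expect_true(all(e$mi >= cuts[e$class]))
  # rebuilding from the same input is identical
  net2 <- build_network(small, q_mm = cfg$q_mm, q_mi = cfg$q_mi, n_perm = 0)
  expect_identical(net1$edges, net2$edges)
})
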