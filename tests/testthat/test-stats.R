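test_that("BH adjustment matches hand-executed step-up on fixed vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # order of input preserved; permutation-invariant up to reordering
  p <- c(0.04, 0.001, 0.7, 0.01)
  adj <- bh_adjust(p)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  # monotone non-decreasing in sorted-p order
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 0)), class = "mirnet_usage_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mirnet_usage_error")
})

test_that("identical tumour/control counts give log2FC 0 and flag ns", {
  set.seed(31)
  counts <- matrix(rnbinom(30 * 10, mu = 100, size = 5), 30, 10)
  tum <- toy_expr(counts, condition = rep("tumour", 10))
  ctl <- toy_expr(counts, condition = rep("control", 10))
  de <- differential_expression(tum, ctl)
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$flag == "ns"))
})

test_that("a planted fourfold shift is detected with log2FC near 2", {
  set.seed(32)
  n <- 30
  base <- matrix(rnbinom(200 * n, mu = 200, size = 8), 200, n)
  tum_counts <- base
  tum_counts[1, ] <- rnbinom(n, mu = 800, size = 8)  # 4x feature 1
  ctl <- toy_expr(base, condition = rep("control", n))
  tum <- toy_expr(tum_counts, condition = rep("tumour", n))
  de <- differential_expression(tum, ctl)
  expect_equal(de$log2fc[1], 2, tolerance = 0.1)
  expect_identical(de$flag[1], "up")
  # sign-test oracle on the per-pair direction
  wins <- sum(tum_counts[1, ] > base[1, ])
  expect_lt(binom.test(wins, n)$p.value, 0.01)
})

test_that("paired design contracts are enforced", {
  counts <- matrix(rpois(20, 50), 10, 2)
  tum <- toy_expr(counts, condition = rep("tumour", 2))
  ctl <- toy_expr(counts, condition = rep("control", 2))
  expect_error(differential_expression(tum, ctl), class = "mirnet_usage_error")
  ctl2 <- toy_expr(counts[1:9, , drop = FALSE], condition = rep("control", 2))
  expect_error(differential_expression(tum, ctl2), class = "mirnet_usage_error")
})

test_that("size factors match DESeq2's median-of-ratios", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  counts <- matrix(rnbinom(300 * 8, mu = 150, size = 4) + 1, 300, 8)
  ours <- mirnet:::size_factors(counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-9)
})

test_that("hypergeometric p equals direct combinatorial summation", {
  # spot grid across the N <= 60 range at 1e-12 relative error
  set.seed(34)
  for (N in c(5, 12, 20, 41, 60)) {
    for (rep in 1:20) {
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      k_max <- min(K, n)
      k <- sample(0:k_max, 1)
      sets <- tibble::tibble(set_id = "s", name = "s", category = NA,
                             members = list(sprintf("g%03d", seq_len(K))),
                             size = K)
      universe <- sprintf("g%03d", seq_len(N))
      # query with overlap exactly k
      query <- c(sprintf("g%03d", seq_len(k)),
                 sprintf("g%03d", K + seq_len(n - k)))
      if (n - k > N - K) next
      res <- suppressWarnings(
        hypergeometric_enrichment(query, sets, universe))
      expect_equal(res$p_value, hyper_tail_oracle(N, K, res$n, res$k),
                   tolerance = 1e-12)
    }
  }
  # closed-form corner: all n draws inside the set
  sets <- tibble::tibble(set_id = "s", name = "s", category = NA,
                         members = list(sprintf("g%02d", 1:5)), size = 5L)
  res <- hypergeometric_enrichment(sprintf("g%02d", 1:5), sets,
                                   sprintf("g%02d", 1:20))
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
})

test_that("enrichment filters and edge cases", {
  universe <- sprintf("g%04d", 1:1500)
  sets <- tibble::tibble(
    set_id = c("big", "small"), name = c("big", "small"), category = NA,
    members = list(universe[1:1200], universe[1:20]),
    size = c(1200L, 20L)
  )
  res <- hypergeometric_enrichment(universe[1:30], sets, universe)
  big <- res[res$set_id == "big", ]
  expect_lt(big$fdr, 0.01)
  expect_false(big$passes_filters)  # size filter
  # zero overlap when K + n <= N gives p = 1
  res2 <- hypergeometric_enrichment(universe[1001:1020], sets[2, ], universe)
  expect_identical(res2$k, 0L)
  expect_equal(res2$p_value, 1)
  # query genes outside the universe are dropped with a warning
  expect_warning(
    hypergeometric_enrichment(c(universe[1:5], "alien"), sets, universe),
    "outside"
  )
  expect_error(hypergeometric_enrichment("g1", sets, character()),
               class = "mirnet_usage_error")
})

test_that("enrichment is invariant under consistent relabelling", {
  set.seed(35)
  universe <- sprintf("g%03d", 1:100)
  sets <- tibble::tibble(
    set_id = sprintf("s%d", 1:5), name = "x", category = NA,
    members = replicate(5, sample(universe, 15), simplify = FALSE),
    size = 15L
  )
  query <- sample(universe, 25)
  res1 <- hypergeometric_enrichment(query, sets, universe)
  relabel <- stats::setNames(sample(sprintf("h%03d", 1:100)), universe)
  sets2 <- sets
  sets2$members <- lapply(sets$members, function(m) unname(relabel[m]))
  res2 <- hypergeometric_enrichment(unname(relabel[query]), sets2,
                                    unname(relabel))
  expect_equal(res1$p_value, res2$p_value)
})

test_that("positional enrichment: closed-form corner and planted recovery", {
  ann <- tibble::tibble(
    feature_id = sprintf("m%02d", 1:20), kind = "miR",
    chromosome = c(rep("chrA", 6), rep("chrB", 14)),
    start = 1L, end = 10L, strand = "+", family = NA_character_,
    cluster = c(rep("regionA", 6), rep(NA, 14))
  )
  universe <- ann$feature_id
  # all network miRs inside the region, K = n = k
  res <- positional_enrichment(sprintf("m%02d", 1:6), ann, "regionA", universe)
  expect_equal(res$p_value, 1 / choose(20, 6), tolerance = 1e-12)
  expect_error(positional_enrichment("m01", ann, "nope", universe),
               class = "mirnet_usage_error")
  # uniformly drawn node sets give uniform-ish p once the support is rich
  # enough for the discreteness to fade
  ann_big <- tibble::tibble(
    feature_id = sprintf("M%03d", 1:200), kind = "miR",
    chromosome = "chrA", start = 1L, end = 10L, strand = "+",
    family = NA_character_,
    cluster = c(rep("regionB", 40), rep(NA, 160))
  )
  set.seed(36)
  ps <- replicate(300, {
    nodes <- sample(ann_big$feature_id, 50)
    positional_enrichment(nodes, ann_big, "regionB",
                          ann_big$feature_id)$p_value
  })
  # the null p is discrete hence super-uniform: P(p <= a) <= a, and the
  # bulk must not pile up near zero
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 300))
  }
  expect_gt(mean(ps), 0.4)
})

test_that("db overlap counts matched edges under both id policies", {
  kinds <- stats::setNames(c("miR", "miR", "mRNA", "mRNA"),
                           c("m1", "m2", "g1", "g2"))
  net <- mi_network(
    nodes = tibble::tibble(node = names(kinds), kind = unname(kinds)),
    edges = tibble::tibble(node_a = c("g1", "g2", "m1"),
                           node_b = c("m1", "m2", "m2"),
                           mi = c(0.4, 0.5, 0.6),
                           class = c("miR-mRNA", "miR-mRNA", "miR-miR"))
  )
  db_exact <- tibble::tibble(mir_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                             source = "validated")
  ov <- db_overlap(net, db_exact)
  expect_identical(ov$summary$n_matched, 2L)
  expect_equal(ov$summary$fraction_matched, 1)
  # empty db
  ov0 <- db_overlap(net, db_exact[0, ])
  expect_identical(nrow(ov0$matched), 0L)
  # family-level matching maps member ids onto the family label
  fam <- tibble::tibble(feature_id = c("m1", "m1b"), family = "famX")
  db_fam <- tibble::tibble(mir_id = "m1b", gene_id = "g1", source = "predicted")
  ov_exact <- db_overlap(net, db_fam)
  expect_identical(ov_exact$summary$n_matched, 0L)
  ov_fam <- db_overlap(net, db_fam, family_map = fam, family_level = TRUE)
  expect_identical(ov_fam$summary$n_matched, 1L)
})

test_that("db overlap at half noise lands inside the binomial band", {
  synth <- default_synth()
  run <- default_run()
  db <- synthetic_interaction_db(synth, noise_fraction = 0.5, n_records = 200,
                                 seed = 77)
  ov <- db_overlap(run$networks$tumour, db)
  # the validated half is drawn from planted edges; decoys are not.
  per_source <- split(ov$summary, ov$summary$source)
  expect_gt(per_source$validated$n_matched, per_source$predicted$n_matched)
})
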