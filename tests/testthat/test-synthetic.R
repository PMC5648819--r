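test_that("generated dataset has the requested shape and bookkeeping", {
  cfg <- synthetic_config(n_mrna = 120, n_mir = 40, n_pairs = 20, seed = 7,
                          hub_control = list(family = "fc", n_members = 3,
                                             n_targets = 10, coupling = 0.9,
                                             target_coupling = 0.8),
                          hub_tumour = list(family = "ft", n_members = 3,
                                            n_targets = 10, coupling = 0.9,
                                            target_coupling = 0.8),
                          cluster = list(label = "cl", chromosome = "chrX",
                                         n_members = 5, coupling = 0.9,
                                         shift = -1.5),
                          core = list(n_edges = 8, coupling = 0.9,
                                      mir_shift = 1.5, mrna_shift = -1.5))
  synth <- synthetic_dataset(cfg)
  for (cond in c("tumour", "control")) {
    expect_identical(dim(synth[[cond]]$mir_counts$values), c(40L, 20L))
    expect_identical(dim(synth[[cond]]$mrna_counts$values), c(120L, 20L))
    expect_identical(dim(synth[[cond]]$mrna_tpm$values), c(120L, 20L))
  }
  # pair ids identical across conditions
  expect_identical(synth$tumour$mir_counts$samples$pair_id,
                   synth$control$mir_counts$samples$pair_id)
  tr <- synth$truth
  expect_identical(nrow(tr$core_pairs), 8L)
  expect_length(tr$cluster_members, 5)
  expect_identical(sum(tr$planted_edges$role == "cluster"), 10L)
  # planted edge endpoints exist
  all_ids <- synth$annotation$feature_id
  expect_true(all(tr$planted_edges$node_a %in% all_ids))
  expect_true(all(tr$planted_edges$node_b %in% all_ids))
  # cluster members share one chromosome, contiguous window
  cl_ann <- synth$annotation[synth$annotation$feature_id %in% tr$cluster_members, ]
  expect_identical(unique(cl_ann$chromosome), "chrX")
  expect_lte(max(cl_ann$end) - min(cl_ann$start), 200000)
})

test_that("same seed and config give bit-identical output", {
  a <- synthetic_dataset(synthetic_config(n_mrna = 60, n_mir = 30,
                                          n_pairs = 15, seed = 3,
                                          core = list(n_edges = 5, coupling = 0.9,
                                                      mir_shift = 1.5,
                                                      mrna_shift = -1.5)))
  b <- synthetic_dataset(synthetic_config(n_mrna = 60, n_mir = 30,
                                          n_pairs = 15, seed = 3,
                                          core = list(n_edges = 5, coupling = 0.9,
                                                      mir_shift = 1.5,
                                                      mrna_shift = -1.5)))
  expect_identical(a$tumour$mir_counts$values, b$tumour$mir_counts$values)
  expect_identical(a$control$mrna_tpm$values, b$control$mrna_tpm$values)
  expect_identical(a$truth$de_features, b$truth$de_features)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(de_log2fc = 0.5), class = "mirnet_config_error")
  expect_error(
    synthetic_config(n_mrna = 30,
                     hub_control = list(family = "f", n_members = 2,
                                        n_targets = 20, coupling = 0.9),
                     hub_tumour = list(family = "g", n_members = 2,
                                       n_targets = 20, coupling = 0.9)),
    class = "mirnet_config_error"
  )
  s <- default_synth()
  expect_error(synthetic_interaction_db(s, noise_fraction = 1.5),
               class = "mirnet_config_error")
})

test_that("zero coupling removes planted-pair correlation; strong coupling creates it", {
  base_cfg <- function(coupling) {
    synthetic_config(
      n_mrna = 80, n_mir = 40, n_pairs = 80, seed = 11,
      hub_control = list(family = "fc", n_members = 2, n_targets = 5,
                         coupling = coupling, target_coupling = coupling),
      hub_tumour = list(family = "ft", n_members = 2, n_targets = 5,
                        coupling = coupling, target_coupling = coupling),
      cluster = list(label = "cl", chromosome = "chrX", n_members = 3,
                     coupling = coupling, shift = -1.5),
      core = list(n_edges = 25, coupling = coupling,
                  mir_shift = 1.5, mrna_shift = -1.5)
    )
  }
  pair_cor <- function(synth) {
    m <- rbind(synth$control$mir_counts$values, synth$control$mrna_counts$values)
    tr <- synth$truth$core_pairs
    planted <- abs(mapply(function(a, b) cor(m[a, ], m[b, ], method = "spearman"),
                          tr$mir_id, tr$gene_id))
    set.seed(99)
    varying <- rownames(m)[apply(m, 1, function(v) length(unique(v)) > 1)]
    rnd <- replicate(200, {
      ij <- sample(varying, 2)
      abs(cor(m[ij[1], ], m[ij[2], ], method = "spearman"))
    })
    list(planted = planted, random = rnd)
  }
  null_case <- pair_cor(synthetic_dataset(base_cfg(0)))
  p0 <- wilcox.test(null_case$planted, null_case$random)$p.value
  expect_gt(p0, 0.01)

  strong <- pair_cor(synthetic_dataset(base_cfg(0.9)))
  expect_gt(mean(strong$planted), quantile(strong$random, 0.99))
})

test_that("planted-vs-random correlation separation grows with coupling", {
  sep <- vapply(c(0.3, 0.6, 0.9), function(cp) {
    cfg <- synthetic_config(
      n_mrna = 140, n_mir = 60, n_pairs = 60, seed = 5,
      core = list(n_edges = 20, coupling = cp, mir_shift = 1.5,
                  mrna_shift = -1.5)
    )
    synth <- synthetic_dataset(cfg)
    m <- rbind(synth$control$mir_counts$values, synth$control$mrna_counts$values)
    tr <- synth$truth$core_pairs
    mean(abs(mapply(function(a, b) cor(m[a, ], m[b, ], method = "spearman"),
                    tr$mir_id, tr$gene_id)))
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("counts are over-dispersed relative to Poisson", {
  synth <- default_synth()
  m <- synth$control$mrna_counts$values
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  hi <- mu > 50  # dispersion dominates shot noise here
  expect_gt(mean(v[hi] > mu[hi]), 0.95)
})

test_that("gene-set collections exercise the documented filters", {
  synth <- default_synth()
  sets <- synthetic_gene_sets(synth)
  expect_gte(sum(grepl("^sig_", sets$go$set_id)), 3)
  expect_gte(sum(grepl("^rand_", sets$go$set_id)), 20)
  expect_gte(max(sets$go$size), 1000)
  expect_lte(min(sets$pathways$size), 3)
  # signal sets overlap their planted blocks
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  sig <- sets$go$members[[which(sets$go$set_id == "sig_hub_tumour")]]
  expect_gte(jac(sig, synth$truth$hub_targets$tumour), 0.6)
})

test_that("random gene sets are unenriched (uniform-ish hypergeometric p)", {
  synth <- default_synth()
  mrna_ids <- synth$annotation$feature_id[synth$annotation$kind == "mRNA"]
  set.seed(21)
  sets <- tibble::tibble(
    set_id = sprintf("r%03d", 1:200), name = "r", category = NA,
    members = replicate(200, sample(mrna_ids, 25), simplify = FALSE),
    size = 25L
  )
  query <- sample(mrna_ids, 60)
  res <- hypergeometric_enrichment(query, sets, mrna_ids, fdr_max = 0.01)
  # discrete null p-values are super-uniform: no excess mass at any level
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(res$p_value <= a), a + 3 * sqrt(a * (1 - a) / 200))
  }
  expect_gt(mean(res$p_value), 0.4)
})

test_that("interaction db respects the noise fraction exactly", {
  synth <- default_synth()
  truth_keys <- with(synth$truth, {
    planted <- rbind(
      data.frame(m = core_pairs$mir_id, g = core_pairs$gene_id),
      expand.grid(m = hub_members$tumour, g = hub_targets$tumour,
                  stringsAsFactors = FALSE),
      expand.grid(m = hub_members$control, g = hub_targets$control,
                  stringsAsFactors = FALSE)
    )
    paste(planted$m, planted$g)
  })
  db0 <- synthetic_interaction_db(synth, noise_fraction = 0, n_records = 60)
  expect_true(all(paste(db0$mir_id, db0$gene_id) %in% truth_keys))
  db1 <- synthetic_interaction_db(synth, noise_fraction = 1, n_records = 60)
  expect_false(any(paste(db1$mir_id, db1$gene_id) %in% truth_keys))
  db5 <- synthetic_interaction_db(synth, noise_fraction = 0.5, n_records = 100)
  expect_identical(sum(paste(db5$mir_id, db5$gene_id) %in% truth_keys), 50L)
})
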