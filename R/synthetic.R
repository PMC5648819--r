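#' Synthetic paired tumour/control dataset configuration
#'
#' Parameters of the planted-structure generator. The defaults describe the
#' benchmark conditions used throughout the package's tests: 300 mRNAs and
#' 150 miRs over 80 matched patients, one control-active and one
#' tumour-active hub miR family co-expressed with dedicated target mRNA
#' blocks, a genomically clustered co-expressed miR block (tumour-active,
#' shifted down in tumour), a conserved core of miR-mRNA pairs present in
#' both conditions with the miR up- and the mRNA down-shifted in tumour,
#' and planted two-fold-plus differential expression on background
#' features.
#'
#' @param n_mrna,n_mir,n_pairs problem size (features, matched patients).
#' @param seed integer seed; the same seed and config give bit-identical
#'   output.
#' @param hub_control,hub_tumour lists: `family`, `n_members`, `n_targets`,
#'   `coupling` (latent loading of the miR members, in \[0, 1\]) and
#'   `target_coupling` (loading of the target mRNAs; the pairwise latent
#'   correlation of two features is the product of their loadings). Members
#'   load more strongly than targets so that miR-miR associations dominate
#'   miR-mRNA ones, which in turn dominate the indirect mRNA-mRNA ones
#'   pruned by the DPI.
#' @param cluster list: `label`, `chromosome`, `n_members`, `coupling`,
#'   `shift` (tumour log2 shift).
#' @param core list: `n_edges`, `coupling`, `mir_shift`, `mrna_shift`
#'   (tumour log2 shifts).
#' @param de_fraction fraction of background features given a planted
#'   tumour/control shift.
#' @param de_log2fc magnitude of that shift (>= 1 so planted DE passes a
#'   twofold rule).
#' @param nb_dispersion negative-binomial dispersion of the counts.
#' @param library_size_range per-sample library-size multiplier range.
#' @param bio_sd biological log2-sd driving the latent signal.
#' @param patient_effect_frac fraction of a background feature's biological
#'   variance shared between a patient's tumour and control samples. Matched
#'   designs exist because much inter-sample variation is patient-level;
#'   the paired tests exploit exactly this component. Factor-coupled
#'   features (hubs, cluster, core) model condition-specific co-expression
#'   programs and keep fully condition-specific variation.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mrna = 300, n_mir = 150, n_pairs = 80, seed = 1,
                             hub_control = list(family = "mirfam-ctl",
                                                n_members = 5, n_targets = 25,
                                                coupling = 0.95,
                                                target_coupling = 0.8),
                             hub_tumour = list(family = "mirfam-tum",
                                               n_members = 5, n_targets = 25,
                                               coupling = 0.95,
                                               target_coupling = 0.8),
                             cluster = list(label = "clusterS14",
                                            chromosome = "chrS14",
                                            n_members = 12, coupling = 0.9,
                                            shift = -1.5),
                             core = list(n_edges = 20, coupling = 0.9,
                                         mir_shift = 1.5, mrna_shift = -1.5),
                             de_fraction = 0.10, de_log2fc = 2,
                             nb_dispersion = 0.15,
                             library_size_range = c(0.7, 1.3),
                             bio_sd = 1.2, patient_effect_frac = 0.5) {
  cfg <- list(n_mrna = n_mrna, n_mir = n_mir, n_pairs = n_pairs, seed = seed,
              hub_control = hub_control, hub_tumour = hub_tumour,
              cluster = cluster, core = core, de_fraction = de_fraction,
              de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
              library_size_range = library_size_range, bio_sd = bio_sd,
              patient_effect_frac = patient_effect_frac)
  if (any(c(n_mrna, n_mir, n_pairs) <= 0)) {
    abort("sizes must be positive.", class = "mirnet_config_error")
  }
  if (de_log2fc < 1) {
    abort("de_log2fc must be >= 1 (planted DE must pass a twofold rule).",
          class = "mirnet_config_error")
  }
  n_target <- hub_control$n_targets + hub_tumour$n_targets + core$n_edges
  if (n_target > n_mrna) {
    abort("planted target counts exceed n_mrna.", class = "mirnet_config_error")
  }
  n_planted_mir <- hub_control$n_members + hub_tumour$n_members +
    cluster$n_members + core$n_edges
  if (n_planted_mir > n_mir) {
    abort("planted miR counts exceed n_mir.", class = "mirnet_config_error")
  }
  structure(cfg, class = c("synthetic_config", "list"))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the synthetic dataset
#'
#' Latent Gaussian factors drive per-feature log2-means: hub family members
#' load on one factor together with their target mRNAs (the coupling is
#' active only in the hub's condition), cluster miRs share a locus factor
#' (tumour-active) and are shifted down in tumour, and each conserved-core
#' miR-mRNA pair shares its own factor in both conditions with the miR mean
#' shifted up and the mRNA mean shifted down in tumour. Counts are drawn
#' negative-binomial around `library_size * 2^z`; mRNA abundance is also
#' emitted as a TPM-like matrix using fixed synthetic transcript lengths.
#' Non-planted features are independent given library size.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `mirnet_synth`: per condition (`tumour`,
#'   `control`) the [expr_matrix()] objects `mir_counts`, `mrna_counts`,
#'   `mrna_tpm`; plus `annotation`, `truth`, `gene_lengths`, `config`.
#'   `truth` holds `planted_edges` (tibble: `node_a`, `node_b`, `condition`,
#'   `role`), `hub_members`, `hub_targets`, `cluster_members`,
#'   `cluster_label`, `de_features` (tibble: `feature_id`, `true_log2fc`).
#' @export
synthetic_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  mir_ids <- sprintf("miR-%03d", seq_len(cfg$n_mir))
  mrna_ids <- sprintf("gene-%03d", seq_len(cfg$n_mrna))

  # ---- deterministic feature layout ----
  hc <- cfg$hub_control; ht <- cfg$hub_tumour; cl <- cfg$cluster; co <- cfg$core
  i <- 0
  hub_c_mirs <- mir_ids[i + seq_len(hc$n_members)]; i <- i + hc$n_members
  hub_t_mirs <- mir_ids[i + seq_len(ht$n_members)]; i <- i + ht$n_members
  cluster_mirs <- mir_ids[i + seq_len(cl$n_members)]; i <- i + cl$n_members
  core_mirs <- mir_ids[i + seq_len(co$n_edges)]; i <- i + co$n_edges
  free_mirs <- mir_ids[-seq_len(i)]
  j <- 0
  hub_c_targets <- mrna_ids[j + seq_len(hc$n_targets)]; j <- j + hc$n_targets
  hub_t_targets <- mrna_ids[j + seq_len(ht$n_targets)]; j <- j + ht$n_targets
  core_mrnas <- mrna_ids[j + seq_len(co$n_edges)]; j <- j + co$n_edges
  free_mrnas <- mrna_ids[-seq_len(j)]

  all_ids <- c(mir_ids, mrna_ids)
  p <- length(all_ids)
  kind <- c(rep("miR", cfg$n_mir), rep("mRNA", cfg$n_mrna))

  # factor group per feature: 0 = none; loading matrix built per condition
  grp <- setNames(integer(p), all_ids)
  grp[c(hub_c_mirs, hub_c_targets)] <- 1L
  grp[c(hub_t_mirs, hub_t_targets)] <- 2L
  grp[cluster_mirs] <- 3L
  core_grp_base <- 3L
  grp[core_mirs] <- core_grp_base + seq_along(core_mirs)
  grp[core_mrnas] <- core_grp_base + seq_along(core_mrnas)
  n_factors <- core_grp_base + co$n_edges
  loading <- setNames(numeric(p), all_ids)
  loading[hub_c_mirs] <- hc$coupling
  loading[hub_c_targets] <- hc$target_coupling %||% hc$coupling
  loading[hub_t_mirs] <- ht$coupling
  loading[hub_t_targets] <- ht$target_coupling %||% ht$coupling
  loading[cluster_mirs] <- cl$coupling
  loading[c(core_mirs, core_mrnas)] <- co$coupling
  # condition gating: group active in tumour and/or control
  grp_active <- matrix(TRUE, n_factors, 2, dimnames = list(NULL, c("control", "tumour")))
  grp_active[1, "tumour"] <- FALSE   # control hub
  grp_active[2, "control"] <- FALSE  # tumour hub
  grp_active[3, "control"] <- FALSE  # genomic cluster (tumour-specific block)

  with_seed(cfg$seed, {
    # base abundance (log2); planted features kept well above the filters
    base <- setNames(numeric(p), all_ids)
    planted_mir <- c(hub_c_mirs, hub_t_mirs, cluster_mirs, core_mirs)
    planted_mrna <- c(hub_c_targets, hub_t_targets, core_mrnas)
    base[planted_mir] <- runif(length(planted_mir), 6, 9)
    base[planted_mrna] <- runif(length(planted_mrna), 6, 9)
    base[free_mirs] <- runif(length(free_mirs), 1, 9)
    base[free_mrnas] <- runif(length(free_mrnas), 1, 9)
    # a slice of background features sits below the count/TPM filters
    low_mirs <- free_mirs[seq_len(min(15, length(free_mirs)))]
    low_mrnas <- free_mrnas[seq_len(min(20, length(free_mrnas)))]
    base[low_mirs] <- runif(length(low_mirs), -2, 1)
    base[low_mrnas] <- runif(length(low_mrnas), -6, -3)

    # tumour shifts (log2FC truth)
    delta <- setNames(numeric(p), all_ids)
    delta[core_mirs] <- co$mir_shift
    delta[core_mrnas] <- co$mrna_shift
    delta[cluster_mirs] <- cl$shift
    de_pool <- c(setdiff(free_mirs, low_mirs), setdiff(free_mrnas, low_mrnas))
    n_de <- round(cfg$de_fraction * length(de_pool))
    de_feats <- sample(de_pool, n_de)
    delta[de_feats] <- cfg$de_log2fc * sample(c(-1, 1), n_de, replace = TRUE)

    gene_lengths <- setNames(round(runif(cfg$n_mrna, 500, 5000)), mrna_ids)
    # patient-level biological effect, shared between a patient's tumour
    # and control samples (background features only)
    pf <- cfg$patient_effect_frac %||% 0
    patient_z <- matrix(rnorm(p * cfg$n_pairs), p, cfg$n_pairs)

    simulate_condition <- function(condition) {
      n <- cfg$n_pairs
      fac <- matrix(rnorm(n_factors * n), n_factors, n)
      z <- matrix(0, p, n)
      for (f in seq_len(p)) {
        g <- grp[[f]]
        if (g == 0) {
          z[f, ] <- sqrt(pf) * patient_z[f, ] + sqrt(1 - pf) * rnorm(n)
          next
        }
        lam_f <- if (grp_active[g, condition]) loading[[f]] else 0
        z[f, ] <- lam_f * fac[g, ] + sqrt(1 - lam_f^2) * rnorm(n)
      }
      logmu <- base + (condition == "tumour") * delta + cfg$bio_sd * z
      lib <- runif(n, cfg$library_size_range[1], cfg$library_size_range[2])
      mu <- sweep(2^logmu, 2, lib, "*")
      counts <- matrix(rnbinom(p * n, mu = mu, size = 1 / cfg$nb_dispersion),
                       p, n, dimnames = list(all_ids, NULL))
      samp_ids <- sprintf("%s-%s", sprintf("P%03d", seq_len(n)),
                          ifelse(condition == "tumour", "T", "C"))
      colnames(counts) <- samp_ids
      samples <- tibble(sample_id = samp_ids, condition = condition,
                        pair_id = sprintf("P%03d", seq_len(n)))
      mir_counts <- expr_matrix(counts[mir_ids, , drop = FALSE],
                                tibble(feature_id = mir_ids, kind = "miR"),
                                samples, value_space = "raw_counts")
      mrna_counts <- expr_matrix(counts[mrna_ids, , drop = FALSE],
                                 tibble(feature_id = mrna_ids, kind = "mRNA"),
                                 samples, value_space = "raw_counts")
      rate <- counts[mrna_ids, , drop = FALSE] / gene_lengths
      tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
      mrna_tpm <- expr_matrix(tpm, tibble(feature_id = mrna_ids, kind = "mRNA"),
                              samples, value_space = "normalized")
      list(mir_counts = mir_counts, mrna_counts = mrna_counts,
           mrna_tpm = mrna_tpm)
    }

    tumour <- simulate_condition("tumour")
    control <- simulate_condition("control")

    # ---- annotation ----
    chroms <- sprintf("chrS%d", 1:5)
    ann_chrom <- setNames(rep(chroms, length.out = p), all_ids)
    ann_start <- setNames(10000L + 5000L * seq_len(p), all_ids)
    # cluster miRs: one 200 kb window on their own chromosome
    ann_chrom[cluster_mirs] <- cl$chromosome
    ann_start[cluster_mirs] <- 100000L + 20000L * (seq_along(cluster_mirs) - 1L)
    width <- ifelse(kind == "miR", 80L, 2000L)
    family <- setNames(rep(NA_character_, p), all_ids)
    family[hub_c_mirs] <- hc$family
    family[hub_t_mirs] <- ht$family
    cluster_lab <- setNames(rep(NA_character_, p), all_ids)
    cluster_lab[cluster_mirs] <- cl$label
    annotation <- tibble(
      feature_id = all_ids, kind = kind,
      chromosome = unname(ann_chrom),
      start = unname(ann_start), end = unname(ann_start) + width,
      strand = rep(c("+", "-"), length.out = p),
      family = unname(family), cluster = unname(cluster_lab)
    )

    # ---- truth ----
    pair_tbl <- function(ids, condition, role) {
      if (length(ids) < 2) return(NULL)
      cmb <- utils::combn(sort(ids), 2)
      tibble(node_a = cmb[1, ], node_b = cmb[2, ],
             condition = condition, role = role)
    }
    sort_pair <- function(a, b) {
      tibble(node_a = pmin(a, b), node_b = pmax(a, b))
    }
    planted_edges <- bind_rows(
      pair_tbl(c(hub_c_mirs, hub_c_targets), "control", "hub_control"),
      pair_tbl(c(hub_t_mirs, hub_t_targets), "tumour", "hub_tumour"),
      pair_tbl(cluster_mirs, "tumour", "cluster"),
      dplyr::bind_cols(sort_pair(core_mirs, core_mrnas),
                       tibble(condition = "both", role = "core"))
    )
    truth <- list(
      planted_edges = planted_edges,
      hub_members = list(control = hub_c_mirs, tumour = hub_t_mirs),
      hub_families = list(control = hc$family, tumour = ht$family),
      hub_targets = list(control = hub_c_targets, tumour = hub_t_targets),
      cluster_members = cluster_mirs,
      cluster_label = cl$label,
      core_pairs = tibble(mir_id = core_mirs, gene_id = core_mrnas),
      de_features = tibble(feature_id = names(delta)[delta != 0],
                           true_log2fc = unname(delta[delta != 0]))
    )
    structure(list(tumour = tumour, control = control,
                   annotation = annotation, truth = truth,
                   gene_lengths = gene_lengths, config = cfg),
              class = "mirnet_synth")
  })
}

#' @export
print.mirnet_synth <- function(x, ...) {
  cat(sprintf("<mirnet_synth> %d miR + %d mRNA x %d pairs (seed %d)\n",
              x$config$n_mir, x$config$n_mrna, x$config$n_pairs,
              x$config$seed))
  cat(sprintf("  planted: %d edges, %d DE features\n",
              nrow(x$truth$planted_edges), nrow(x$truth$de_features)))
  invisible(x)
}

#' Generate gene-set collections over the synthetic universe
#'
#' Builds two collections: a "GO-like" one — at least three signal sets
#' enriched in the planted target mRNAs (Jaccard with a planted target block
#' at least `signal_overlap`), `n_random` random sets, and one oversized set
#' (> 1000 members, padded with unmeasured ids) to exercise the set-size
#' filter — and a "pathway-like" one with a planted deregulated pathway
#' (tumour-hub targets plus core mRNAs), a sub-minimal pathway (< 4 genes)
#' and random pathways.
#'
#' @param synth a `mirnet_synth` dataset (or its `truth`, plus `mrna_ids`).
#' @param n_random number of random GO-like sets (default 24).
#' @param signal_overlap minimum Jaccard between each signal set and its
#'   planted block (default 0.6).
#' @param seed seed (defaults to the dataset's seed + 1).
#' @return List with tibble collections `go` and `pathways` in the
#'   [read_gmt()] layout.
#' @export
synthetic_gene_sets <- function(synth, n_random = 24, signal_overlap = 0.6,
                                seed = NULL) {
  stopifnot(inherits(synth, "mirnet_synth"))
  truth <- synth$truth
  mrna_ids <- synth$annotation$feature_id[synth$annotation$kind == "mRNA"]
  seed <- seed %||% (synth$config$seed + 1L)
  with_seed(seed, {
    jitter_set <- function(block, universe) {
      # keep most of the block, swap a few members for background genes
      k <- max(1, round(length(block) * (1 - signal_overlap) / 2))
      kept <- setdiff(block, sample(block, k))
      c(kept, sample(setdiff(universe, block), k))
    }
    signal_blocks <- list(
      sig_hub_tumour = truth$hub_targets$tumour,
      sig_hub_control = truth$hub_targets$control,
      sig_core = truth$core_pairs$gene_id
    )
    go_sets <- purrr::imap(signal_blocks, function(block, nm) {
      tibble(set_id = nm, name = paste0("signal set ", nm),
             members = list(sort(unique(jitter_set(block, mrna_ids)))))
    })
    rand_sets <- purrr::map(seq_len(n_random), function(k) {
      size <- sample(10:50, 1)
      tibble(set_id = sprintf("rand_%03d", k),
             name = sprintf("random set %d", k),
             members = list(sort(sample(mrna_ids, size))))
    })
    big <- tibble(set_id = "oversize", name = "oversized set",
                  members = list(c(sample(mrna_ids, 50),
                                   sprintf("unmeasured-%04d", 1:1000))))
    go <- bind_rows(c(go_sets, rand_sets, list(big)))
    go$category <- "GO-like"
    go$size <- lengths(go$members)

    dereg <- sort(unique(c(truth$hub_targets$tumour, truth$core_pairs$gene_id)))
    path_sets <- list(
      tibble(set_id = "pw_dereg", name = "planted deregulated pathway",
             members = list(dereg)),
      tibble(set_id = "pw_tiny", name = "sub-minimal pathway",
             members = list(sample(mrna_ids, 3)))
    )
    rand_pw <- purrr::map(1:10, function(k) {
      tibble(set_id = sprintf("pw_rand_%02d", k),
             name = sprintf("random pathway %d", k),
             members = list(sort(sample(mrna_ids, sample(5:30, 1)))))
    })
    pathways <- bind_rows(c(path_sets, rand_pw))
    pathways$category <- "pathway-like"
    pathways$size <- lengths(pathways$members)
    cols <- c("set_id", "name", "category", "members", "size")
    list(go = go[, cols], pathways = pathways[, cols])
  })
}

#' Generate a synthetic miR-target interaction table
#'
#' Draws a stated fraction of the planted miR-mRNA associations (core pairs
#' and hub-family targets) plus decoy pairs that were never planted.
#'
#' @param synth a `mirnet_synth` dataset.
#' @param noise_fraction fraction of records that are decoys, in \[0, 1\].
#' @param n_records total records (default 100).
#' @param seed seed (defaults to the dataset's seed + 2).
#' @return Interaction tibble (`mir_id`, `gene_id`, `source`).
#' @export
synthetic_interaction_db <- function(synth, noise_fraction = 0.2,
                                     n_records = 100, seed = NULL) {
  stopifnot(inherits(synth, "mirnet_synth"))
  if (noise_fraction < 0 || noise_fraction > 1) {
    abort("noise_fraction must be in [0, 1].", class = "mirnet_config_error")
  }
  truth <- synth$truth
  seed <- seed %||% (synth$config$seed + 2L)
  planted <- bind_rows(
    tibble(mir_id = truth$core_pairs$mir_id, gene_id = truth$core_pairs$gene_id),
    tidyr::expand_grid(mir_id = truth$hub_members$tumour,
                       gene_id = truth$hub_targets$tumour),
    tidyr::expand_grid(mir_id = truth$hub_members$control,
                       gene_id = truth$hub_targets$control)
  )
  # core pairs were built as (miR, mRNA); enforce the column semantics
  mir_ids <- synth$annotation$feature_id[synth$annotation$kind == "miR"]
  mrna_ids <- synth$annotation$feature_id[synth$annotation$kind == "mRNA"]
  stopifnot(all(planted$mir_id %in% mir_ids), all(planted$gene_id %in% mrna_ids))
  with_seed(seed, {
    n_true <- round((1 - noise_fraction) * n_records)
    n_noise <- n_records - n_true
    keep <- planted[sample(nrow(planted), min(n_true, nrow(planted))), ]
    planted_key <- paste(planted$mir_id, planted$gene_id)
    decoys <- tibble(mir_id = character(), gene_id = character())
    while (nrow(decoys) < n_noise) {
      cand <- tibble(mir_id = sample(mir_ids, n_noise, replace = TRUE),
                     gene_id = sample(mrna_ids, n_noise, replace = TRUE))
      cand <- cand[!(paste(cand$mir_id, cand$gene_id) %in% planted_key), ]
      decoys <- distinct(bind_rows(decoys, cand))
    }
    decoys <- decoys[seq_len(n_noise), ]
    db <- bind_rows(mutate(keep, source = "validated"),
                    mutate(decoys, source = "predicted"))
    validate_interactions(db)
  })
}

#' Write a complete synthetic dataset directory
#'
#' Emits every artifact of [synthetic_dataset()] (count and TPM matrices
#' per condition, annotation, GMT collections, interaction table, truth
#' tables) through the package's readers/writers, ready for
#' [run_study()].
#'
#' @param synth a `mirnet_synth` dataset.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(synth, dir) {
  stopifnot(inherits(synth, "mirnet_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  for (cond in c("tumour", "control")) {
    write_expression_tsv(synth[[cond]]$mir_counts, fp(paste0("mir_counts_", cond, ".tsv")))
    write_expression_tsv(synth[[cond]]$mrna_counts, fp(paste0("mrna_counts_", cond, ".tsv")))
    write_expression_tsv(synth[[cond]]$mrna_tpm, fp(paste0("mrna_tpm_", cond, ".tsv")))
  }
  write_annotation_tsv(synth$annotation, fp("annotation.tsv"))
  sets <- synthetic_gene_sets(synth)
  write_gmt(sets$go, fp("go_like.gmt"))
  write_gmt(sets$pathways, fp("pathways.gmt"))
  db <- synthetic_interaction_db(synth)
  write_interactions_tsv(db, fp("interactions.tsv"))
  readr::write_tsv(synth$truth$planted_edges, fp("truth_edges.tsv"), progress = FALSE)
  readr::write_tsv(synth$truth$de_features, fp("truth_de.tsv"), progress = FALSE)
  invisible(dir)
}
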