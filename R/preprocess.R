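#' Filter miRs by minimum count prevalence
#'
#' Keeps a miR iff its count is at least `min_count` in strictly more than
#' `min_sample_frac` of the samples. With the defaults this drops miRs that
#' fail to reach 5 counts in more than 25% of samples — low-abundance
#' features whose MI estimates would be rank noise.
#'
#' @param counts an [expr_matrix()] in `raw_counts` space, all features miR.
#' @param min_count minimum count (default 5).
#' @param min_sample_frac prevalence fraction (default 0.25); the boundary
#'   is strict (`>`), see the vignette.
#' @return The filtered `expr_matrix`; the sample set is unchanged.
#' @export
filter_mir_counts <- function(counts, min_count = 5, min_sample_frac = 0.25) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$value_space != "raw_counts") {
    abort("miR count filter expects raw_counts space.", class = "mirnet_usage_error")
  }
  if (!all(counts$features$kind == "miR")) {
    abort("non-miR features present.", class = "mirnet_usage_error")
  }
  n <- ncol(counts$values)
  keep <- rowSums(counts$values >= min_count) > min_sample_frac * n
  subset_expr(counts, features = counts$features$feature_id[keep])
}

#' Filter mRNAs by mean normalized abundance
#'
#' Keeps a feature iff its mean abundance across samples is at least
#' `min_mean` (default 10, i.e. "less than 10 TPM on average" is dropped;
#' exactly 10 survives).
#'
#' @param tpm an [expr_matrix()] in `normalized` space.
#' @param min_mean minimum mean abundance (default 10).
#' @return The filtered `expr_matrix`.
#' @export
filter_mrna_abundance <- function(tpm, min_mean = 10) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$value_space == "raw_counts") {
    abort("abundance filter expects normalized space.", class = "mirnet_usage_error")
  }
  keep <- rowMeans(tpm$values) >= min_mean
  subset_expr(tpm, features = tpm$features$feature_id[keep])
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' For each sample s against the reference r, with library sizes N and
#' counts y over features with nonzero counts in both:
#' \eqn{M_f = \log_2\frac{y_{fs}/N_s}{y_{fr}/N_r}},
#' \eqn{A_f = \tfrac12\log_2\left(\frac{y_{fs}}{N_s}\cdot\frac{y_{fr}}{N_r}\right)}.
#' The top and bottom `trim_m` fraction by M and `trim_a` fraction by A are
#' discarded and the factor is \eqn{2^{\sum M_f/v_f \,/\, \sum 1/v_f}},
#' weighting each feature by the inverse of its approximate (delta-method)
#' variance
#' \eqn{v_f = \frac{N_s - y_{fs}}{N_s y_{fs}} + \frac{N_r - y_{fr}}{N_r y_{fr}}}.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts an [expr_matrix()] in `raw_counts` space.
#' @param reference_sample sample id of the reference; default picks the
#'   sample whose (count-scaled) upper quartile is closest to the mean upper
#'   quartile.
#' @param trim_m,trim_a two-sided trim fractions (defaults 0.30 / 0.05).
#' @return Tibble `sample_id`, `factor`, plus attributes `method = "TMM"`
#'   and `reference`.
#' @export
tmm_factors <- function(counts, reference_sample = NULL,
                        trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(counts, "expr_matrix"))
  y <- counts$values
  lib <- colSums(y)
  if (any(lib == 0)) abort("sample with zero total count.",
                           class = "mirnet_validation_error")
  if (is.null(reference_sample)) {
    uq <- apply(y, 2, function(v) quantile(v[v > 0], 0.75, type = 7)) / lib
    reference_sample <- colnames(y)[which.min(abs(uq - mean(uq)))]
  }
  stopifnot(reference_sample %in% colnames(y))
  yr <- y[, reference_sample]
  nr <- lib[[reference_sample]]
  f <- vapply(colnames(y), function(s) {
    if (s == reference_sample) return(1)
    ys <- y[, s]
    ns <- lib[[s]]
    ok <- ys > 0 & yr > 0
    m <- log2((ys[ok] / ns) / (yr[ok] / nr))
    a <- 0.5 * log2((ys[ok] / ns) * (yr[ok] / nr))
    v <- (ns - ys[ok]) / (ns * ys[ok]) + (nr - yr[ok]) / (nr * yr[ok])
    # two-sided trim by rank (average ranks on ties, the canonical
    # convention): keep features inside both trimmed ranges
    nf <- length(m)
    lo_m <- floor(nf * trim_m) + 1
    hi_m <- nf + 1 - lo_m
    lo_a <- floor(nf * trim_a) + 1
    hi_a <- nf + 1 - lo_a
    rm_ <- rank(m)
    ra_ <- rank(a)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep)) return(1)
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  out <- tibble(sample_id = colnames(y), factor = unname(f))
  attr(out, "method") <- "TMM"
  attr(out, "reference") <- reference_sample
  out
}

#' Apply TMM factors as counts-per-million
#'
#' Divides each sample by its effective library size (raw library size times
#' its TMM factor) and scales to counts per million.
#'
#' @param counts an [expr_matrix()] in `raw_counts` space.
#' @param factors output of [tmm_factors()]; computed if `NULL`.
#' @return An `expr_matrix` in `normalized` space.
#' @export
tmm_cpm <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "expr_matrix"))
  factors <- factors %||% tmm_factors(counts)
  stopifnot(setequal(factors$sample_id, colnames(counts$values)))
  f <- factors$factor[match(colnames(counts$values), factors$sample_id)]
  eff <- colSums(counts$values) * f
  vals <- sweep(counts$values, 2, eff, "/") * 1e6
  expr_matrix(vals, counts$features, counts$samples,
              value_space = "normalized", paired = counts$paired)
}

#' Upper-quartile normalization
#'
#' Divides each sample by its 75th percentile over features with nonzero
#' count, then rescales by the grand mean of those quartiles so the output
#' stays on the input's abundance scale.
#'
#' @param counts an [expr_matrix()] (raw counts or RSEM-like estimates).
#' @return An `expr_matrix` in `normalized` space.
#' @export
upper_quartile_normalize <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  y <- counts$values
  if (any(colSums(y) == 0)) {
    abort("sample with all-zero counts.", class = "mirnet_validation_error")
  }
  uq <- apply(y, 2, function(v) quantile(v[v > 0], 0.75, type = 7))
  vals <- sweep(y, 2, uq, "/") * mean(uq)
  expr_matrix(vals, counts$features, counts$samples,
              value_space = "normalized", paired = counts$paired)
}

#' Join miR and mRNA matrices into one network-ready matrix
#'
#' Row-stacks the two matrices restricted to the samples present in both
#' (matched by `pair_id` + `condition`); samples missing from either side
#' are dropped with a warning.
#'
#' @param mir_norm,mrna_norm [expr_matrix()] objects with disjoint feature
#'   ids, normalized or log2 space.
#' @return The joined `expr_matrix`.
#' @export
join_matrices <- function(mir_norm, mrna_norm) {
  stopifnot(inherits(mir_norm, "expr_matrix"), inherits(mrna_norm, "expr_matrix"))
  dup <- intersect(mir_norm$features$feature_id, mrna_norm$features$feature_id)
  if (length(dup) > 0) {
    abort("duplicate feature ids across inputs.", class = "mirnet_validation_error")
  }
  key <- function(x) paste(x$samples$pair_id, x$samples$condition, sep = "::")
  ka <- key(mir_norm)
  kb <- key(mrna_norm)
  common <- intersect(ka, kb)
  if (length(common) == 0) abort("no common samples.", class = "mirnet_validation_error")
  dropped <- length(union(ka, kb)) - length(common)
  if (dropped > 0) {
    warn(sprintf("%d sample(s) absent from one input dropped in join.", dropped))
  }
  ia <- match(common, ka)
  ib <- match(common, kb)
  va <- mir_norm$values[, ia, drop = FALSE]
  vb <- mrna_norm$values[, ib, drop = FALSE]
  colnames(vb) <- colnames(va)
  samples <- mir_norm$samples[ia, ]
  vals <- rbind(va, vb)
  feats <- bind_rows(mir_norm$features, mrna_norm$features)
  space <- if (mir_norm$value_space == mrna_norm$value_space) {
    mir_norm$value_space
  } else "normalized"
  expr_matrix(vals, feats, samples, value_space = space, paired = FALSE)
}

#' Log2-stabilize a normalized matrix
#'
#' `log2(x + 1)` on a `normalized` matrix. The network inference ranks each
#' feature, so any monotone stabilization gives identical MI; the transform
#' exists for inspection, plotting and PDS input.
#'
#' @param x an [expr_matrix()] in `normalized` space.
#' @return An `expr_matrix` in `log2` space.
#' @export
log2_stabilize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$value_space != "normalized") {
    abort("log2_stabilize expects normalized space.", class = "mirnet_usage_error")
  }
  expr_matrix(log2(x$values + 1), x$features, x$samples,
              value_space = "log2", paired = x$paired)
}

#' Full preprocessing of one condition
#'
#' miR side: count filter, TMM, CPM. mRNA side: TPM-like conversion is
#' assumed done (input is abundance), upper-quartile normalization, mean
#' filter. Both are log2(x+1)-stabilized and joined.
#'
#' @param mir_counts miR [expr_matrix()], raw counts.
#' @param mrna_abund mRNA [expr_matrix()], abundance (TPM-like) in
#'   `normalized` space, or raw counts (then only upper-quartile scaling is
#'   applied).
#' @param config list of thresholds, see [default_config()].
#' @return List: `joint` (network-ready log2 `expr_matrix`), `mir`, `mrna`
#'   (the per-side normalized matrices), `report` (tibble of feature counts
#'   in/out per stage).
#' @export
preprocess_condition <- function(mir_counts, mrna_abund,
                                 config = default_config()) {
  cfg <- modifyList(default_config(), config)
  mir_f <- filter_mir_counts(mir_counts, cfg$mir_min_count, cfg$mir_min_sample_frac)
  mir_n <- tmm_cpm(mir_f)
  if (mrna_abund$value_space == "raw_counts") {
    mrna_abund$value_space <- "normalized"  # RSEM-like estimates enter as-is
  }
  mrna_u <- upper_quartile_normalize(mrna_abund)
  mrna_f <- filter_mrna_abundance(mrna_u, cfg$mrna_min_mean_tpm)
  joint <- join_matrices(log2_stabilize(mir_n), log2_stabilize(mrna_f))
  report <- tibble(
    stage = c("mir_count_filter", "mrna_abundance_filter", "join"),
    features_in = c(nrow(mir_counts$values), nrow(mrna_u$values),
                    nrow(mir_n$values) + nrow(mrna_f$values)),
    features_out = c(nrow(mir_f$values), nrow(mrna_f$values),
                     nrow(joint$values))
  )
  list(joint = joint, mir = mir_n, mrna = mrna_f, report = report)
}
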