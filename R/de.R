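#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved. Thin validated wrapper around `stats::p.adjust`.
#'
#' @param pvals numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("p-values must be in (0, 1].", class = "mirnet_usage_error")
  }
  p.adjust(pvals, method = "BH")
}

# median-of-ratios size factors (geometric-mean reference over features
# with no zero anywhere)
size_factors <- function(counts) {
  logc <- log(counts)
  ok <- rowSums(!is.finite(logc)) == 0
  if (!any(ok)) {
    abort("no feature free of zeros; cannot compute size factors.",
          class = "mirnet_validation_error")
  }
  ref <- rowMeans(logc[ok, , drop = FALSE])
  apply(logc[ok, , drop = FALSE], 2, function(lc) exp(median(lc - ref)))
}

#' Paired differential expression with a twofold / FDR rule
#'
#' Normalizes both conditions jointly by median-of-ratios size factors,
#' forms per-feature log2 fold changes from size-factor-normalized means
#' (pseudocount 0.5), tests each feature with a Wilcoxon signed-rank test
#' on per-pair log-ratios (paired design; `paired = FALSE` uses a rank-sum
#' test across samples), adjusts with Benjamini-Hochberg, and flags a
#' feature `up`/`down` iff its absolute log2FC is at least `fc_min` and
#' the adjusted p-value is below `fdr_max`.
#'
#' @param counts_tumour,counts_control [expr_matrix()] objects in
#'   `raw_counts` space with identical feature sets; for the paired design
#'   their `pair_id`s must match.
#' @param paired use the matched-pairs design (default `TRUE`).
#' @param fc_min minimum |log2FC| to flag (default 1, i.e. twofold).
#' @param fdr_max maximum BH-adjusted p to flag (default 0.01).
#' @return Tibble of class `mirnet_de`: `feature_id`, `kind`,
#'   `base_mean`, `log2fc` (tumour vs control), `p_value`, `p_adj`,
#'   `flag` (`"up"`, `"down"`, `"ns"`).
#' @export
differential_expression <- function(counts_tumour, counts_control,
                                    paired = TRUE, fc_min = 1, fdr_max = 0.01) {
  stopifnot(inherits(counts_tumour, "expr_matrix"),
            inherits(counts_control, "expr_matrix"))
  if (counts_tumour$value_space != "raw_counts" ||
      counts_control$value_space != "raw_counts") {
    abort("differential expression expects raw counts.",
          class = "mirnet_usage_error")
  }
  if (!identical(counts_tumour$features$feature_id,
                 counts_control$features$feature_id)) {
    abort("feature sets differ between conditions.", class = "mirnet_usage_error")
  }
  yt <- counts_tumour$values
  yc <- counts_control$values
  if (paired) {
    common <- intersect(counts_tumour$samples$pair_id,
                        counts_control$samples$pair_id)
    if (length(common) < 3) {
      abort("need >= 3 matched pairs.", class = "mirnet_usage_error")
    }
    if (length(common) < length(unique(counts_tumour$samples$pair_id)) ||
        length(common) < length(unique(counts_control$samples$pair_id))) {
      abort("unpaired samples present with paired = TRUE.",
            class = "mirnet_usage_error")
    }
    yt <- yt[, match(common, counts_tumour$samples$pair_id), drop = FALSE]
    yc <- yc[, match(common, counts_control$samples$pair_id), drop = FALSE]
  }
  joint <- cbind(yt, yc)
  sf <- size_factors(joint)
  nt <- ncol(yt)
  yt_n <- sweep(yt, 2, sf[seq_len(nt)], "/")
  yc_n <- sweep(yc, 2, sf[-seq_len(nt)], "/")
  log2fc <- unname(log2((rowMeans(yt_n) + 0.5) / (rowMeans(yc_n) + 0.5)))
  pvals <- vapply(seq_len(nrow(yt_n)), function(f) {
    if (paired) {
      d <- log2(yt_n[f, ] + 0.5) - log2(yc_n[f, ] + 0.5)
      if (all(d == 0)) return(1)
      wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
    } else {
      a <- yt_n[f, ]; b <- yc_n[f, ]
      if (all(a == a[1]) && all(b == a[1])) return(1)
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    }
  }, numeric(1))
  pvals[is.na(pvals)] <- 1
  padj <- bh_adjust(pvals)
  flag <- ifelse(abs(log2fc) >= fc_min & padj < fdr_max,
                 ifelse(log2fc > 0, "up", "down"), "ns")
  out <- tibble(
    feature_id = counts_tumour$features$feature_id,
    kind = counts_tumour$features$kind,
    base_mean = unname(rowMeans(cbind(yt_n, yc_n))),
    log2fc = log2fc,
    p_value = pvals, p_adj = padj, flag = flag
  )
  class(out) <- c("mirnet_de", class(out))
  out
}

#' @export
glance.mirnet_de <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_up = sum(x$flag == "up"),
         n_down = sum(x$flag == "down"),
         n_ns = sum(x$flag == "ns"))
}
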