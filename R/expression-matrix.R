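#' Expression matrix container
#'
#' A light container for a features-by-samples abundance matrix carrying the
#' per-feature and per-sample metadata that the network pipeline needs:
#' feature kind (`"miR"` or `"mRNA"`), sample condition (`"tumour"` or
#' `"control"`), patient pairing, and the value space the numbers live in.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Dimnames are taken from `features`/`samples` if absent.
#' @param features data frame with columns `feature_id` and `kind`
#'   (`"miR"`/`"mRNA"`), one row per matrix row.
#' @param samples data frame with columns `sample_id`, `condition`
#'   (`"tumour"`/`"control"`) and `pair_id`, one row per matrix column.
#' @param value_space one of `"raw_counts"`, `"normalized"`, `"log2"`.
#' @param paired if `TRUE`, every pair_id with a tumour sample must also have
#'   a control sample (and vice versa); violations are an error.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `features` (tibble), `samples` (tibble), `value_space`, `paired`.
#' @export
#' @examples
#' em <- expr_matrix(
#'   matrix(rpois(6, 10), 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2"))),
#'   features = data.frame(feature_id = c("a", "b", "c"), kind = "mRNA"),
#'   samples = data.frame(sample_id = c("s1", "s2"), condition = "tumour",
#'                        pair_id = c("p1", "p2"))
#' )
#' em
expr_matrix <- function(values, features, samples,
                        value_space = c("raw_counts", "normalized", "log2"),
                        paired = FALSE) {
  value_space <- match.arg(value_space)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "mirnet_format_error")
  }
  features <- as_tibble(features)
  samples <- as_tibble(samples)
  stopifnot(all(c("feature_id", "kind") %in% names(features)),
            all(c("sample_id", "condition", "pair_id") %in% names(samples)))
  if (nrow(features) != nrow(values) || nrow(samples) != ncol(values)) {
    abort("metadata dimensions do not match `values`.",
          class = "mirnet_format_error")
  }
  if (anyDuplicated(features$feature_id)) {
    abort("duplicate feature_ids.", class = "mirnet_format_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample_ids.", class = "mirnet_format_error")
  }
  if (!all(features$kind %in% c("miR", "mRNA"))) {
    abort("feature kind must be 'miR' or 'mRNA'.", class = "mirnet_format_error")
  }
  if (!all(samples$condition %in% c("tumour", "control"))) {
    abort("sample condition must be 'tumour' or 'control'.",
          class = "mirnet_format_error")
  }
  if (value_space %in% c("raw_counts", "normalized") &&
      any(values < 0, na.rm = TRUE)) {
    abort(sprintf("negative values not allowed in %s space.", value_space),
          class = "mirnet_validation_error")
  }
  if (paired) {
    tum <- unique(samples$pair_id[samples$condition == "tumour"])
    ctl <- unique(samples$pair_id[samples$condition == "control"])
    if (!setequal(tum, ctl)) {
      abort("matrix declared paired but tumour/control pair_ids differ.",
            class = "mirnet_validation_error")
    }
  }
  rownames(values) <- features$feature_id
  colnames(values) <- samples$sample_id
  structure(
    list(values = values, features = features, samples = samples,
         value_space = value_space, paired = paired),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d features x %d samples [%s%s]\n",
    nrow(x$values), ncol(x$values), x$value_space,
    if (x$paired) ", paired" else ""
  ))
  kinds <- table(x$features$kind)
  conds <- table(x$samples$condition)
  cat("  features:", paste(sprintf("%s %s", kinds, names(kinds)), collapse = ", "), "\n")
  cat("  samples: ", paste(sprintf("%s %s", conds, names(conds)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature and/or sample ids
#'
#' @param x an [expr_matrix()].
#' @param features,samples character vectors of ids to keep (default: all).
#'   Order follows the original matrix, not the selector.
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  fi <- if (is.null(features)) rep(TRUE, nrow(x$values)) else
    x$features$feature_id %in% features
  si <- if (is.null(samples)) rep(TRUE, ncol(x$values)) else
    x$samples$sample_id %in% samples
  expr_matrix(x$values[fi, si, drop = FALSE],
              x$features[fi, , drop = FALSE],
              x$samples[si, , drop = FALSE],
              value_space = x$value_space, paired = FALSE)
}

#' Tidy an expression matrix into long form
#'
#' @param x an [expr_matrix()].
#' @param ... unused.
#' @return A tibble with one row per (feature, sample) cell: `feature_id`,
#'   `kind`, `sample_id`, `condition`, `pair_id`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  long <- tibble(
    feature_id = rep(x$features$feature_id, times = ncol(x$values)),
    kind = rep(x$features$kind, times = ncol(x$values)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$values)),
    condition = rep(x$samples$condition, each = nrow(x$values)),
    pair_id = rep(x$samples$pair_id, each = nrow(x$values)),
    value = as.vector(x$values)
  )
  long
}

#' @export
glance.expr_matrix <- function(x, ...) {
  tibble(
    n_features = nrow(x$values),
    n_mir = sum(x$features$kind == "miR"),
    n_mrna = sum(x$features$kind == "mRNA"),
    n_samples = ncol(x$values),
    n_tumour = sum(x$samples$condition == "tumour"),
    n_control = sum(x$samples$condition == "control"),
    value_space = x$value_space,
    paired = x$paired
  )
}

#' Generics for broom-style tidiers
#'
#' `tidy()` returns a long/tabular view of an object; `glance()` a one-row
#' summary. Methods exist for the package's result classes.
#' @param x object to tidy.
#' @param ... passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
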