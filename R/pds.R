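#' Pathway selection filters for deregulation scoring
#'
#' Keeps a pathway iff it contains at least one required gene (typically
#' the mRNA nodes of a first-neighbour network), at least `min_genes` of
#' its members are measured, and fewer measured members than there are
#' samples (so the pathway cloud is not rank-deficient by construction).
#'
#' @param collection gene-set tibble as from [read_gmt()].
#' @param required_genes character vector; a pathway must intersect it.
#' @param measured_genes character vector of genes present in the
#'   expression matrix.
#' @param n_samples number of samples.
#' @param min_genes minimum measured members (default 4).
#' @return The filtered collection with an added `n_measured` column.
#' @export
select_pathways <- function(collection, required_genes, measured_genes,
                            n_samples, min_genes = 4) {
  if (nrow(collection) == 0) return(collection)
  n_meas <- vapply(collection$members,
                   function(m) length(intersect(m, measured_genes)), integer(1))
  has_req <- vapply(collection$members,
                    function(m) length(intersect(m, required_genes)) > 0, logical(1))
  keep <- has_req & n_meas >= min_genes & n_meas < n_samples
  out <- collection[keep, ]
  out$n_measured <- n_meas[keep]
  out
}

# squared-distance projection of points onto a polyline.
# curve: m x d ordered points. Returns per-point nearest arc-length
# position and squared distance.
project_to_curve <- function(points, curve) {
  m <- nrow(curve)
  seg <- curve[-1, , drop = FALSE] - curve[-m, , drop = FALSE]
  seg_len2 <- rowSums(seg^2)
  seg_len <- sqrt(seg_len2)
  s0 <- c(0, cumsum(seg_len))[seq_len(m - 1)]
  n <- nrow(points)
  lambda <- numeric(n)
  dist2 <- numeric(n)
  for (i in seq_len(n)) {
    x <- points[i, ]
    dx <- sweep(curve[-m, , drop = FALSE], 2, x, "-")
    tt <- -rowSums(dx * seg) / pmax(seg_len2, .Machine$double.eps)
    tt <- pmin(pmax(tt, 0), 1)
    proj <- curve[-m, , drop = FALSE] + seg * tt
    d2 <- rowSums(sweep(proj, 2, x, "-")^2)
    k <- which.min(d2)
    lambda[i] <- s0[k] + tt[k] * seg_len[k]
    dist2[i] <- d2[k]
  }
  list(lambda = lambda, dist2 = dist2, total_length = sum(seg_len))
}

#' Fit a principal curve by projection / local-averaging iterations
#'
#' Hastie-Stuetzle-style fit: the curve is initialized along the first
#' principal component (or a supplied ordering), then alternates between
#' projecting every point onto the current polyline and re-estimating each
#' coordinate as a lowess smooth against the projection arc-length, until
#' the mean squared projection distance stops decreasing by more than a
#' relative `tol` (the objective plateaus and then oscillates at the
#' smoother's resolution) or `max_iter` iterations.
#'
#' @param points numeric matrix, observations x dimensions (`n >= 8`,
#'   `d >= 2`).
#' @param start_order optional integer ordering or numeric score used to
#'   initialize the curve (default: first principal component score).
#' @param span lowess span for the local averaging (default 0.3).
#' @param max_iter,tol stopping rule (defaults 100 / 1e-4 relative).
#' @param orient_toward optional row indices; the curve is flipped so the
#'   centroid of these rows projects nearer arc-length 0.
#' @return List of class `principal_curve`: `curve` (ordered points),
#'   `lambda` (per-observation arc-length), `dist2`, `total_length`,
#'   `n_iter`, `converged`, `mse_path`.
#' @export
fit_principal_curve <- function(points, start_order = NULL, span = 0.3,
                                max_iter = 100, tol = 1e-4,
                                orient_toward = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  stopifnot(n >= 8, d >= 2)
  if (all(apply(points, 2, sd) < .Machine$double.eps * 10)) {
    abort("degenerate zero-variance point cloud.", class = "mirnet_validation_error")
  }
  score <- if (is.null(start_order)) {
    pc <- prcomp(points, center = TRUE, scale. = FALSE)
    pc$x[, 1]
  } else as.numeric(start_order)

  smooth_curve <- function(lambda) {
    ord <- order(lambda)
    lam_s <- lambda[ord]
    fitted <- vapply(seq_len(d), function(j) {
      # iter = 0: plain local-linear smoothing, linear in the response, so
      # the fit is equivariant under orthogonal rotation of the cloud
      lw <- lowess(lam_s, points[ord, j], f = span, iter = 0)
      # lowess returns values at sorted unique-ish x; interpolate back
      stats::approx(lw$x, lw$y, xout = lam_s, rule = 2, ties = "ordered")$y
    }, numeric(n))
    # collapse duplicated arc positions to single curve points
    keep <- !duplicated(lam_s)
    fitted[keep, , drop = FALSE]
  }

  lambda <- score
  mse_path <- numeric()
  converged <- FALSE
  proj <- NULL
  for (it in seq_len(max_iter)) {
    curve <- smooth_curve(lambda)
    if (nrow(curve) < 2) {
      abort("curve collapsed to a point.", class = "mirnet_validation_error")
    }
    proj <- project_to_curve(points, curve)
    mse <- mean(proj$dist2)
    mse_path <- c(mse_path, mse)
    if (it > 1 && (mse_path[it - 1] - mse) < tol * mse_path[it - 1]) {
      converged <- TRUE
      break
    }
    lambda <- proj$lambda
  }
  lambda <- proj$lambda
  total <- proj$total_length
  if (!is.null(orient_toward)) {
    anchor <- mean(lambda[orient_toward])
    if (anchor > total / 2) {
      curve <- curve[rev(seq_len(nrow(curve))), , drop = FALSE]
      lambda <- total - lambda
    }
  }
  structure(list(curve = curve, lambda = lambda, dist2 = proj$dist2,
                 total_length = total, n_iter = length(mse_path),
                 converged = converged, mse_path = mse_path),
            class = "principal_curve")
}

#' Pathway deregulation scores for one pathway
#'
#' Standardizes the pathway genes (zero mean, unit variance over all
#' samples), reduces by PCA to the smallest dimension capturing at least
#' `variance_target` of the variance (min 2, max min(genes, samples - 1)),
#' fits a principal curve anchored at the control centroid, and scores
#' every sample by its arc-length from the curve start to its projection,
#' normalized by the maximum arc-length so scores live in \[0, 1\].
#'
#' @param expr an [expr_matrix()] (log2 space recommended).
#' @param pathway_genes gene ids of the pathway.
#' @param control_sample_ids sample ids anchoring the curve start.
#' @param variance_target PCA variance fraction (default 0.9).
#' @param span lowess span for the curve fit (default 0.3).
#' @return Tibble: `sample_id`, `condition`, `pds`; attributes
#'   `n_genes_used`, `n_dims`, `variance_captured`.
#' @export
pds_scores <- function(expr, pathway_genes, control_sample_ids,
                       variance_target = 0.9, span = 0.3) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- intersect(pathway_genes, expr$features$feature_id)
  if (length(genes) < 2) {
    abort("fewer than 2 measured pathway genes.", class = "mirnet_validation_error")
  }
  x <- t(expr$values[genes, , drop = FALSE])  # samples x genes
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < 2) {
    abort("fewer than 2 variable pathway genes.", class = "mirnet_validation_error")
  }
  x <- scale(x)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  dmax <- min(ncol(x), nrow(x) - 1)
  if (dmax < 2) abort("fewer than 2 retained dimensions.",
                      class = "mirnet_validation_error")
  ndim <- min(max(2, which(varfrac >= variance_target)[1]), dmax)
  red <- pc$x[, seq_len(ndim), drop = FALSE]
  ctrl_idx <- which(rownames(red) %in% control_sample_ids)
  fit <- fit_principal_curve(red, span = span, orient_toward = ctrl_idx)
  maxlam <- max(fit$lambda)
  if (maxlam <= 0) abort("curve has zero usable length.",
                         class = "mirnet_validation_error")
  out <- tibble(sample_id = rownames(red),
                condition = expr$samples$condition[
                  match(rownames(red), expr$samples$sample_id)],
                pds = fit$lambda / maxlam)
  attr(out, "n_genes_used") <- ncol(x)
  attr(out, "n_dims") <- ndim
  attr(out, "variance_captured") <- varfrac[ndim]
  out
}

#' Assemble the pathway-by-sample PDS matrix
#'
#' Applies [select_pathways()] then [pds_scores()] per pathway; pathways
#' whose scoring fails (degenerate clouds) are skipped with a warning.
#'
#' @param expr an [expr_matrix()].
#' @param collection gene-set tibble.
#' @param required_genes see [select_pathways()].
#' @param control_ids control sample ids.
#' @param variance_target,span see [pds_scores()].
#' @return Object of class `mirnet_pds`: list with `scores` (pathway x
#'   sample matrix in \[0, 1\]), `samples` (tibble `sample_id`,
#'   `condition`), `pathways` (metadata tibble: `set_id`, `n_measured`,
#'   `n_dims`, `variance_captured`).
#' @export
pds_matrix <- function(expr, collection, required_genes, control_ids,
                       variance_target = 0.9, span = 0.3) {
  stopifnot(inherits(expr, "expr_matrix"))
  sel <- select_pathways(collection, required_genes,
                         expr$features$feature_id, ncol(expr$values))
  rows <- list()
  meta <- list()
  for (i in seq_len(nrow(sel))) {
    id <- sel$set_id[i]
    res <- tryCatch(
      pds_scores(expr, sel$members[[i]], control_ids,
                 variance_target = variance_target, span = span),
      error = function(e) {
        warn(sprintf("pathway '%s' skipped: %s", id, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) next
    rows[[id]] <- setNames(res$pds, res$sample_id)
    meta[[id]] <- tibble(set_id = id, n_measured = attr(res, "n_genes_used"),
                         n_dims = attr(res, "n_dims"),
                         variance_captured = attr(res, "variance_captured"))
  }
  sample_ids <- expr$samples$sample_id
  scores <- if (length(rows) > 0) {
    do.call(rbind, lapply(rows, function(r) r[sample_ids]))
  } else {
    matrix(numeric(), 0, length(sample_ids))
  }
  colnames(scores) <- sample_ids
  structure(list(scores = scores,
                 samples = expr$samples[, c("sample_id", "condition")],
                 pathways = bind_rows(meta)),
            class = "mirnet_pds")
}

#' @export
print.mirnet_pds <- function(x, ...) {
  cat(sprintf("<mirnet_pds> %d pathways x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' @export
tidy.mirnet_pds <- function(x, ...) {
  if (nrow(x$scores) == 0) {
    return(tibble(set_id = character(), sample_id = character(),
                  condition = character(), pds = numeric()))
  }
  tibble(
    set_id = rep(rownames(x$scores), times = ncol(x$scores)),
    sample_id = rep(colnames(x$scores), each = nrow(x$scores)),
    condition = rep(x$samples$condition[
      match(colnames(x$scores), x$samples$sample_id)], each = nrow(x$scores)),
    pds = as.vector(x$scores)
  )
}

#' @export
glance.mirnet_pds <- function(x, ...) {
  tibble(n_pathways = nrow(x$scores), n_samples = ncol(x$scores),
         mean_pds = if (nrow(x$scores) > 0) mean(x$scores) else NA_real_)
}

#' Condition separation per pathway
#'
#' Wilcoxon rank-sum test of tumour vs control PDS per pathway.
#'
#' @param pds a `mirnet_pds`.
#' @return Tibble: `set_id`, `median_tumour`, `median_control`, `p_value`,
#'   `fdr`.
#' @export
pds_separation <- function(pds) {
  stopifnot(inherits(pds, "mirnet_pds"))
  if (nrow(pds$scores) == 0) {
    return(tibble(set_id = character(), median_tumour = numeric(),
                  median_control = numeric(), p_value = numeric(),
                  fdr = numeric()))
  }
  cond <- pds$samples$condition[match(colnames(pds$scores),
                                      pds$samples$sample_id)]
  rows <- purrr::map(rownames(pds$scores), function(id) {
    v <- pds$scores[id, ]
    tum <- v[cond == "tumour"]
    ctl <- v[cond == "control"]
    p <- wilcox.test(tum, ctl, exact = FALSE, correct = TRUE)$p.value
    tibble(set_id = id, median_tumour = median(tum),
           median_control = median(ctl), p_value = p)
  })
  out <- bind_rows(rows)
  out$fdr <- bh_adjust(pmin(pmax(out$p_value, .Machine$double.xmin), 1))
  out
}
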