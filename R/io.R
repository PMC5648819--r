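#' Read an expression matrix from TSV
#'
#' The matrix file is tab-separated with the feature id in the first column
#' and one column per sample. Sample condition and pairing come from a
#' sidecar sample table; feature kind comes from an annotation table or,
#' under an explicit opt-in, from an id-prefix rule (`"hsa-miR-"`/`"miR"`
#' prefixes mark miRs).
#'
#' @param path matrix TSV path.
#' @param samples sample table: data frame (or TSV path) with columns
#'   `sample_id`, `condition`, `pair_id`.
#' @param annotation optional feature annotation (data frame or TSV path,
#'   see [read_annotation_tsv()]) supplying feature kind.
#' @param kind_policy `"annotation"` (default) or `"prefix"`; `"prefix"`
#'   classifies ids starting with `"hsa-miR"`, `"hsa-mir"` or `"miR"` as miR
#'   and everything else as mRNA.
#' @param value_space,paired forwarded to [expr_matrix()].
#' @return An [expr_matrix()].
#' @export
read_expression_tsv <- function(path, samples, annotation = NULL,
                                kind_policy = c("annotation", "prefix"),
                                value_space = "raw_counts", paired = FALSE) {
  kind_policy <- match.arg(kind_policy)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort("matrix file needs >= 2 columns.",
                           class = "mirnet_format_error")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    abort("duplicate feature rows in matrix file.", class = "mirnet_format_error")
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- ids
  if (is.character(samples)) {
    samples <- readr::read_tsv(samples, show_col_types = FALSE, progress = FALSE)
  }
  samples <- as_tibble(samples)
  missing <- setdiff(colnames(values), samples$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("samples absent from sample table: %s",
                  paste(missing, collapse = ", ")),
          class = "mirnet_validation_error")
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  kind <- switch(kind_policy,
    annotation = {
      if (is.null(annotation)) {
        abort("kind_policy = 'annotation' requires an annotation table.",
              class = "mirnet_usage_error")
      }
      if (is.character(annotation)) annotation <- read_annotation_tsv(annotation)
      idx <- match(ids, annotation$feature_id)
      if (anyNA(idx)) {
        abort("features missing from annotation; cannot assign kind.",
              class = "mirnet_validation_error")
      }
      annotation$kind[idx]
    },
    prefix = ifelse(grepl("^(hsa-)?mir", ids, ignore.case = TRUE), "miR", "mRNA")
  )
  expr_matrix(values, tibble(feature_id = ids, kind = kind), samples,
              value_space = value_space, paired = paired)
}

#' Write an expression matrix (and its sample sidecar) to TSV
#'
#' @param x an [expr_matrix()].
#' @param path matrix TSV path; the sample table goes to
#'   `<path>.samples.tsv` unless `samples_path` is given.
#' @param samples_path optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, samples_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- tibble(feature_id = x$features$feature_id)
  tab <- dplyr::bind_cols(tab, as_tibble(x$values, .name_repair = "minimal"))
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(x$samples, samples_path %||% paste0(path, ".samples.tsv"),
                   progress = FALSE)
  invisible(path)
}

#' Read a feature annotation table
#'
#' Expected columns: `feature_id`, `kind`, `chromosome`, `start`, `end`,
#' `strand`, optional `family` and `cluster`. Coordinates are 1-based
#' inclusive.
#'
#' @param path TSV path.
#' @return A tibble; invariants (start <= end, start >= 1, family only on
#'   miRs) are checked.
#' @export
read_annotation_tsv <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann <- as_tibble(ann)
  req <- c("feature_id", "kind", "chromosome", "start", "end", "strand")
  if (!all(req %in% names(ann))) {
    abort(sprintf("annotation must have columns: %s", paste(req, collapse = ", ")),
          class = "mirnet_format_error")
  }
  if (!"family" %in% names(ann)) ann$family <- NA_character_
  if (!"cluster" %in% names(ann)) ann$cluster <- NA_character_
  if (anyDuplicated(ann$feature_id)) {
    abort("duplicate feature_ids in annotation.", class = "mirnet_format_error")
  }
  if (any(ann$start > ann$end) || any(ann$start < 1)) {
    abort("annotation coordinates must satisfy 1 <= start <= end.",
          class = "mirnet_validation_error")
  }
  bad_fam <- !is.na(ann$family) & ann$family != "" & ann$kind != "miR"
  if (any(bad_fam)) {
    abort("family labels are only allowed on miR features.",
          class = "mirnet_validation_error")
  }
  ann
}

#' Write an annotation table; optionally a BED-like export
#'
#' The native TSV keeps 1-based inclusive coordinates. `format = "bed"`
#' converts to 0-based half-open (start - 1, end) as BED requires.
#'
#' @param ann annotation tibble.
#' @param path output path.
#' @param format `"tsv"` (native) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  ann <- validate_annotation(ann)
  if (format == "tsv") {
    readr::write_tsv(ann, path, progress = FALSE)
  } else {
    bed <- tibble(chrom = ann$chromosome, chromStart = ann$start - 1L,
                  chromEnd = ann$end, name = ann$feature_id, score = 0L,
                  strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "."))
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `set_id TAB description TAB member...`. Duplicate
#' members within a line are dropped with a warning.
#'
#' @param path GMT path.
#' @param category optional category label stored on every set.
#' @return A `gene_set_collection`: tibble with columns `set_id`, `name`,
#'   `category`, `members` (list column), `size`.
#' @export
read_gmt <- function(path, category = NA_character_) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(sprintf("GMT line(s) with < 3 fields: %s",
                  paste(which(bad), collapse = ", ")),
          class = "mirnet_format_error")
  }
  sets <- purrr::map(parts, function(p) {
    members <- p[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("duplicate members in set '%s' deduplicated.", p[[1]]))
      members <- unique(members)
    }
    tibble(set_id = p[[1]], name = p[[2]], members = list(members))
  })
  out <- bind_rows(sets)
  if (anyDuplicated(out$set_id)) {
    abort("duplicate set_ids in GMT.", class = "mirnet_format_error")
  }
  out$category <- category
  out$size <- lengths(out$members)
  out[, c("set_id", "name", "category", "members", "size")]
}

#' Write a gene-set collection to GMT
#'
#' @param sets collection as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$set_id, sets$name, sets$members),
    function(id, nm, mem) paste(c(id, nm, mem), collapse = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a miR-target interaction table
#'
#' TSV with columns `mir_id`, `gene_id`, `source` (`"validated"` or
#' `"predicted"`). Duplicate triples are an error.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_interactions_tsv <- function(path) {
  db <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_interactions(db)
}

validate_interactions <- function(db) {
  db <- as_tibble(db)
  req <- c("mir_id", "gene_id", "source")
  if (!all(req %in% names(db))) {
    abort("interaction table needs columns mir_id, gene_id, source.",
          class = "mirnet_format_error")
  }
  if (!all(db$source %in% c("validated", "predicted"))) {
    abort("interaction source must be 'validated' or 'predicted'.",
          class = "mirnet_validation_error")
  }
  if (anyDuplicated(db[, req])) {
    abort("duplicate (mir, gene, source) records.", class = "mirnet_format_error")
  }
  db
}

#' @rdname read_interactions_tsv
#' @param db interaction tibble.
#' @export
write_interactions_tsv <- function(db, path) {
  readr::write_tsv(validate_interactions(db), path, progress = FALSE)
  invisible(path)
}

#' Write a network to SIF, GraphML or edge-TSV
#'
#' SIF uses the edge class (`miR-miR`, `miR-mRNA`, `mRNA-mRNA`) as the
#' relation token. Edge-TSV columns are `node_a`, `node_b`, `mi`, `class`,
#' `p_value` (plus `p_adj` and `dpi_removed` when present). GraphML stores
#' node kind and all edge attributes. Edge-TSV and GraphML round-trip MI
#' values to full double precision.
#'
#' @param network an [mi_network()].
#' @param path output path.
#' @param format `"edge_tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "mi_network"))
  format <- match.arg(format)
  e <- network$edges
  switch(format,
    edge_tsv = {
      out <- e
      for (col in c("mi", "p_value")) {
        if (col %in% names(out)) out[[col]] <- sprintf("%.17g", out[[col]])
      }
      readr::write_tsv(out, path, progress = FALSE)
      readr::write_tsv(network$nodes, paste0(path, ".nodes.tsv"), progress = FALSE)
    },
    sif = {
      lines <- if (nrow(e) > 0) {
        sprintf("%s\t%s\t%s", e$node_a, e$class, e$node_b)
      } else character()
      iso <- setdiff(network$nodes$node, c(e$node_a, e$node_b))
      readr::write_lines(c(lines, iso), path)
    },
    graphml = write_graphml(network, path)
  )
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path input path.
#' @param format `"edge_tsv"` or `"graphml"` (SIF drops MI values and is
#'   export-only).
#' @return An [mi_network()].
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    e <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           node_a = "c", node_b = "c", mi = "d",
                           class = "c", p_value = "d", .default = "?"))
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"),
                             show_col_types = FALSE, progress = FALSE)
    mi_network(nodes = nodes, edges = e)
  } else {
    read_graphml(path)
  }
}

write_graphml <- function(network, path) {
  n <- network$nodes
  e <- network$edges
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  header <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="kind" for="node" attr.name="kind" attr.type="string"/>',
    '<key id="mi" for="edge" attr.name="mi" attr.type="double"/>',
    '<key id="class" for="edge" attr.name="class" attr.type="string"/>',
    '<key id="p_value" for="edge" attr.name="p_value" attr.type="double"/>',
    '<key id="dpi_removed" for="edge" attr.name="dpi_removed" attr.type="boolean"/>',
    '<graph edgedefault="undirected">'
  )
  nodes <- sprintf('<node id="%s"><data key="kind">%s</data></node>',
                   esc(n$node), esc(n$kind))
  pv <- if ("p_value" %in% names(e)) e$p_value else rep(NA_real_, nrow(e))
  dr <- if ("dpi_removed" %in% names(e)) e$dpi_removed else rep(FALSE, nrow(e))
  edges <- if (nrow(e) > 0) {
    sprintf(paste0(
      '<edge source="%s" target="%s"><data key="mi">%.17g</data>',
      '<data key="class">%s</data><data key="p_value">%.17g</data>',
      '<data key="dpi_removed">%s</data></edge>'),
      esc(e$node_a), esc(e$node_b), e$mi, esc(e$class), pv,
      ifelse(dr, "true", "false"))
  } else character()
  writeLines(c(header, nodes, edges, "</graph>", "</graphml>"), path)
  invisible(path)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nd <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- tibble(
    node = xml2::xml_attr(nd, "id"),
    kind = xml2::xml_text(xml2::xml_find_first(nd, ".//g:data[@key='kind']", ns))
  )
  ed <- xml2::xml_find_all(doc, ".//g:edge", ns)
  grab <- function(key) {
    xml2::xml_text(xml2::xml_find_first(
      ed, sprintf(".//g:data[@key='%s']", key), ns))
  }
  edges <- tibble(
    node_a = xml2::xml_attr(ed, "source"),
    node_b = xml2::xml_attr(ed, "target"),
    mi = as.numeric(grab("mi")),
    class = grab("class"),
    p_value = as.numeric(grab("p_value")),
    dpi_removed = grab("dpi_removed") == "true"
  )
  mi_network(nodes = nodes, edges = edges)
}

#' Read / write a run configuration
#'
#' Configurations are YAML key/value trees; [default_config()] lists every
#' threshold the pipeline uses with its default.
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_config <- function(path) {
  modifyList(default_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Pipeline defaults
#'
#' All thresholds used anywhere in the pipeline, as one named list. The
#' network percentiles and DPI tolerance reflect the values used for the
#' 86-patient breast-carcinoma analysis this pipeline replicates; they are
#' appropriate for matrices with thousands of features (millions of pairs).
#' [synthetic_run_config()] scales the percentiles for small planted
#' benchmarks.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    mir_min_count = 5, mir_min_sample_frac = 0.25,
    mrna_min_mean_tpm = 10,
    tmm_trim_m = 0.30, tmm_trim_a = 0.05,
    q_mm = 0.99987, q_mi = 0.99741,
    dpi_tolerance = 0.10,
    n_perm = 1000, tail_fit = TRUE,
    mi_loo_weight = 0.6, mi_bandwidth_const = NULL,
    de_fc_min = 1, de_fdr_max = 0.01, de_paired = TRUE,
    enrich_fdr_max = 0.01, enrich_max_set_size = 1000,
    pds_variance_target = 0.9, pds_span = 0.3,
    top_k_degree = 10
  )
}
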