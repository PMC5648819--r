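#' Plot MI histograms per edge class
#'
#' Overlaid MI distributions of the network's edges, faceted by edge class
#' — the classic view for comparing tumour and control networks.
#'
#' @param ... named [mi_network()] objects (e.g. `tumour = net_t,
#'   control = net_c`).
#' @param bins histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_mi_histogram <- function(..., bins = 30) {
  nets <- list(...)
  if (is.null(names(nets)) || any(names(nets) == "")) {
    names(nets) <- paste0("network_", seq_along(nets))
  }
  df <- bind_rows(purrr::imap(nets, function(n, nm) {
    mutate(live_edges(n), network = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mi, fill = .data$network)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::labs(x = "mutual information (nats)", y = "edges") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression
#'
#' @param object a [differential_expression()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mirnet_de
#' @export
autoplot.mirnet_de <- function(object, ...) {
  df <- mutate(object,
               neglogp = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neglogp,
                                   colour = .data$flag)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "log2 fold change (tumour vs control)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' @param object a [hypergeometric_enrichment()] result.
#' @param top show the `top` sets by FDR (default 20).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mirnet_enrichment
#' @export
autoplot.mirnet_enrichment <- function(object, top = 20, ...) {
  df <- head(object, top)
  df$set_id <- factor(df$set_id, levels = rev(df$set_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$fdr, 1e-300)),
                                   y = .data$set_id,
                                   size = .data$k,
                                   colour = .data$passes_filters)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 FDR", y = NULL, size = "overlap k",
                  colour = "passes filters") +
    ggplot2::theme_minimal()
}

#' Tile map of pathway deregulation scores
#'
#' Pathways by samples, samples grouped by condition.
#'
#' @param object a [pds_matrix()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mirnet_pds
#' @export
autoplot.mirnet_pds <- function(object, ...) {
  df <- tidy(object)
  ord <- object$samples$sample_id[order(object$samples$condition)]
  df$sample_id <- factor(df$sample_id, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$set_id,
                                   fill = .data$pds)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$condition),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PDS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Degree distribution by node kind
#'
#' @param network an [mi_network()].
#' @param family_map optional family map, see [degree_table()].
#' @return A ggplot object.
#' @export
plot_degree <- function(network, family_map = NULL) {
  dt <- degree_table(network, family_map)
  nodes <- if (is.data.frame(dt)) dt else dt$nodes
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$degree, fill = .data$kind)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "degree", y = "nodes") +
    ggplot2::theme_minimal()
}

#' @method autoplot mi_network
#' @export
autoplot.mi_network <- function(object, ...) plot_mi_histogram(network = object)

# re-export the ggplot2 generic so autoplot methods are reachable
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
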