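#' Pairwise Spearman correlation and p-value matrices
#'
#' Rank-based correlation with average ranks for ties; two-sided p-values
#' from the t approximation, `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom. Constant columns have undefined correlations
#' and are recorded as `NA`.
#'
#' @param columns Numeric matrix or data frame; variables in columns
#'   (rarefied ASV abundances plus abiotic process parameters), at least 5
#'   paired observations.
#' @return List with symmetric matrices `rho` and `p` (unadjusted).
#' @export
spearman_matrix <- function(columns) {
  x <- as.matrix(columns)
  if (!is.numeric(x)) stop("all columns must be numeric")
  n <- nrow(x)
  if (n < 5) stop("need at least 5 paired observations")
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  const <- apply(x, 2, function(v) stats::var(v) == 0)
  rho[const, ] <- NA; rho[, const] <- NA
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(rho) <- 1; diag(p) <- 0
  list(rho = rho, p = p)
}

#' Build the co-occurrence network
#'
#' Edges connect variable pairs whose Spearman rho is strictly beyond the
#' cutoff in magnitude and whose FDR-adjusted p-value is strictly below the
#' significance cutoff. The Benjamini-Hochberg family is all unique
#' off-diagonal pairs in one correction. Nodes carry a type (`asv` or
#' `abiotic`) and, when taxonomy is given, a genus.
#'
#' @param rho,p Matched symmetric matrices from [spearman_matrix()]; `p`
#'   unadjusted (adjustment happens here over the unique pairs) unless
#'   `adjust = FALSE`.
#' @param rho_cutoff Correlation-magnitude threshold (default 0.7, strict).
#' @param p_cutoff Adjusted-p threshold (default 0.05, strict).
#' @param adjust Apply BH adjustment across the unique pairs (default TRUE).
#' @param asv_ids Which variables are ASVs (default: names starting "ASV");
#'   the rest are typed abiotic.
#' @param taxonomy Optional taxonomy data frame for genus annotation.
#' @return A `cooccurrence_network`: list with `nodes` (id, type, genus,
#'   degree), `edges` (from, to, rho, p_adj, sign) and `thresholds`.
#' @export
build_network <- function(rho, p, rho_cutoff = 0.7, p_cutoff = 0.05,
                          adjust = TRUE, asv_ids = NULL, taxonomy = NULL) {
  stopifnot(identical(dim(rho), dim(p)))
  vars <- colnames(rho)
  ut <- upper.tri(rho)
  pairs <- which(ut, arr.ind = TRUE)
  p_vec <- p[ut]
  p_adj <- if (adjust) fdr_adjust(p_vec) else p_vec
  r_vec <- rho[ut]
  keep <- !is.na(r_vec) & abs(r_vec) > rho_cutoff & p_adj < p_cutoff
  edges <- data.frame(from = vars[pairs[keep, 1]],
                      to = vars[pairs[keep, 2]],
                      rho = r_vec[keep], p_adj = p_adj[keep],
                      sign = ifelse(r_vec[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  if (is.null(asv_ids)) asv_ids <- grep("^ASV", vars, value = TRUE)
  deg <- stats::setNames(rep(0L, length(vars)), vars)
  tab <- table(c(edges$from, edges$to))
  deg[names(tab)] <- as.integer(tab)
  nodes <- data.frame(id = vars,
                      type = ifelse(vars %in% asv_ids, "asv", "abiotic"),
                      genus = NA_character_, degree = unname(deg),
                      stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    nodes$genus <- taxonomy$genus[match(nodes$id, taxonomy$asv_id)]
  }
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(rho = rho_cutoff, p = p_cutoff)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|rho| > ", x$thresholds$rho, ", adjusted p < ",
      x$thresholds$p, ")\n", sep = "")
  invisible(x)
}

#' Hub nodes by degree
#'
#' @param network A `cooccurrence_network`.
#' @param k Number of hubs to return (default 5).
#' @return The `k` highest-degree rows of the node table.
#' @export
network_hubs <- function(network, k = 5) {
  ord <- order(-network$nodes$degree, network$nodes$id)
  utils::head(network$nodes[ord, ], k)
}

.xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

#' Export a network for Gephi
#'
#' `export_gexf()` writes GEXF 1.2 (undirected, node attributes `type` and
#' `genus`, edge attributes `rho` and `sign`); `export_graphml()` writes
#' GraphML through igraph. Both load directly in Gephi.
#'
#' @param network A `cooccurrence_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_gexf <- function(network, path) {
  n <- network$nodes; e <- network$edges
  con <- try(file(path, "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph mode="static" defaultedgetype="undirected">')
  w('    <attributes class="node">')
  w('      <attribute id="0" title="type" type="string"/>')
  w('      <attribute id="1" title="genus" type="string"/>')
  w('    </attributes>')
  w('    <attributes class="edge">')
  w('      <attribute id="0" title="rho" type="double"/>')
  w('      <attribute id="1" title="sign" type="string"/>')
  w('    </attributes>')
  w('    <nodes>')
  for (i in seq_len(nrow(n))) {
    w('      <node id="%s" label="%s">', .xml_escape(n$id[i]), .xml_escape(n$id[i]))
    w('        <attvalues>')
    w('          <attvalue for="0" value="%s"/>', n$type[i])
    if (!is.na(n$genus[i])) w('          <attvalue for="1" value="%s"/>',
                              .xml_escape(n$genus[i]))
    w('        </attvalues>')
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  for (i in seq_len(nrow(e))) {
    w('      <edge id="%d" source="%s" target="%s" weight="%s">',
      i - 1L, .xml_escape(e$from[i]), .xml_escape(e$to[i]),
      format(abs(e$rho[i]), digits = 10))
    w('        <attvalues>')
    w('          <attvalue for="0" value="%s"/>', format(e$rho[i], digits = 10))
    w('          <attvalue for="1" value="%s"/>', e$sign[i])
    w('        </attvalues>')
    w('      </edge>')
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}

#' @rdname export_gexf
#' @export
export_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_gexf
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Write the edge list as TSV
#'
#' @inheritParams export_gexf
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
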