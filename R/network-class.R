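#' Signed co-expression network container
#'
#' An undirected graph over genes where each edge carries a Spearman
#' correlation `rho`, its p-value and a sign ("+" for positive, "-" for
#' negative correlation). Within each edge the two gene ids are stored in
#' lexicographic order, and edges are sorted lexicographically so that all
#' exports are byte-stable. Isolated nodes are kept in the node set.
#'
#' @param nodes character vector of gene ids.
#' @param edges data frame with columns `gene_a`, `gene_b`, `rho`,
#'   `pvalue`; a `sign` column is derived from `rho` if absent.
#' @param threshold_rho the `|rho|` cutoff the edges satisfy.
#' @param n_samples number of libraries the correlations were computed on.
#' @param alpha the p-value cutoff the edges satisfy.
#' @return An object of class `coexpression_network`.
#' @export
coexpression_network <- function(nodes, edges, threshold_rho, n_samples,
                                 alpha = 0.05) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        rho = numeric(0), pvalue = numeric(0),
                        sign = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    a <- as.character(edges$gene_a)
    b <- as.character(edges$gene_b)
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    edges <- data.frame(gene_a = a, gene_b = b, rho = edges$rho,
                        pvalue = edges$pvalue,
                        sign = ifelse(edges$rho >= 0, "+", "-"),
                        stringsAsFactors = FALSE)
    if (any(edges$gene_a == edges$gene_b)) {
      stop("self-edge on gene ", edges$gene_a[edges$gene_a == edges$gene_b][1])
    }
    key <- paste(edges$gene_a, edges$gene_b)
    if (anyDuplicated(key)) stop("duplicate edge: ", key[duplicated(key)][1])
    if (any(abs(edges$rho) < threshold_rho)) {
      stop("edge below the |rho| threshold")
    }
    miss <- setdiff(unique(c(edges$gene_a, edges$gene_b)), nodes)
    if (length(miss) > 0) {
      stop("edge endpoint not in node set: ", miss[1])
    }
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges,
                 threshold_rho = threshold_rho,
                 n_samples = n_samples, alpha = alpha),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d nodes, %d edges (|rho| >= %g, p < %g, n = %d)\n",
    length(x$nodes), nrow(x$edges), x$threshold_rho, x$alpha, x$n_samples))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  positive edges: %d, negative edges: %d\n",
                sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  }
  invisible(x)
}

#' Convert a co-expression network to an igraph graph
#' @param net a `coexpression_network`.
#' @return An undirected `igraph` graph with `rho`, `pvalue` and `sign`
#'   edge attributes.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(match(net$edges$gene_a, net$nodes),
               match(net$edges$gene_b, net$nodes)),
      rho = net$edges$rho, pvalue = net$edges$pvalue, sign = net$edges$sign)
  }
  g
}

#' Node degrees of a co-expression network
#' @param net a `coexpression_network`.
#' @return Named integer vector over all nodes (isolated nodes have 0).
#' @export
node_degrees <- function(net) {
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0) {
    t1 <- table(factor(net$edges$gene_a, levels = net$nodes))
    t2 <- table(factor(net$edges$gene_b, levels = net$nodes))
    deg <- stats::setNames(as.integer(t1 + t2), net$nodes)
  }
  deg
}

#' Export a network as an edge-list TSV, SIF or GraphML file
#'
#' `edge_tsv` writes columns (gene_a, gene_b, rho, pvalue, sign); `sif`
#' writes "gene_a pos|neg gene_b" lines (isolated nodes as single-column
#' lines); `graphml` stores rho and pvalue as edge attributes. All formats
#' are written with edges sorted lexicographically.
#'
#' @param net a `coexpression_network`.
#' @param path output file path.
#' @param format one of "edge_tsv", "sif", "graphml".
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  e <- net$edges
  if (format == "edge_tsv") {
    out <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
                      rho = formatC(e$rho, digits = 15, format = "g"),
                      pvalue = formatC(e$pvalue, digits = 15, format = "g"),
                      sign = e$sign, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- character(0)
    if (nrow(e) > 0) {
      lines <- sprintf("%s\t%s\t%s", e$gene_a,
                       ifelse(e$sign == "+", "pos", "neg"), e$gene_b)
    }
    iso <- setdiff(net$nodes, unique(c(e$gene_a, e$gene_b)))
    writeLines(c(lines, iso), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from an edge-list TSV
#' @param path an edge TSV written by [write_network()].
#' @param threshold_rho the `|rho|` cutoff the file satisfies.
#' @param n_samples library count used for the p-values.
#' @param alpha significance cutoff the file satisfies.
#' @param nodes optional node set; defaults to the edge endpoints.
#' @return A `coexpression_network`.
#' @export
read_network_tsv <- function(path, threshold_rho, n_samples, alpha = 0.05,
                             nodes = NULL) {
  tab <- read_tsv_strict(path, "edge list")
  need <- c("gene_a", "gene_b", "rho", "pvalue")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("edge list missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(nodes)) nodes <- unique(c(tab$gene_a, tab$gene_b))
  coexpression_network(nodes, tab, threshold_rho, n_samples, alpha)
}
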