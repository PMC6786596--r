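#' Spearman rank correlation of two series
#'
#' Pearson correlation of the average (fractional) ranks. Constant series
#' have undefined rank correlation and return `NA` with a warning; the
#' network builder treats such genes as edge-free.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return Correlation in `[-1, 1]`, or `NA` for a constant series.
#' @examples
#' spearman_rho(1:3, c(2, 4, 6))   # 1
#' spearman_rho(1:3, c(3, 2, 1))   # -1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("series have different lengths")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant series: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Two-sided significance of a correlation via the t-distribution
#'
#' Maps a correlation observed on `n` samples to
#' `t = |r| / sqrt((1 - r^2) / (n - 2))` and returns the two-sided tail
#' probability of Student's t with `n - 2` degrees of freedom. `r = 0`
#' gives 1; `|r| = 1` gives 0. Vectorized over `rho` and `n`.
#'
#' @param rho correlation value(s) in `[-1, 1]`.
#' @param n sample count(s), at least 3.
#' @return p-value(s) in `[0, 1]`.
#' @export
correlation_pvalue <- function(rho, n) {
  if (any(n < 3)) stop("n must be at least 3")
  if (any(abs(rho) > 1, na.rm = TRUE)) stop("rho must lie in [-1, 1]")
  k <- pmax(length(rho), length(n))
  rho <- rep_len(rho, k); n <- rep_len(n, k)
  p <- rep(NA_real_, k)
  lim <- !is.na(rho) & abs(rho) == 1
  ok <- !is.na(rho) & !lim
  tstat <- abs(rho[ok]) / sqrt((1 - rho[ok]^2) / (n[ok] - 2))
  p[ok] <- 2 * stats::pt(tstat, n[ok] - 2, lower.tail = FALSE)
  p[lim] <- 0
  p
}

#' Build a signed Spearman co-expression network
#'
#' Computes all pairwise Spearman correlations over the matrix libraries
#' for the selected genes and keeps the pairs with `|rho| >=
#' rho_threshold` and t-distribution p-value `< alpha`. Edge sign is the
#' sign of rho. Genes with constant expression are kept as isolated nodes
#' (with a warning), as are genes whose correlations all fall below the
#' thresholds.
#'
#' @param mat an [expression_matrix()].
#' @param gene_set gene ids to correlate; `NULL` means all matrix genes.
#' @param rho_threshold minimum `|rho|` (default 0.8).
#' @param alpha p-value cutoff (default 0.05).
#' @return A [coexpression_network()].
#' @export
build_network <- function(mat, gene_set = NULL, rho_threshold = 0.8,
                          alpha = 0.05) {
  if (is.null(gene_set)) gene_set <- rownames(mat$values)
  gene_set <- as.character(gene_set)
  miss <- setdiff(gene_set, rownames(mat$values))
  if (length(miss) > 0) stop("gene not in matrix: ", miss[1])
  n_lib <- ncol(mat$values)
  if (n_lib < 3) stop("need at least 3 libraries for correlation")
  if (length(gene_set) < 2) {
    return(coexpression_network(gene_set, NULL, rho_threshold, n_lib, alpha))
  }
  vals <- mat$values[gene_set, , drop = FALSE]
  constant <- apply(vals, 1, function(v) length(unique(v)) == 1)
  if (any(constant)) {
    warning(sum(constant), " constant-expression gene(s) excluded from ",
            "correlation (kept as isolated nodes)")
  }
  active <- gene_set[!constant]
  edges <- NULL
  if (length(active) >= 2) {
    ranks <- t(apply(vals[active, , drop = FALSE], 1, rank))
    rho <- stats::cor(t(ranks))
    pv <- correlation_pvalue(rho[upper.tri(rho)], n_lib)
    ut <- which(upper.tri(rho), arr.ind = TRUE)
    keep <- abs(rho[upper.tri(rho)]) >= rho_threshold & pv < alpha
    if (any(keep)) {
      edges <- data.frame(
        gene_a = active[ut[keep, 1]],
        gene_b = active[ut[keep, 2]],
        rho = rho[upper.tri(rho)][keep],
        pvalue = pv[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  coexpression_network(gene_set, edges, rho_threshold, n_lib, alpha)
}

#' Degree, hub and per-group connectivity summary
#'
#' Node degrees, the top-`k_hubs` nodes by degree (ties broken by
#' lexicographic gene id), and, when seed groups are given, each group's
#' mean number of connections per gene (rounded to 2 decimals; `NA` for
#' an empty group).
#'
#' @param net a [coexpression_network()].
#' @param seed_groups optional named list of gene id sets (must be
#'   network nodes).
#' @param k_hubs how many hubs to report (default 10).
#' @return List: `degree` (data frame `gene_id`, `degree`), `hubs`
#'   (character vector), `group_means` (data frame `group`, `n_genes`,
#'   `mean_degree`, or `NULL`).
#' @export
degree_stats <- function(net, seed_groups = NULL, k_hubs = 10) {
  deg <- node_degrees(net)
  ord <- order(-deg, names(deg))
  hubs <- names(deg)[ord][seq_len(min(k_hubs, length(deg)))]
  group_means <- NULL
  if (!is.null(seed_groups)) {
    group_means <- do.call(rbind, lapply(names(seed_groups), function(g) {
      members <- as.character(seed_groups[[g]])
      out <- setdiff(members, net$nodes)
      if (length(out) > 0) {
        stop("seed group '", g, "' contains non-network gene: ", out[1])
      }
      data.frame(group = g, n_genes = length(members),
                 mean_degree = if (length(members) == 0) NA_real_ else
                   round(sum(deg[members]) / length(members), 2),
                 stringsAsFactors = FALSE)
    }))
  }
  list(degree = data.frame(gene_id = names(deg), degree = unname(deg),
                           stringsAsFactors = FALSE),
       hubs = hubs, group_means = group_means)
}

#' Ego subnetwork around seed genes (radius 1)
#'
#' Keeps the seeds, their direct neighbors, and only the edges incident
#' to a seed; edges between two non-seed neighbors are dropped. Isolated
#' seeds are retained as single nodes.
#'
#' @param net a [coexpression_network()].
#' @param seeds gene ids (must be network nodes).
#' @return A [coexpression_network()].
#' @export
neighbor_subnetwork <- function(net, seeds) {
  seeds <- as.character(seeds)
  miss <- setdiff(seeds, net$nodes)
  if (length(miss) > 0) stop("seed not in network: ", miss[1])
  e <- net$edges
  keep <- e$gene_a %in% seeds | e$gene_b %in% seeds
  e <- e[keep, , drop = FALSE]
  nodes <- union(seeds, unique(c(e$gene_a, e$gene_b)))
  coexpression_network(nodes, e, net$threshold_rho, net$n_samples, net$alpha)
}

#' 2-D similarity map of libraries (classical MDS)
#'
#' Pairwise library distance is the root-mean-square difference of log2
#' values over the most variable genes, embedded in two dimensions by
#' classical metric multidimensional scaling. The sign of each axis is
#' fixed by forcing the first library's coordinate to be non-negative, so
#' the output is fully deterministic.
#'
#' @param mat an [expression_matrix()] with at least 3 libraries.
#' @param n_top_genes how many most-variable genes to use (default 500;
#'   clamped to the gene count with a warning).
#' @return Data frame: `library_id`, `condition`, `dim1`, `dim2`.
#' @export
library_similarity_map <- function(mat, n_top_genes = 500) {
  if (ncol(mat$values) < 3) stop("need at least 3 libraries for an MDS map")
  if (n_top_genes > nrow(mat$values)) {
    warning("n_top_genes exceeds gene count; using all ",
            nrow(mat$values), " genes")
    n_top_genes <- nrow(mat$values)
  }
  v <- apply(mat$values, 1, stats::var)
  top <- rownames(mat$values)[order(-v, rownames(mat$values))][seq_len(n_top_genes)]
  x <- mat$values[top, , drop = FALSE]
  d <- as.matrix(stats::dist(t(x))) / sqrt(nrow(x))
  coords <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (ncol(coords) < 2) {
    coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
  }
  for (ax in 1:2) {
    if (coords[1, ax] < 0) coords[, ax] <- -coords[, ax]
  }
  data.frame(library_id = colnames(mat$values),
             condition = mat$design$condition,
             dim1 = coords[, 1], dim2 = coords[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}
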