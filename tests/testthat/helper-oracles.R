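# Independent oracles and tiny fixture builders used across the suite.

# Pearson correlation written out from the definition (no stats::cor),
# applied to average ranks: an independent Spearman implementation.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Two-sided t tail probability by numeric integration of the t density.
oracle_t_pvalue <- function(rho, n) {
  if (abs(rho) == 1) return(0)
  tstat <- abs(rho) / sqrt((1 - rho^2) / (n - 2))
  df <- n - 2
  tail <- stats::integrate(function(x) stats::dt(x, df), tstat, Inf,
                           rel.tol = 1e-13, abs.tol = 1e-14)$value
  2 * tail
}

# All permutations of 1..n (n <= 7).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# Exact permutation p-value for |Spearman rho| by full enumeration.
oracle_perm_pvalue <- function(x, y) {
  n <- length(x)
  obs <- abs(oracle_spearman(x, y))
  perms <- all_perms(n)
  stat <- apply(perms, 1, function(p) abs(oracle_spearman(x, y[p])))
  mean(stat >= obs - 1e-12)
}

# Brute-force all-pairs network scan: per-pair scalar Spearman (via the
# independent oracle) and the t-formula written inline.
oracle_network_edges <- function(values, gene_set, rho_threshold, alpha) {
  n <- ncol(values)
  out <- NULL
  for (i in seq_along(gene_set)) {
    for (j in seq_along(gene_set)) {
      if (i >= j) next
      a <- gene_set[i]; b <- gene_set[j]
      if (length(unique(values[a, ])) == 1 ||
          length(unique(values[b, ])) == 1) next
      r <- oracle_spearman(values[a, ], values[b, ])
      p <- if (abs(r) >= 1) 0 else
        2 * stats::pt(abs(r) / sqrt((1 - r^2) / (n - 2)), n - 2,
                      lower.tail = FALSE)
      if (abs(r) >= rho_threshold && p < alpha) {
        lo <- min(a, b); hi <- max(a, b)
        out <- rbind(out, data.frame(gene_a = lo, gene_b = hi,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0)))
  }
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# A small two-condition design (stress vs control, n replicates each).
toy_design <- function(n_rep = 3) {
  experiment_design(
    library_id = c(sprintf("ctl_r%d", seq_len(n_rep)),
                   sprintf("str_r%d", seq_len(n_rep))),
    condition = rep(c("control", "stress"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    control_condition = rep(c(NA, "control"), each = n_rep)
  )
}

toy_contrast <- function() contrast("stress_vs_control", "stress", "control")

# Expression matrix from a plain numeric matrix and a design.
toy_matrix <- function(values, design, present = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  colnames(values) <- design$library_id
  expression_matrix(values, design, present)
}
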