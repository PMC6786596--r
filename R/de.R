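#' Present-call filter
#'
#' Keeps genes detected (flagged present) in every replicate of at least
#' one condition — the standard reliability filter before differential
#' expression testing on microarray detection calls.
#'
#' @param mat an [expression_matrix()].
#' @return Character vector of retained gene ids, in matrix order.
#' @export
present_filter <- function(mat) {
  conds <- unique(mat$design$condition)
  keep <- rep(FALSE, nrow(mat$values))
  for (cond in conds) {
    libs <- condition_libraries(mat$design, cond)
    keep <- keep | rowSums(!mat$present[, libs, drop = FALSE]) == 0
  }
  rownames(mat$values)[keep]
}

#' Per-gene two-sample Student's t-test for a contrast
#'
#' Classic pooled-variance two-sided t-test of stress vs control log2
#' values, vectorized over genes. When both groups have zero variance the
#' statistic is undefined; by convention p = 1 for equal means and p = 0
#' otherwise.
#'
#' @param mat an [expression_matrix()].
#' @param contr one-row contrast data frame from [contrast()] or a row of
#'   [default_contrasts()].
#' @param alpha significance level for the flag (default 0.05).
#' @param var_equal pooled variance (classic Student, default) or
#'   `FALSE` for Welch.
#' @return Data frame: `gene_id`, `pvalue`, `significant`.
#' @export
ttest_contrast <- function(mat, contr, alpha = 0.05, var_equal = TRUE) {
  s_libs <- condition_libraries(mat$design, contr$stress_condition)
  c_libs <- condition_libraries(mat$design, contr$control_condition)
  n1 <- length(s_libs); n2 <- length(c_libs)
  if (n1 < 2 || n2 < 2) {
    stop("t-test needs at least 2 replicates per condition (",
         contr$stress_condition, ": ", n1, ", ",
         contr$control_condition, ": ", n2, ")")
  }
  x <- mat$values[, s_libs, drop = FALSE]
  y <- mat$values[, c_libs, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  data.frame(gene_id = rownames(mat$values), pvalue = p,
             significant = p < alpha, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Regulation coefficient: mean stress value over mean control value
#'
#' The per-gene ratio of replicate means between the stress and control
#' conditions of a contrast. The default `log_ratio` scale divides the
#' stored log2 means directly; `linear_ratio` instead returns
#' `2^(mean_stress - mean_control)`, the fold change on the linear
#' intensity scale.
#'
#' @param mat an [expression_matrix()].
#' @param contr one-row contrast data frame.
#' @param scale `"log_ratio"` (default) or `"linear_ratio"`.
#' @return Named numeric vector of coefficients over genes.
#' @export
regulation_coefficient <- function(mat, contr,
                                   scale = c("log_ratio", "linear_ratio")) {
  scale <- match.arg(scale)
  s_libs <- condition_libraries(mat$design, contr$stress_condition)
  c_libs <- condition_libraries(mat$design, contr$control_condition)
  m_s <- rowMeans(mat$values[, s_libs, drop = FALSE])
  m_c <- rowMeans(mat$values[, c_libs, drop = FALSE])
  if (scale == "log_ratio") {
    if (any(m_c <= 0)) {
      bad <- rownames(mat$values)[m_c <= 0][1]
      stop("non-positive control mean for gene ", bad,
           "; log-scale ratio undefined (use scale = 'linear_ratio')")
    }
    coef <- m_s / m_c
  } else {
    coef <- 2^(m_s - m_c)
  }
  stats::setNames(coef, rownames(mat$values))
}

#' Categorical regulation calls from p-value and coefficient
#'
#' Sign calls require significance: a gene is called positive when
#' `pvalue < alpha` and coefficient > 1, negative when `pvalue < alpha`
#' and coefficient < 1, otherwise none. The variation filters flag genes
#' whose coefficient leaves the unchanged band, boundaries inclusive on
#' the regulated side: 20% variation means coefficient <= 0.83 or >= 1.2;
#' two-fold means coefficient <= 0.5 or >= 2. Two-fold calls are a subset
#' of 20% calls, which are a subset of sign calls.
#'
#' @param pvalue numeric vector of per-gene p-values.
#' @param coefficient numeric vector of regulation coefficients.
#' @param alpha significance level (default 0.05).
#' @param pct20_bounds unchanged band for the 20% filter
#'   (default `c(0.83, 1.2)`; the printed lower bound 0.83, not 1/1.2).
#' @param twofold_bounds unchanged band for the two-fold filter
#'   (default `c(0.5, 2)`).
#' @return Data frame: `call_sign` (positive/negative/none), `call_20pct`,
#'   `call_twofold`.
#' @export
classify_regulation <- function(pvalue, coefficient, alpha = 0.05,
                                pct20_bounds = c(0.83, 1.2),
                                twofold_bounds = c(0.5, 2)) {
  stopifnot(length(pvalue) == length(coefficient))
  sig <- pvalue < alpha
  call_sign <- ifelse(!sig | coefficient == 1, "none",
                      ifelse(coefficient > 1, "positive", "negative"))
  call_20pct <- sig & (coefficient <= pct20_bounds[1] |
                       coefficient >= pct20_bounds[2])
  call_twofold <- sig & (coefficient <= twofold_bounds[1] |
                         coefficient >= twofold_bounds[2])
  data.frame(call_sign = call_sign, call_20pct = call_20pct,
             call_twofold = call_twofold, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Full regulation profile for one contrast
#'
#' Runs the t-test, the regulation coefficient and the categorical calls
#' for every gene of the matrix (optionally restricted to a gene set) and
#' returns them as one table.
#'
#' @param mat an [expression_matrix()].
#' @param contr one-row contrast data frame.
#' @param alpha significance level (default 0.05).
#' @param scale coefficient scale, see [regulation_coefficient()].
#' @param genes optional gene id subset.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   default `"none"` (raw p-values, the classic microarray practice).
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return Data frame: `gene_id`, `contrast`, `pvalue`, `coefficient`,
#'   `call_sign`, `call_20pct`, `call_twofold`.
#' @export
regulation_profile <- function(mat, contr, alpha = 0.05,
                               scale = c("log_ratio", "linear_ratio"),
                               genes = NULL, adjust = "none",
                               var_equal = TRUE) {
  scale <- match.arg(scale)
  tt <- ttest_contrast(mat, contr, alpha, var_equal)
  coef <- regulation_coefficient(mat, contr, scale)
  p <- stats::p.adjust(tt$pvalue, method = adjust)
  calls <- classify_regulation(p, coef, alpha)
  out <- data.frame(gene_id = tt$gene_id, contrast = contr$name,
                    pvalue = p, coefficient = unname(coef), calls,
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    miss <- setdiff(genes, out$gene_id)
    if (length(miss) > 0) stop("gene not in matrix: ", miss[1])
    out <- out[out$gene_id %in% genes, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Per-contrast regulated-gene counts with exclusivity
#'
#' For each contrast, counts genes called up and down under the chosen
#' variation filter, and how many of those are exclusive — called (in
#' either direction) at that contrast and at none of the others.
#'
#' @param profiles named list of [regulation_profile()] tables, one per
#'   contrast, over a common gene set.
#' @param filter which call column defines "regulated": `"twofold"`
#'   (default), `"pct20"` or `"sign"`.
#' @return Data frame: `contrast`, `n_up`, `n_down`, `n_up_exclusive`,
#'   `n_down_exclusive`.
#' @export
timepoint_exclusivity <- function(profiles,
                                  filter = c("twofold", "pct20", "sign")) {
  filter <- match.arg(filter)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    stop("profiles must be a named list (one name per contrast)")
  }
  called <- lapply(profiles, function(p) {
    flag <- switch(filter,
                   twofold = p$call_twofold,
                   pct20 = p$call_20pct,
                   sign = p$call_sign != "none")
    stats::setNames(ifelse(flag, p$call_sign, "none"), p$gene_id)
  })
  all_genes <- sort(unique(unlist(lapply(profiles, `[[`, "gene_id"))))
  call_mat <- vapply(called, function(v) {
    out <- rep("none", length(all_genes))
    out[match(names(v), all_genes)] <- v
    out
  }, character(length(all_genes)))
  n_called <- rowSums(call_mat != "none")
  out <- lapply(names(profiles), function(nm) {
    v <- call_mat[, nm]
    excl <- v != "none" & n_called == 1
    data.frame(contrast = nm,
               n_up = sum(v == "positive"),
               n_down = sum(v == "negative"),
               n_up_exclusive = sum(v == "positive" & excl),
               n_down_exclusive = sum(v == "negative" & excl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
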