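#' Cross-stress concordance classification
#'
#' Classifies each gene by its aluminium and phosphate regulation
#' coefficients against a variation threshold: concordant_positive when
#' both coefficients reach the upper bound, concordant_negative when both
#' fall to the lower bound, discordant when the bounds are crossed in
#' opposite directions, and unregulated otherwise. Discordant genes are
#' flagged, not dropped. At the default 20% threshold the bounds are 1.2
#' and 0.83 (the conventional printed lower bound rather than 1/1.2).
#'
#' @param al_profile,p_profile data frames with `gene_id` and
#'   `coefficient` columns (e.g. from [regulation_profile()]), or named
#'   numeric vectors of coefficients.
#' @param threshold_pct variation threshold as a fraction (default 0.2).
#' @param bounds optional `c(lower, upper)` override of the coefficient
#'   bounds.
#' @return Data frame: `gene_id`, `al_coefficient`, `p_coefficient`,
#'   `status`. Genes present in only one profile are excluded with a
#'   message.
#' @examples
#' al <- c(a = 1.3, b = 0.7, c = 1.05)
#' p <- c(a = 1.25, b = 0.8, c = 1.5)
#' dual_stress_concordance(al, p)
#' @export
dual_stress_concordance <- function(al_profile, p_profile,
                                    threshold_pct = 0.2, bounds = NULL) {
  al <- as_coefficient_vector(al_profile)
  p <- as_coefficient_vector(p_profile)
  common <- intersect(names(al), names(p))
  dropped <- length(union(names(al), names(p))) - length(common)
  if (dropped > 0) {
    message(dropped, " gene(s) missing from one profile were excluded")
  }
  if (is.null(bounds)) {
    upper <- 1 + threshold_pct
    lower <- if (isTRUE(all.equal(threshold_pct, 0.2))) 0.83 else
      1 / (1 + threshold_pct)
  } else {
    lower <- bounds[1]; upper <- bounds[2]
  }
  a <- al[common]; b <- p[common]
  up_a <- a >= upper; dn_a <- a <= lower
  up_b <- b >= upper; dn_b <- b <= lower
  status <- rep("unregulated", length(common))
  status[up_a & up_b] <- "concordant_positive"
  status[dn_a & dn_b] <- "concordant_negative"
  status[(up_a & dn_b) | (dn_a & up_b)] <- "discordant"
  data.frame(gene_id = common, al_coefficient = unname(a),
             p_coefficient = unname(b), status = status,
             stringsAsFactors = FALSE)
}

as_coefficient_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "coefficient") %in% names(x))) {
      stop("profile must have gene_id and coefficient columns")
    }
    return(stats::setNames(x$coefficient, x$gene_id))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("profile must be a data frame or a named numeric vector")
}

#' Regulation-sign pattern groups across the two stresses
#'
#' Assigns each gene a group from its sign calls over the five contrasts
#' (Al 6 h, Al 54 h, Al 246 h, P mild, P severe):
#'
#' * `G1` — positive at 6 h and 246 h of aluminium and negative under
#'   both phosphate starvation contrasts (the 54 h call is free);
#' * the mirrored pattern (negative under aluminium at 6 h and 246 h,
#'   positive under both phosphate contrasts) is split by network
#'   topology when `group_split = "components"`: the mirrored-pattern
#'   genes are induced as a subgraph, and the largest connected component
#'   none of whose members neighbors a G1 gene in the full network is
#'   `G2` (the component most detached from G1); the remaining mirrored
#'   genes are `G3`. With `group_split = "none"` all mirrored genes are
#'   reported as one merged `G2G3` group;
#' * every other pattern is `other`.
#'
#' @param profiles named list of [regulation_profile()] tables for the
#'   five contrasts; names must include `al_6h`, `al_246h`, `p_mild`,
#'   `p_severe` (names are matched case-insensitively).
#' @param net a [coexpression_network()] over (at least) the mirrored
#'   genes; required for `group_split = "components"`.
#' @param group_split `"components"` (default) or `"none"`.
#' @return Data frame: `gene_id`, one sign column per contrast, `group`.
#' @export
sign_pattern_groups <- function(profiles, net = NULL,
                                group_split = c("components", "none")) {
  group_split <- match.arg(group_split)
  need <- c("al_6h", "al_246h", "p_mild", "p_severe")
  nm <- tolower(names(profiles))
  miss <- setdiff(need, nm)
  if (length(miss) > 0) {
    stop("missing contrast profile(s): ", paste(miss, collapse = ", "))
  }
  genes <- sort(Reduce(intersect, lapply(profiles, `[[`, "gene_id")))
  if (length(genes) == 0) stop("profiles share no genes")
  signs <- vapply(profiles, function(p) {
    p$call_sign[match(genes, p$gene_id)]
  }, character(length(genes)))
  colnames(signs) <- names(profiles)
  s <- function(contr) signs[, which(nm == contr)[1]]
  g1 <- s("al_6h") == "positive" & s("al_246h") == "positive" &
    s("p_mild") == "negative" & s("p_severe") == "negative"
  mirror <- s("al_6h") == "negative" & s("al_246h") == "negative" &
    s("p_mild") == "positive" & s("p_severe") == "positive"
  group <- rep("other", length(genes))
  group[g1] <- "G1"
  if (any(mirror)) {
    if (group_split == "none" || is.null(net)) {
      if (group_split == "components" && is.null(net)) {
        stop("group_split = 'components' needs a co-expression network")
      }
      group[mirror] <- "G2G3"
    } else {
      group[mirror] <- split_mirror_groups(net, genes[mirror], genes[g1])
    }
  }
  out <- data.frame(gene_id = genes, signs, group = group,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("gene_id", names(profiles), "group")
  out
}

# Split mirrored-pattern genes into G2 (largest connected component of the
# induced subgraph with no G1 neighbor in the full network) and G3 (rest).
split_mirror_groups <- function(net, mirror_genes, g1_genes) {
  present <- intersect(mirror_genes, net$nodes)
  e <- net$edges
  sub <- e[e$gene_a %in% present & e$gene_b %in% present, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    sub[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = present))
  comp <- igraph::components(g)
  membership <- stats::setNames(comp$membership, igraph::V(g)$name)
  touches_g1 <- e$gene_a %in% g1_genes | e$gene_b %in% g1_genes
  g1_neighbors <- unique(c(e$gene_a[touches_g1], e$gene_b[touches_g1]))
  out <- stats::setNames(rep("G3", length(mirror_genes)), mirror_genes)
  if (comp$no > 0) {
    eligible <- which(vapply(seq_len(comp$no), function(k) {
      members <- names(membership)[membership == k]
      !any(members %in% g1_neighbors)
    }, logical(1)))
    if (length(eligible) > 0) {
      sizes <- comp$csize[eligible]
      # largest eligible component; ties broken by smallest member id
      best <- eligible[order(-sizes, vapply(eligible, function(k) {
        min(names(membership)[membership == k])
      }, character(1)))][1]
      out[names(membership)[membership == best]] <- "G2"
    }
  }
  unname(out[mirror_genes])
}

#' Transcription-factor regulation-call table
#'
#' Restricts regulation profiles to genes with a TF family annotation and
#' a two-fold call in at least one contrast, and tabulates the sign call
#' (or `NA`) per contrast.
#'
#' @param profiles named list of [regulation_profile()] tables (one per
#'   contrast, typically the three aluminium time points).
#' @param tf_families data frame with `gene_id` and `family` columns.
#' @return Data frame: `gene_id`, `family`, one `call_<contrast>` column
#'   per profile; ordered by gene id.
#' @export
tf_call_table <- function(profiles, tf_families) {
  if (!all(c("gene_id", "family") %in% names(tf_families))) {
    stop("tf_families must have gene_id and family columns")
  }
  if (nrow(tf_families) == 0) {
    out <- data.frame(gene_id = character(0), family = character(0),
                      stringsAsFactors = FALSE)
    for (nm in names(profiles)) out[[paste0("call_", nm)]] <- character(0)
    return(out)
  }
  genes <- sort(intersect(tf_families$gene_id,
                          unique(unlist(lapply(profiles, `[[`, "gene_id")))))
  calls <- lapply(profiles, function(p) {
    i <- match(genes, p$gene_id)
    ifelse(!is.na(i) & p$call_twofold[i], p$call_sign[i], NA_character_)
  })
  any_call <- Reduce(`|`, lapply(calls, function(v) !is.na(v)))
  out <- data.frame(
    gene_id = genes,
    family = tf_families$family[match(genes, tf_families$gene_id)],
    stringsAsFactors = FALSE
  )
  for (nm in names(profiles)) out[[paste0("call_", nm)]] <- calls[[nm]]
  out <- out[any_call, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-contrast counts from a TF call table
#' @param tab a call table with `call_*` columns (e.g. [tf_call_table()]
#'   output or the `tf_calls` element of [reference_tables()]).
#' @return Data frame: `contrast`, `n_called`, `n_positive`, `n_negative`.
#' @export
tf_call_counts <- function(tab) {
  cols <- grep("^call_", names(tab), value = TRUE)
  do.call(rbind, lapply(cols, function(cl) {
    v <- tab[[cl]]
    data.frame(contrast = sub("^call_", "", cl),
               n_called = sum(!is.na(v)),
               n_positive = sum(v == "positive", na.rm = TRUE),
               n_negative = sum(v == "negative", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Per-group GO subclass percentage table
#'
#' For each gene group and functional subclass, the percentage of the
#' group's genes carrying that subclass (a gene with several subclasses
#' counts once in each), rounded to 2 decimals. Subclasses absent from a
#' group are `NA` (rendered "n.d." by [format_go_table()]).
#'
#' @param groups named list of gene id sets; empty groups are an error.
#' @param annotations data frame with `gene_id` and `subclass` columns
#'   (one row per gene-subclass pair).
#' @return Data frame with `subclass` and one percentage column per group.
#' @export
go_subclass_distribution <- function(groups, annotations) {
  if (!all(c("gene_id", "subclass") %in% names(annotations))) {
    stop("annotations must have gene_id and subclass columns")
  }
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) stop("empty group: ", empty[1])
  ann <- unique(annotations[, c("gene_id", "subclass")])
  subclasses <- sort(unique(ann$subclass))
  out <- data.frame(subclass = subclasses, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    members <- unique(as.character(groups[[g]]))
    counts <- vapply(subclasses, function(sc) {
      sum(members %in% ann$gene_id[ann$subclass == sc])
    }, numeric(1))
    pct <- round(100 * counts / length(members), 2)
    pct[counts == 0] <- NA_real_
    out[[g]] <- pct
  }
  out
}

#' Format a GO percentage table for printing ("n.d." for absent)
#' @param tab output of [go_subclass_distribution()].
#' @return Data frame of character columns with "%" suffixed values.
#' @export
format_go_table <- function(tab) {
  out <- tab
  for (cl in setdiff(names(tab), "subclass")) {
    out[[cl]] <- ifelse(is.na(tab[[cl]]), "n.d.",
                        sprintf("%.2f%%", tab[[cl]]))
  }
  out
}

#' Screen study genes against a curated reference list via best hits
#'
#' Returns the study genes whose best-hit subject is a member of the
#' reference list. Only rank-1 hits are considered, so the result is
#' invariant to input ordering and to lower-ranked duplicate hits.
#'
#' @param best_hits a best-hit map from [best_hit_map()] (or any ranked
#'   `homology_hits` table; rank-1 rows are used).
#' @param reference character vector of reference member ids, or a list
#'   with a `members` element.
#' @return Sorted character vector of matching query gene ids.
#' @export
homology_screen <- function(best_hits, reference) {
  if (is.list(reference) && !is.null(reference$members)) {
    reference <- reference$members
  }
  if (nrow(best_hits) == 0) return(character(0))
  if ("rank" %in% names(best_hits)) {
    best_hits <- best_hits[best_hits$rank == 1, , drop = FALSE]
  }
  sort(unique(best_hits$query[best_hits$subject %in% reference]))
}

#' Count positive edges between two gene sets
#'
#' Number of positive-sign network edges with one endpoint in each set.
#' Overlapping sets raise a warning and shared genes are excluded from
#' both sides, so only disjoint-endpoint edges are counted.
#'
#' @param net a [coexpression_network()].
#' @param set_a,set_b gene id sets (must be network nodes).
#' @return Integer count.
#' @export
cross_list_correlation_check <- function(net, set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  for (s in list(set_a, set_b)) {
    miss <- setdiff(s, net$nodes)
    if (length(miss) > 0) stop("gene not in network: ", miss[1])
  }
  shared <- intersect(set_a, set_b)
  if (length(shared) > 0) {
    warning(length(shared), " gene(s) in both sets excluded from the count")
    set_a <- setdiff(set_a, shared)
    set_b <- setdiff(set_b, shared)
  }
  e <- net$edges
  sum(e$sign == "+" &
        ((e$gene_a %in% set_a & e$gene_b %in% set_b) |
         (e$gene_a %in% set_b & e$gene_b %in% set_a)))
}
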