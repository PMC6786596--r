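test_that("concordance statuses partition the gene set", {
  al <- c(a = 1.3, b = 0.7, c = 1.05, d = 1.5, e = 0.5)
  p <- c(a = 1.25, b = 0.8, c = 1.5, d = 0.5, e = 0.4)
  out <- dual_stress_concordance(al, p)
  expect_equal(stats::setNames(out$status, out$gene_id),
               c(a = "concordant_positive", b = "concordant_negative",
                 c = "unregulated", d = "discordant",
                 e = "concordant_negative"))
  expect_true(all(out$status %in% c("concordant_positive",
                                    "concordant_negative", "discordant",
                                    "unregulated")))
})

test_that("genes missing from one profile are excluded with a message", {
  al <- c(a = 1.3, b = 0.7)
  p <- c(a = 1.25, z = 2)
  expect_message(out <- dual_stress_concordance(al, p), "excluded")
  expect_equal(out$gene_id, "a")
})

test_that("raising the threshold monotonically shrinks the concordant sets", {
  set.seed(23)
  al <- stats::setNames(exp(rnorm(200, 0, 0.5)), sprintf("g%03d", 1:200))
  p <- stats::setNames(exp(rnorm(200, 0, 0.5)), sprintf("g%03d", 1:200))
  prev <- NULL
  for (pct in c(0.1, 0.2, 0.5, 1.0)) {
    out <- dual_stress_concordance(al, p, threshold_pct = pct)
    conc <- out$gene_id[grepl("^concordant", out$status)]
    if (!is.null(prev)) expect_true(all(conc %in% prev))
    prev <- conc
  }
})

mk_sign_profile <- function(nm, genes, sign) {
  data.frame(gene_id = genes, contrast = nm, pvalue = 0.01,
             coefficient = ifelse(sign == "positive", 2,
                                  ifelse(sign == "negative", 0.5, 1)),
             call_sign = sign, call_20pct = sign != "none",
             call_twofold = sign != "none", stringsAsFactors = FALSE)
}

test_that("sign patterns map to G1, mirrored genes and other", {
  genes <- c("g1", "m1", "m2", "m3", "x1")
  profs <- list(
    al_6h = mk_sign_profile("al_6h", genes,
                            c("positive", "negative", "negative", "negative",
                              "positive")),
    al_54h = mk_sign_profile("al_54h", genes,
                             c("positive", "negative", "positive", "none",
                               "positive")),
    al_246h = mk_sign_profile("al_246h", genes,
                              c("positive", "negative", "negative",
                                "negative", "positive")),
    p_mild = mk_sign_profile("p_mild", genes,
                             c("negative", "positive", "positive",
                               "positive", "positive")),
    p_severe = mk_sign_profile("p_severe", genes,
                               c("negative", "positive", "positive",
                                 "positive", "positive"))
  )
  out <- sign_pattern_groups(profs, group_split = "none")
  expect_equal(out$group[out$gene_id == "g1"], "G1")
  expect_equal(out$group[out$gene_id == "x1"], "other")   # all-positive
  expect_true(all(out$group[out$gene_id %in% c("m1", "m2", "m3")] == "G2G3"))
  # the 54 h call is free: m2 (positive at 54 h) is still mirrored
  expect_error(sign_pattern_groups(profs[-1]), "al_6h")
})

test_that("topology split separates G2 (detached) from G3", {
  genes <- c("g1", "m1", "m2", "m3", "m4")
  profs <- list(
    al_6h = mk_sign_profile("al_6h", genes,
                            c("positive", rep("negative", 4))),
    al_54h = mk_sign_profile("al_54h", genes, rep("none", 5)),
    al_246h = mk_sign_profile("al_246h", genes,
                              c("positive", rep("negative", 4))),
    p_mild = mk_sign_profile("p_mild", genes,
                             c("negative", rep("positive", 4))),
    p_severe = mk_sign_profile("p_severe", genes,
                               c("negative", rep("positive", 4)))
  )
  # m1-m2 component touches g1; m3-m4 component is detached -> G2
  net <- coexpression_network(
    genes,
    data.frame(gene_a = c("m1", "m1", "m3"),
               gene_b = c("m2", "g1", "m4"),
               rho = c(0.9, -0.9, 0.9), pvalue = 1e-4),
    threshold_rho = 0.8, n_samples = 27)
  out <- sign_pattern_groups(profs, net = net, group_split = "components")
  grp <- stats::setNames(out$group, out$gene_id)
  expect_equal(unname(grp[c("m3", "m4")]), c("G2", "G2"))
  expect_equal(unname(grp[c("m1", "m2")]), c("G3", "G3"))
  expect_equal(unname(grp["g1"]), "G1")
})

test_that("TF call table restricts to annotated genes with two-fold calls", {
  genes <- c("tf1", "tf2", "tf3", "plain")
  p6 <- mk_sign_profile("al_6h", genes,
                        c("positive", "none", "negative", "positive"))
  p6$call_twofold <- c(TRUE, FALSE, FALSE, TRUE)
  p54 <- mk_sign_profile("al_54h", genes,
                         c("none", "none", "negative", "none"))
  p54$call_twofold <- c(FALSE, FALSE, TRUE, FALSE)
  fams <- data.frame(gene_id = c("tf1", "tf2", "tf3"),
                     family = c("MYB", "NAC", "WRKY"),
                     stringsAsFactors = FALSE)
  tab <- tf_call_table(list(al_6h = p6, al_54h = p54), fams)
  expect_equal(tab$gene_id, c("tf1", "tf3"))   # tf2 has no call; plain no family
  expect_equal(tab$call_al_6h, c("positive", NA))
  expect_equal(tab$call_al_54h, c(NA, "negative"))

  empty <- tf_call_table(list(al_6h = p6), fams[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("GO subclass percentages match hand-computed counts", {
  groups <- list(G1 = sprintf("a%d", 1:4), G2 = sprintf("b%d", 1:5))
  ann <- data.frame(
    gene_id = c("a1", "a1", "a2", "b1", "b2", "b3", "zz"),
    subclass = c("Membrane", "Binding", "Membrane", "Binding", "Binding",
                 "Organelle", "Membrane"),
    stringsAsFactors = FALSE
  )
  tab <- go_subclass_distribution(groups, ann)
  get <- function(sc, g) tab[[g]][tab$subclass == sc]
  expect_equal(get("Membrane", "G1"), 50)        # 2 of 4
  expect_equal(get("Binding", "G1"), 25)         # multi-label gene counts once
  expect_equal(get("Binding", "G2"), 40)         # 2 of 5
  expect_true(is.na(get("Organelle", "G1")))     # n.d.
  fmt <- format_go_table(tab)
  expect_equal(fmt$G1[fmt$subclass == "Organelle"], "n.d.")
  expect_equal(fmt$G1[fmt$subclass == "Membrane"], "50.00%")
  expect_error(go_subclass_distribution(list(G1 = character(0)), ann),
               "empty group: G1")
})

test_that("GO percentages match a brute-force count oracle on a toy partition", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:20)
  groups <- list(A = genes[1:8], B = genes[9:20])
  ann <- data.frame(
    gene_id = sample(genes, 30, replace = TRUE),
    subclass = sample(c("s1", "s2", "s3"), 30, replace = TRUE),
    stringsAsFactors = FALSE
  )
  tab <- go_subclass_distribution(groups, ann)
  for (g in names(groups)) {
    for (sc in tab$subclass) {
      n <- sum(vapply(groups[[g]], function(gene) {
        any(ann$gene_id == gene & ann$subclass == sc)
      }, logical(1)))
      want <- if (n == 0) NA_real_ else round(100 * n / length(groups[[g]]), 2)
      expect_equal(tab[[g]][tab$subclass == sc], want)
    }
  }
})

test_that("homology screen returns best-hit members only", {
  hits <- data.frame(
    query = c("x1", "x1", "x2", "x3"),
    subject = c("REF1", "OTHER", "OTHER2", "REF2"),
    pident = 90, evalue = c(1e-20, 1e-10, 1e-8, 1e-9),
    bitscore = 100, rank = c(1L, 2L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  ref <- c("REF1", "REF2", "OTHER")  # OTHER is only a rank-2 hit of x1
  expect_equal(homology_screen(hits, ref), c("x1", "x3"))
  # invariant to row order and to sub-rank-1 duplicates
  expect_equal(homology_screen(hits[sample(nrow(hits)), ], ref), c("x1", "x3"))
  expect_equal(homology_screen(hits[0, ], ref), character(0))
})

test_that("cross-set positive edge counts match an exhaustive scan", {
  set.seed(29)
  nodes <- sprintf("n%02d", 1:12)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.4
  rho <- ifelse(runif(sum(keep)) < 0.5, 0.9, -0.9)
  net <- coexpression_network(
    nodes, data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                      rho = rho, pvalue = 1e-4),
    threshold_rho = 0.8, n_samples = 9)
  set_a <- nodes[1:5]
  set_b <- nodes[6:9]
  got <- cross_list_correlation_check(net, set_a, set_b)
  want <- 0
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    if (e$sign == "+" &&
        ((e$gene_a %in% set_a && e$gene_b %in% set_b) ||
         (e$gene_a %in% set_b && e$gene_b %in% set_a))) {
      want <- want + 1
    }
  }
  expect_equal(got, want)

  expect_warning(
    overlap <- cross_list_correlation_check(net, nodes[1:5], nodes[5:9]),
    "both sets")
  # shared node n05 excluded from both sides
  expect_equal(overlap,
               cross_list_correlation_check(net, nodes[1:4], nodes[6:9]))
})
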