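#' Curated reference tables from a published poplar dual-stress re-analysis
#'
#' Two small tables of published results on *Populus trichocarpa* roots,
#' shipped for cross-checking the pipeline's categorical logic:
#'
#' * `tf_calls` — the 25 transcription factors with more than two-fold
#'   transcriptional variation under aluminium stress: gene id, predicted
#'   TF family, and the regulation call (positive/negative, or `NA` where
#'   no call was made) at 6, 54 and 246 hours of exposure.
#' * `concordance` — the eight genes regulated in the same direction
#'   (variation of at least 20%) by both severe phosphate starvation and
#'   6-hour aluminium stress: gene id, best *A. thaliana* BLAST hit, the
#'   phosphorus and aluminium regulation coefficients, and the shared
#'   direction.
#'
#' @return List with data frames `tf_calls` (25 rows) and `concordance`
#'   (8 rows).
#' @examples
#' ref <- reference_tables()
#' nrow(ref$tf_calls)
#' table(ref$concordance$direction)
#' @export
reference_tables <- function() {
  tf <- data.frame(
    gene_id = c(
      "Potri.017G099800.1", "Potri.019G011500.1", "Potri.015G016100.1",
      "Potri.015G017000.1", "Potri.001G137800.2", "Potri.012G133800.1",
      "Potri.003G103500.1", "Potri.009G117200.2", "Potri.014G047000.1",
      "Potri.010G143600.1", "Potri.001G214900.1", "Potri.001G220500.1",
      "Potri.T050600.1", "Potri.T144800.1", "Potri.002G129900.1",
      "Potri.001G197000.1", "Potri.001G461000.1", "Potri.003G214000.1",
      "Potri.012G024200.1", "Potri.012G133700.1", "Potri.005G095100.1",
      "Potri.002G228700.1", "Potri.006G048700.2", "Potri.006G105300.1",
      "Potri.010G167500.1"),
    family = c(
      "MIKC-MADS", "GRAS", "B3", "B3", "HD-ZIP", "ARR-B", "NAC",
      "MYB_related", "ERF", "GRAS", "M-type-MADS", "NAC", "ERF", "MYB",
      "B3", "MYB", "bHLH", "C2H2", "NAC", "LBD", "GRAS", "MYB",
      "MIKC-MADS", "WRKY", "MYB"),
    call_6h = c(
      "negative", "positive", "positive", "positive", "negative",
      "negative", "negative", "negative", "negative", "negative",
      "positive", "negative", "positive", "negative", "negative",
      "negative", "negative", "negative", "negative", "negative",
      "positive", "negative", "negative", "positive", "negative"),
    call_54h = c(
      "positive", NA, "positive", NA, "positive", NA, NA, NA, NA, NA, NA,
      NA, NA, "positive", NA, NA, "negative", NA, NA, "positive", NA,
      "positive", NA, "negative", NA),
    call_246h = c(
      "negative", "positive", "negative", "negative", NA, NA, NA, NA, NA,
      NA, NA, NA, NA, "positive", NA, NA, NA, NA, "positive", NA, NA, NA,
      NA, NA, NA),
    stringsAsFactors = FALSE
  )

  conc <- data.frame(
    gene_id = c(
      "Potri.003G034600", "Potri.010G071600", "Potri.010G071700",
      "Potri.001G218800", "Potri.002G002100", "Potri.010G072000",
      "Potri.014G092800", "Potri.010G193100"),
    best_hit = c(
      "AT1G17710.1", "AT2G38940.1", "AT2G38940.1", "AT3G44350.2",
      "AT1G21010.1", "AT2G38940.1", "AT5G24090.1", "AT2G38080.1"),
    p_coefficient = c(1.845046, 1.673688, 1.561246, 0.745537, 0.748707,
                      1.738861, 1.254137, 1.226961),
    al_coefficient = c(1.220214, 1.230394, 1.226014, 0.753407, 0.631502,
                       1.274632, 2.475638, 4.14973),
    direction = c("positive", "positive", "positive", "negative",
                  "negative", "positive", "positive", "positive"),
    stringsAsFactors = FALSE
  )
  list(tf_calls = tf, concordance = conc)
}

#' Read a reference gene list from TSV
#'
#' The file has columns `name` and `member_id` (one row per member; `#`
#' lines are comments). When `name` is given, only that list's members are
#' returned.
#'
#' @param path path to the TSV.
#' @param name optional list name to filter on.
#' @return Character vector of unique member ids.
#' @export
read_gene_list <- function(path, name = NULL) {
  tab <- read_tsv_strict(path, "gene list")
  miss <- setdiff(c("name", "member_id"), names(tab))
  if (length(miss) > 0) {
    stop("gene list missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(name)) {
    tab <- tab[tab$name == name, , drop = FALSE]
    if (nrow(tab) == 0) stop("no members for list: ", name)
  }
  unique(as.character(tab$member_id))
}
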