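#' Expression matrix container
#'
#' Holds a genes x libraries grid of log2 intensities, a parallel grid of
#' present/absent detection flags, and the experimental design. Column
#' order always follows the design's library order.
#'
#' @param values numeric matrix of log2 intensities; rownames are gene (or
#'   probe) ids, colnames are library ids.
#' @param design an [experiment_design()] covering exactly the matrix
#'   columns.
#' @param present logical matrix of the same dimension; `NULL` means all
#'   measurements are treated as present.
#' @return An object of class `expression_matrix` with elements `values`,
#'   `present`, `design`.
#' @export
expression_matrix <- function(values, design, present = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have library ids as colnames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id: ", rownames(values)[duplicated(rownames(values))][1])
  }
  validate_design(design)
  extra <- setdiff(colnames(values), design$library_id)
  if (length(extra) > 0) {
    stop("library in matrix absent from design: ", paste(extra, collapse = ", "))
  }
  missing_lib <- setdiff(design$library_id, colnames(values))
  if (length(missing_lib) > 0) {
    stop("library in design absent from matrix: ",
         paste(missing_lib, collapse = ", "))
  }
  values <- values[, design$library_id, drop = FALSE]
  if (any(!is.finite(values))) {
    stop("non-finite intensity values in matrix")
  }
  if (is.null(present)) {
    present <- matrix(TRUE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  } else {
    if (!is.matrix(present) || !is.logical(present)) {
      stop("present must be a logical matrix")
    }
    if (!identical(dim(present), dim(values))) {
      stop("present flags and values have different dimensions")
    }
    if (!is.null(colnames(present))) {
      present <- present[, design$library_id, drop = FALSE]
    }
    dimnames(present) <- dimnames(values)
    if (anyNA(present)) stop("present flags contain missing cells")
  }
  structure(list(values = values, present = present, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d libraries (%d conditions)\n",
              nrow(x$values), ncol(x$values), length(unique(x$design$condition))))
  cat(sprintf("  present calls: %.1f%%\n", 100 * mean(x$present)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene ids of an expression matrix
#' @param mat an `expression_matrix`.
#' @return Character vector of gene ids in matrix order.
#' @export
genes <- function(mat) rownames(mat$values)

# Strict TSV reader: rejects ragged tables before type conversion.
read_tsv_strict <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0) stop("empty ", what, " in ", path)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged %s in %s: line %d has %d fields, expected %d",
                 what, path, keep[bad], nf[bad], nf[1]))
  }
  utils::read.delim(text = paste(lines[keep], collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

#' Read an expression matrix, its design and optional present flags from TSV
#'
#' The matrix file has a `gene_id` first column and one column per library.
#' The design file has columns `library_id`, `condition`, `replicate`,
#' `control_condition`, `timepoint_hours`. The optional flags file mirrors
#' the matrix layout with TRUE/FALSE (or 1/0) cells; when omitted, all
#' measurements are flagged present.
#'
#' @param matrix_path path to the intensity TSV.
#' @param design_path path to the design TSV.
#' @param present_path optional path to the present/absent TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_path, design_path,
                                   present_path = NULL) {
  tab <- read_tsv_strict(matrix_path, "expression matrix")
  if (names(tab)[1] != "gene_id") {
    stop("first column of ", matrix_path, " must be 'gene_id', found '",
         names(tab)[1], "'")
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene id: ", tab$gene_id[duplicated(tab$gene_id)][1])
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric intensity cell in ", matrix_path)
  rownames(values) <- tab$gene_id

  dtab <- read_tsv_strict(design_path, "design")
  design <- experiment_design(
    library_id = dtab$library_id,
    condition = dtab$condition,
    replicate = dtab$replicate,
    control_condition = if ("control_condition" %in% names(dtab)) {
      ifelse(dtab$control_condition %in% c("", "NA"), NA_character_,
             as.character(dtab$control_condition))
    } else NA_character_,
    timepoint_hours = if ("timepoint_hours" %in% names(dtab)) {
      suppressWarnings(as.numeric(dtab$timepoint_hours))
    } else NA_real_
  )

  present <- NULL
  if (!is.null(present_path)) {
    ptab <- read_tsv_strict(present_path, "present flags")
    if (names(ptab)[1] != "gene_id") {
      stop("first column of ", present_path, " must be 'gene_id'")
    }
    pm <- as.matrix(ptab[, -1, drop = FALSE])
    present <- matrix(as.logical(pm), nrow(pm), ncol(pm))
    dimnames(present) <- list(ptab$gene_id, colnames(pm))
    if (!identical(rownames(present), rownames(values))) {
      stop("present flags and matrix list different genes")
    }
    present <- present[, colnames(values), drop = FALSE]
  }
  expression_matrix(values, design, present)
}

#' Write an expression matrix (and design, and flags) to TSV
#'
#' Output is deterministic: genes in matrix order, libraries in design
#' order, tab-separated with "." decimals and no quoting.
#'
#' @param mat an `expression_matrix`.
#' @param matrix_path output path for intensities.
#' @param design_path optional output path for the design.
#' @param present_path optional output path for the present/absent flags.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression_matrix <- function(mat, matrix_path, design_path = NULL,
                                    present_path = NULL) {
  df <- data.frame(gene_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(design_path)) {
    utils::write.table(as.data.frame(mat$design), design_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(present_path)) {
    pf <- data.frame(gene_id = rownames(mat$present),
                     ifelse(mat$present, "TRUE", "FALSE"),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(pf) <- c("gene_id", colnames(mat$present))
    utils::write.table(pf, present_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Relabel probe rows with gene ids via a best-hit map
#'
#' Rows whose probe id has a best hit are renamed to the hit's subject
#' gene id; probes without a hit are dropped. When two or more probes map
#' to the same gene, the probe with the highest mean intensity is kept.
#'
#' @param mat an `expression_matrix` whose rows are probe ids.
#' @param best_hits a best-hit map from [best_hit_map()].
#' @return An `expression_matrix` with gene-id rows.
#' @export
relabel_probes <- function(mat, best_hits) {
  probes <- intersect(rownames(mat$values), best_hits$query)
  if (length(probes) == 0) stop("no probe in the matrix has a best hit")
  subj <- best_hits$subject[match(probes, best_hits$query)]
  means <- rowMeans(mat$values[probes, , drop = FALSE])
  ord <- order(subj, -means, probes)
  keep <- probes[ord][!duplicated(subj[ord])]
  gene_ids <- subj[match(keep, probes)]
  values <- mat$values[keep, , drop = FALSE]
  present <- mat$present[keep, , drop = FALSE]
  rownames(values) <- gene_ids
  rownames(present) <- gene_ids
  ord2 <- order(gene_ids)
  expression_matrix(values[ord2, , drop = FALSE], mat$design,
                    present[ord2, , drop = FALSE])
}
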