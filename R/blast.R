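#' Read tabular BLAST output (outfmt 6) with e-value and hit-count filters
#'
#' Expects the standard 12 columns: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore. Hits with
#' `evalue < max_evalue` are retained; within each query, hits are sorted
#' by ascending e-value, then descending bitscore, then subject id (for
#' full determinism), truncated to `max_hits_per_query`, and ranked from 1.
#' The result is independent of input row order.
#'
#' @param path path to the tabular BLAST file.
#' @param max_evalue strict upper bound on the e-value (default `1e-5`).
#' @param max_hits_per_query maximum retained hits per query (default 10).
#' @return Data frame of class `homology_hits` with columns `query`,
#'   `subject`, `pident`, `evalue`, `bitscore`, `rank`.
#' @export
read_blast_tabular <- function(path, max_evalue = 1e-5,
                               max_hits_per_query = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(cols)
  if (any(n_fields != 12)) {
    bad <- which(n_fields != 12)[1]
    stop(sprintf("malformed BLAST row at line %d of %s: %d fields, expected 12",
                 bad, path, n_fields[bad]))
  }
  m <- do.call(rbind, cols)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  bitscore <- suppressWarnings(as.numeric(m[, 12]))
  pident <- suppressWarnings(as.numeric(m[, 3]))
  bad_num <- which(is.na(evalue) | is.na(bitscore) | is.na(pident))
  if (length(bad_num) > 0) {
    stop(sprintf("malformed BLAST row at line %d of %s: non-numeric field",
                 bad_num[1], path))
  }
  hits <- data.frame(query = m[, 1], subject = m[, 2], pident = pident,
                     evalue = evalue, bitscore = bitscore,
                     stringsAsFactors = FALSE)
  rank_hits(hits, max_evalue, max_hits_per_query)
}

#' @keywords internal
rank_hits <- function(hits, max_evalue, max_hits_per_query) {
  hits <- hits[hits$evalue < max_evalue, , drop = FALSE]
  ord <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  rk <- stats::ave(seq_len(nrow(hits)), hits$query, FUN = seq_along)
  hits$rank <- as.integer(rk)
  hits <- hits[hits$rank <= max_hits_per_query, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("homology_hits", "data.frame")
  hits
}

#' Best (rank-1) hit per query
#' @param hits a ranked `homology_hits` data frame.
#' @return Data frame with one row per query: the rank-1 hit.
#' @export
best_hit_map <- function(hits) {
  if (nrow(hits) == 0) {
    out <- hits[0, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (!"rank" %in% names(hits)) stop("hits must carry a rank column")
  out <- hits[hits$rank == 1, , drop = FALSE]
  out <- out[order(out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}
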