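#' Write Cluster 3.0 / Java TreeView compatible files
#'
#' Exports a two-way clustering as the classic triplet of tab-delimited
#' files: a CDT holding the matrix reordered to dendrogram leaf order,
#' a GTR describing the row tree and an ATR describing the column tree.
#' Identifier conventions follow Cluster 3.0: rows are `GENE<i>X`,
#' columns `ARRY<j>X` (both 0-based in original matrix order) and merge
#' nodes `NODE<s>X` (1-based in merge order). Each tree line is
#' `node id, child id, child id, join similarity`; with average linkage
#' the join similarities are non-increasing down the file.
#'
#' @param tw a `"chi_two_way"` clustering (see [two_way_cluster()]).
#' @param cdt,gtr,atr output file paths.
#' @return Invisibly, a named list of the three paths.
#' @export
write_cdt_gtr_atr <- function(tw, cdt, gtr, atr) {
  stopifnot(inherits(tw, "chi_two_way"))
  m <- tw$matrix
  if (!identical(rownames(m), tw$rows$labels) ||
      !identical(colnames(m), tw$cols$labels)) {
    stop("dendrogram leaf sets do not match the matrix axes", call. = FALSE)
  }
  row_ids <- sprintf("GENE%dX", seq_len(nrow(m)) - 1L)
  col_ids <- sprintf("ARRY%dX", seq_len(ncol(m)) - 1L)

  writeLines(tree_lines(tw$rows, row_ids), gtr)
  writeLines(tree_lines(tw$cols, col_ids), atr)

  ro <- tw$rows$order
  co <- tw$cols$order
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m)[co]),
                  collapse = "\t")
  aid <- paste(c("AID", "", "", "", col_ids[co]), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "", rep("1", ncol(m))),
                   collapse = "\t")
  body <- vapply(ro, function(i) {
    paste(c(row_ids[i], rownames(m)[i], rownames(m)[i], "1",
            format_num(m[i, co])), collapse = "\t")
  }, character(1))
  writeLines(c(header, aid, eweight, body), cdt)
  invisible(list(cdt = cdt, gtr = gtr, atr = atr))
}

tree_lines <- function(dend, leaf_ids) {
  n <- length(dend$labels)
  child_id <- function(id) {
    if (id < 0L) leaf_ids[-id] else sprintf("NODE%dX", id)
  }
  vapply(seq_len(n - 1L), function(s) {
    paste(sprintf("NODE%dX", s),
          child_id(dend$merge[s, 1]),
          child_id(dend$merge[s, 2]),
          format_num(dend$similarity[s]),
          sep = "\t")
  }, character(1))
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 10)
  trimws(out)
}

#' Read the data matrix back out of a CDT file
#'
#' Returns the reordered matrix exactly as written by
#' [write_cdt_gtr_atr()]; used for round-trip checks and downstream
#' consumption of clustered output.
#'
#' @param path CDT file path.
#' @return Numeric matrix in CDT (leaf) order.
#' @export
read_cdt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  header <- lines[[1]]
  genes <- header[-(1:4)]
  body <- lines[-(1:3)]
  vals <- t(vapply(body, function(r) as.numeric(r[-(1:4)]),
                   numeric(length(genes))))
  rownames(vals) <- vapply(body, `[[`, character(1), 2L)
  colnames(vals) <- genes
  vals
}
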