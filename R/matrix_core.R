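#' Construct and validate a CHI interaction matrix
#'
#' An interaction matrix records the outcome of a complex heterozygosity
#' (CHI) screen: rows are query alleles, columns are the deletion-allele
#' genes they were crossed against, and each cell holds a growth-defect
#' score. A score of 0 means no interaction was observed; scores 1--3 grade
#' the severity of the digenic defect, with 1 = lethality, 2 = a severe
#' growth defect, and 3 = a mildly reduced colony size.
#'
#' @param score integer matrix of scores in `{0, 1, 2, 3}` with allele ids
#'   as row names and gene ids as column names.
#' @return An integer matrix of class `"chi_matrix"`.
#' @examples
#' m <- chi_matrix(matrix(c(1L, 0L, 0L, 3L), 2, 2,
#'                        dimnames = list(c("a1", "a2"), c("g1", "g2"))))
#' to_edge_list(m)
#' @export
chi_matrix <- function(score) {
  if (!is.matrix(score)) {
    stop("`score` must be a matrix", call. = FALSE)
  }
  storage.mode(score) <- "integer"
  validate_chi_matrix(score)
  structure(score, class = c("chi_matrix", class(unclass(score))))
}

validate_chi_matrix <- function(score) {
  if (is.null(rownames(score)) || is.null(colnames(score))) {
    stop("interaction matrix needs allele row names and gene column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(score))) {
    stop("duplicate allele ids: ",
         paste(unique(rownames(score)[duplicated(rownames(score))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(score))) {
    stop("duplicate gene ids: ",
         paste(unique(colnames(score)[duplicated(colnames(score))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(score)) {
    stop("interaction matrix must not contain missing cells", call. = FALSE)
  }
  bad <- !(score %in% 0:3)
  if (any(bad)) {
    stop("scores must lie in {0, 1, 2, 3}; offending values: ",
         paste(utils::head(unique(score[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(score)
}

#' @export
print.chi_matrix <- function(x, ...) {
  cat(sprintf("CHI interaction matrix: %d alleles x %d genes, %d interactions\n",
              nrow(x), ncol(x), sum(x > 0)))
  invisible(x)
}

#' Reverse score weights for clustering
#'
#' Severity scores rank 1 as the strongest defect (lethality) and 3 as the
#' mildest, but similarity-based clustering needs the opposite convention:
#' the strongest interaction must carry the largest weight so that weak
#' scores sit closest to non-interactions. Scores 1--3 are mapped to weights
#' `4 - score` (1 -> 3, 2 -> 2, 3 -> 1) and non-interactions stay 0.
#'
#' @param m a [chi_matrix()].
#' @return An integer matrix of class `"chi_weighted"` with the same axes,
#'   weights in `{0, 1, 2, 3}` where 3 is now the strongest interaction.
#' @export
reverse_weights <- function(m) {
  m <- as_chi_matrix(m)
  w <- unclass(m)
  nz <- w > 0L
  w[nz] <- 4L - w[nz]
  class(w) <- setdiff(class(w), "chi_matrix")
  structure(w, class = c("chi_weighted", class(w)))
}

as_chi_matrix <- function(m) {
  if (inherits(m, "chi_matrix")) return(m)
  chi_matrix(m)
}

#' @export
print.chi_weighted <- function(x, ...) {
  cat(sprintf("weight-reversed CHI matrix: %d alleles x %d genes (3 = strongest)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read / write an interaction matrix
#'
#' Matrices are stored as tab-delimited text: first row gene ids (first
#' field empty or a corner label), first column allele ids, cells either
#' blank, or an integer 0--3. Blank cells are read as 0; on write every
#' cell is emitted explicitly, so `read_chi_matrix(write_chi_matrix(m))`
#' round-trips exactly.
#'
#' @param path file path.
#' @return [read_chi_matrix()] returns a [chi_matrix()];
#'   [write_chi_matrix()] returns `path` invisibly.
#' @export
read_chi_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop("matrix file needs a header line and at least one allele row",
         call. = FALSE)
  }
  # sentinel keeps trailing blank cells that strsplit would drop
  fields <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) sub("\x01$", "", f))
  header <- fields[[1]]
  genes <- header[-1]
  n_field <- length(header)
  rows <- fields[-1]
  widths <- lengths(rows)
  if (any(widths != n_field)) {
    stop("ragged matrix file: line ",
         which(widths != n_field)[1] + 1L, " has ", widths[widths != n_field][1],
         " fields, expected ", n_field, call. = FALSE)
  }
  alleles <- vapply(rows, `[[`, character(1), 1L)
  cells <- t(vapply(rows, function(r) r[-1], character(length(genes))))
  if (length(genes) == 1L) cells <- matrix(cells, ncol = 1L)
  cells[cells == ""] <- "0"
  suppressWarnings(num <- matrix(as.integer(cells), nrow = length(alleles)))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[1]
    stop("non-integer cell on line ", bad + 1L, call. = FALSE)
  }
  dimnames(num) <- list(alleles, genes)
  chi_matrix(num)
}

#' @rdname read_chi_matrix
#' @param m a [chi_matrix()] (or coercible matrix).
#' @export
write_chi_matrix <- function(m, path) {
  m <- as_chi_matrix(m)
  header <- paste(c("allele", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Convert between a matrix and its nonzero edge list
#'
#' @param m a [chi_matrix()].
#' @return [to_edge_list()] returns a data frame with columns `allele`,
#'   `gene`, `score`, one row per nonzero cell (alleles in row order,
#'   genes in column order within allele).
#' @export
to_edge_list <- function(m) {
  m <- as_chi_matrix(m)
  idx <- which(t(unclass(m)) > 0L)  # transpose: order by allele then gene
  gene_i <- (idx - 1L) %% ncol(m) + 1L
  allele_i <- (idx - 1L) %/% ncol(m) + 1L
  data.frame(allele = rownames(m)[allele_i],
             gene = colnames(m)[gene_i],
             score = unclass(m)[cbind(allele_i, gene_i)],
             stringsAsFactors = FALSE)
}

#' @rdname to_edge_list
#' @param edges data frame with columns `allele`, `gene`, `score`.
#' @param allele_ids,gene_ids the full (ordered) axes of the matrix to
#'   rebuild; edges must reference only these ids.
#' @return [edge_list_to_matrix()] returns the [chi_matrix()] over the
#'   given axes with zeros where no edge is present.
#' @export
edge_list_to_matrix <- function(edges, allele_ids, gene_ids) {
  if (!all(edges$allele %in% allele_ids)) {
    stop("edge list references unknown alleles", call. = FALSE)
  }
  if (!all(edges$gene %in% gene_ids)) {
    stop("edge list references unknown genes", call. = FALSE)
  }
  m <- matrix(0L, length(allele_ids), length(gene_ids),
              dimnames = list(allele_ids, gene_ids))
  m[cbind(match(edges$allele, allele_ids), match(edges$gene, gene_ids))] <-
    as.integer(edges$score)
  chi_matrix(m)
}
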