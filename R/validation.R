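#' Replicate screen call sets
#'
#' A replicate set holds the interactions called in each of several
#' repeated screens of the same allele x gene grid. Each replicate is a
#' data frame with columns `allele`, `gene` (a called pair appears once).
#'
#' @param replicates list of data frames with columns `allele`, `gene`.
#' @param min_support minimum number of replicates a pair must appear in
#'   to enter the gold standard (default 2, i.e. "two or more screens").
#' @return A list of class `"chi_replicates"`.
#' @export
chi_replicates <- function(replicates, min_support = 2L) {
  if (!length(replicates)) {
    stop("need at least one replicate", call. = FALSE)
  }
  for (r in replicates) {
    if (!all(c("allele", "gene") %in% names(r))) {
      stop("each replicate needs `allele` and `gene` columns", call. = FALSE)
    }
  }
  min_support <- as.integer(min_support)
  if (min_support < 1L || min_support > length(replicates)) {
    stop("min_support must be between 1 and the number of replicates",
         call. = FALSE)
  }
  structure(list(replicates = replicates, min_support = min_support),
            class = "chi_replicates")
}

pair_keys <- function(df) {
  unique(paste(df$allele, df$gene, sep = "\r"))
}

keys_to_pairs <- function(keys) {
  if (!length(keys)) {
    return(data.frame(allele = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(allele = vapply(parts, `[[`, character(1), 1L),
             gene = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Build the replicate-supported gold standard
#'
#' The gold standard is the set of allele/gene pairs called in at least
#' `min_support` replicates (by default two or more).
#'
#' @param reps a [chi_replicates()] object (needs >= 2 replicates).
#' @return A data frame of pairs (`allele`, `gene`), sorted for
#'   reproducibility.
#' @export
build_standard <- function(reps) {
  stopifnot(inherits(reps, "chi_replicates"))
  if (length(reps$replicates) < 2L) {
    stop("gold standard needs at least two replicates", call. = FALSE)
  }
  support <- table(unlist(lapply(reps$replicates, pair_keys)))
  keys <- sort(names(support)[support >= reps$min_support])
  keys_to_pairs(keys)
}

#' Precision and recall of a screen against a standard
#'
#' Precision is the fraction of called pairs present in the standard;
#' recall is the fraction of the standard recovered by the calls.
#' Severity scores play no role: a pair is called if it was scored at all.
#'
#' @param called data frame of called pairs (`allele`, `gene`), non-empty.
#' @param standard data frame of gold-standard pairs, non-empty.
#' @return A list of class `"chi_validation"` with elements `n_called`,
#'   `n_standard`, `n_overlap`, `precision`, `recall`, and the two pair
#'   sets.
#' @export
precision_recall <- function(called, standard) {
  ck <- pair_keys(called)
  sk <- pair_keys(standard)
  if (!length(ck)) {
    stop("precision undefined: no called pairs", call. = FALSE)
  }
  if (!length(sk)) {
    stop("recall undefined: empty standard", call. = FALSE)
  }
  ov <- length(intersect(ck, sk))
  structure(list(n_called = length(ck), n_standard = length(sk),
                 n_overlap = ov,
                 precision = ov / length(ck), recall = ov / length(sk),
                 called = keys_to_pairs(sort(ck)),
                 standard = keys_to_pairs(sort(sk))),
            class = "chi_validation")
}

#' @export
print.chi_validation <- function(x, ...) {
  cat(sprintf(
    "screen validation: %d called, %d in standard, %d overlap\nprecision = %.1f%%, recall = %.1f%%\n",
    x$n_called, x$n_standard, x$n_overlap,
    100 * x$precision, 100 * x$recall))
  invisible(x)
}

#' Read / write replicate edge lists
#'
#' Each replicate is a tab-delimited file with columns `allele`, `gene`
#' (header included); scores, if present in a third column, are ignored
#' for validation.
#'
#' @param paths character vector of replicate file paths.
#' @param min_support passed to [chi_replicates()].
#' @export
read_replicates <- function(paths, min_support = 2L) {
  reps <- lapply(paths, function(p) {
    utils::read.delim(p, stringsAsFactors = FALSE)
  })
  chi_replicates(reps, min_support = min_support)
}

#' @rdname read_replicates
#' @param pairs data frame with columns `allele`, `gene`.
#' @param path output file path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("allele", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
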