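#' Interaction degree of every allele
#'
#' The degree of an allele is the number of genes it interacts with at any
#' severity (score > 0); the score itself is ignored.
#'
#' @param m a [chi_matrix()].
#' @return A data frame with columns `id`, `degree`, one row per allele in
#'   matrix order.
#' @export
allele_degrees <- function(m) {
  m <- as_chi_matrix(m)
  data.frame(id = rownames(m), degree = as.integer(rowSums(unclass(m) > 0L)),
             stringsAsFactors = FALSE)
}

#' @rdname allele_degrees
#' @export
gene_degrees <- function(m) {
  m <- as_chi_matrix(m)
  data.frame(id = colnames(m), degree = as.integer(colSums(unclass(m) > 0L)),
             stringsAsFactors = FALSE)
}

#' Histogram of gene interaction degrees
#'
#' Counts, for each degree value, how many genes interact with exactly
#' that many alleles. The degree-0 bin counts genes that interacted with
#' no query allele at all.
#'
#' @param m a [chi_matrix()].
#' @return A data frame with columns `degree`, `n_genes`; `sum(n_genes)`
#'   equals the number of genes.
#' @export
gene_degree_histogram <- function(m) {
  d <- gene_degrees(m)$degree
  tab <- table(factor(d, levels = 0:max(d)))
  out <- data.frame(degree = as.integer(names(tab)),
                    n_genes = as.integer(tab))
  out[out$n_genes > 0L | out$degree == 0L, , drop = FALSE]
}

#' Mean interaction degree by phenotype class
#'
#' @param degrees degree table from [allele_degrees()] (columns `id`,
#'   `degree`).
#' @param ann annotation data frame covering every allele in `degrees`.
#' @return A data frame with columns `phenotype`, `n_alleles`,
#'   `mean_degree` (full precision) and `mean_degree_1dp` (rounded to one
#'   decimal, the conventional reporting precision).
#' @export
phenotype_class_summary <- function(degrees, ann) {
  missing_ids <- setdiff(degrees$id, ann$allele_id)
  if (length(missing_ids)) {
    stop("unannotated alleles: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  cls <- ann$phenotype[match(degrees$id, ann$allele_id)]
  agg <- stats::aggregate(degrees$degree, by = list(phenotype = cls),
                   FUN = function(v) c(n = length(v), mean = mean(v)))
  out <- data.frame(phenotype = agg$phenotype,
                    n_alleles = as.integer(agg$x[, "n"]),
                    mean_degree = agg$x[, "mean"],
                    stringsAsFactors = FALSE)
  out$mean_degree_1dp <- round(out$mean_degree, 1)
  out[order(-out$mean_degree), , drop = FALSE]
}

#' Pearson correlation with confidence interval
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and a confidence
#' interval by Fisher's z transform, as used when correlating interaction
#' degree with quantitative gene features.
#'
#' @param x,y numeric vectors of equal length (n >= 4), neither constant.
#' @param confidence confidence level for the interval (default 0.95).
#' @return A list of class `"chi_correlation"` with elements `r`, `p`,
#'   `ci_low`, `ci_high`, `n`, `confidence`.
#' @export
pearson_with_ci <- function(x, y, confidence = 0.95) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 4L) {
    stop("need at least 4 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = confidence)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 n = length(x), confidence = confidence),
            class = "chi_correlation")
}

#' @export
print.chi_correlation <- function(x, ...) {
  cat(sprintf("r = %.4f (%d%% CI %.4f to %.4f), p = %.4g, n = %d\n",
              x$r, round(100 * x$confidence), x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Number of digenic combinations among n loci
#'
#' An individual carrying `n` loss-of-function loci has `n * (n - 1) / 2`
#' distinct pairwise (digenic) combinations, each a potential deleterious
#' complex-haploinsufficiency interaction.
#'
#' @param n_loci integer >= 2.
#' @return The number of unordered pairs, as a double (exact for any
#'   realistic n).
#' @examples
#' digenic_combinations(150)
#' @export
digenic_combinations <- function(n_loci) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci != round(n_loci)) {
    stop("n_loci must be a single integer", call. = FALSE)
  }
  if (n_loci < 2) {
    stop("need at least 2 loci", call. = FALSE)
  }
  n_loci * (n_loci - 1) / 2
}
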