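# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Correlation between profile similarity and structural distance
#'
#' Pearson correlation between the pairwise profile-similarity vector and
#' the pairwise structural-distance vector for one subunit configuration,
#' with two p-values: an analytic two-sided p from the t transform with
#' `n_pairs - 2` degrees of freedom, and a Mantel-style permutation p.
#' Because the pairwise observations share alleles and are therefore not
#' independent, the permutation p is the honest one: allele identities
#' are permuted jointly (relabelling rows and columns of the distance
#' relation together, never shuffling the flattened pair vector), and
#' the two-sided p counts permuted `|r| >= |observed r|` with the +1
#' correction.
#'
#' @param table a `"chi_pair_table"` from [distance_table()].
#' @param config which distance column to use: `"monomer"`, `"stacked"`
#'   or `"backed"`.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations (required, so results are
#'   reproducible).
#' @return A list of class `"chi_mantel"` with `r`, `p_analytic`,
#'   `p_permutation`, `n_pairs`, `n_alleles`, `n_permutations`, `seed`,
#'   `config`.
#' @export
similarity_distance_correlation <- function(table,
                                            config = c("stacked", "monomer",
                                                       "backed"),
                                            n_perm = 10000L, seed) {
  config <- match.arg(config)
  if (missing(seed)) stop("a permutation seed is required", call. = FALSE)
  pairs <- table$pairs
  dcol <- paste0("d_", config)

  # alleles in canonical order so results do not depend on input order
  alleles <- sort(unique(c(pairs$allele_a, pairs$allele_b)))
  n <- length(alleles)
  S <- matrix(NA_real_, n, n, dimnames = list(alleles, alleles))
  D <- S
  ia <- match(pairs$allele_a, alleles)
  ib <- match(pairs$allele_b, alleles)
  S[cbind(ia, ib)] <- S[cbind(ib, ia)] <- pairs$similarity
  D[cbind(ia, ib)] <- D[cbind(ib, ia)] <- pairs[[dcol]]

  # restrict to alleles with every distance defined (Mantel needs a
  # complete relabel-able relation)
  ok <- colSums(is.na(D)) <= 1L  # only the diagonal NA allowed
  if (any(!ok)) {
    keep <- alleles[ok]
    S <- S[keep, keep, drop = FALSE]
    D <- D[keep, keep, drop = FALSE]
    n <- length(keep)
  }
  lt <- lower.tri(D)
  sv <- S[lt]
  dv <- D[lt]
  if (length(dv) < 10L) {
    stop("need at least 10 fully defined pairs", call. = FALSE)
  }
  if (stats::sd(dv) == 0) {
    stop("distance vector is constant; correlation undefined", call. = FALSE)
  }
  r <- stats::cor(sv, dv)
  np <- length(dv)
  tstat <- r * sqrt(np - 2) / sqrt(1 - r^2)
  p_analytic <- 2 * stats::pt(abs(tstat), df = np - 2, lower.tail = FALSE)

  n_perm <- as.integer(n_perm)
  exceed <- with_local_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      rp <- stats::cor(sv, D[perm, perm][lt])
      if (abs(rp) >= abs(r) - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  p_permutation <- (exceed + 1L) / (n_perm + 1L)

  structure(list(r = r, p_analytic = p_analytic,
                 p_permutation = p_permutation,
                 n_pairs = np, n_alleles = n,
                 n_permutations = n_perm, seed = seed, config = config),
            class = "chi_mantel")
}

#' @export
print.chi_mantel <- function(x, ...) {
  cat(sprintf(
    "%s configuration: r = %.4f over %d pairs (%d alleles)\n  p_analytic = %.4g, p_permutation = %.4g (%d permutations, seed %s)\n",
    x$config, x$r, x$n_pairs, x$n_alleles, x$p_analytic, x$p_permutation,
    x$n_permutations, format(x$seed)))
  invisible(x)
}

#' Split alleles into exposed and obscured surface-region groups
#'
#' Combines the four surface-location classes into two groups: the
#' exposed/filament-stacking regions (front plus top/bottom) versus the
#' regions tucked inside the filament (back plus side). Alleles located
#' in the ATP cleft (not on the surface) or with undetermined location
#' (ND) are excluded and listed.
#'
#' @param ann annotation data frame with a normalised `location` column.
#' @return A list with `front_top_bottom`, `back_side` and `excluded`
#'   allele-id vectors.
#' @export
region_groups <- function(ann) {
  loc <- normalize_location(ann$location)
  a <- ann$allele_id[loc %in% c("front", "top/bottom")]
  b <- ann$allele_id[loc %in% c("back", "side")]
  excluded <- ann$allele_id[loc %in% c("ATP cleft", "ND")]
  if (!length(b)) {
    warning("back/side group is empty", call. = FALSE)
  }
  list(front_top_bottom = a, back_side = b, excluded = excluded)
}

#' Wilcoxon rank-sum comparison of two degree distributions
#'
#' Two-sided Wilcoxon rank-sum test: the exact null distribution is used
#' when both groups have at most 12 observations and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' The reported statistic is the rank sum of group A.
#'
#' @param a,b numeric vectors (e.g. interaction degrees of two allele
#'   groups), both non-empty.
#' @return A list of class `"chi_ranksum"` with `median_a`, `median_b`,
#'   `statistic` (rank-sum of A), `p`, `exact`.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(a, b)))
  use_exact <- length(a) <= 12L && length(b) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  ranksum_a <- unname(wt$statistic) + length(a) * (length(a) + 1) / 2
  structure(list(median_a = stats::median(a), median_b = stats::median(b),
                 statistic = ranksum_a, p = wt$p.value, exact = use_exact),
            class = "chi_ranksum")
}

#' @export
print.chi_ranksum <- function(x, ...) {
  cat(sprintf(
    "rank-sum test (%s): medians %.4g vs %.4g, rank-sum A = %.4g, p = %.4g\n",
    if (x$exact) "exact" else "normal approximation",
    x$median_a, x$median_b, x$statistic, x$p))
  invisible(x)
}
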