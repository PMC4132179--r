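#' Parse a mutation specification string
#'
#' Alanine-scan alleles are described by comma-separated substitution
#' tokens such as `"D363A,E364A"`: wild-type residue (one-letter code),
#' position in mature-protein numbering, mutant residue.
#'
#' @param text a single non-empty specification string.
#' @return A data frame with one row per substitution and columns
#'   `wild_type`, `position` (integer, >= 1), `mutant`, in token order.
#' @examples
#' parse_mutation_spec("D363A,E364A")
#' @export
parse_mutation_spec <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("mutation spec must be a single non-empty string", call. = FALSE)
  }
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  pat <- sprintf("^([%s])([0-9]+)([%s])$", aa, aa)
  ok <- grepl(pat, tokens)
  if (any(!ok)) {
    stop("malformed substitution token: '", tokens[!ok][1], "'", call. = FALSE)
  }
  pos <- as.integer(sub(pat, "\\2", tokens))
  if (any(pos < 1L)) {
    stop("substitution position must be >= 1 in token '",
         tokens[pos < 1L][1], "'", call. = FALSE)
  }
  data.frame(wild_type = sub(pat, "\\1", tokens),
             position = pos,
             mutant = sub(pat, "\\3", tokens),
             stringsAsFactors = FALSE)
}

#' Closed vocabularies for allele annotation
#'
#' @name chi_vocabularies
#' @keywords internal
NULL

chi_phenotype_classes <- c(
  "wild type", "Ts-", "Cs- Ts-", "weak Ts-", "lethal recessive",
  "lethal partial dominant", "Ts- weakly dominant", "other")

chi_location_classes <- c("front", "back", "side", "top/bottom",
                          "ATP cleft", "ND")

#' Normalise a free-text phenotype label to its class
#'
#' Published tables write phenotype classes with varying punctuation and
#' superscripts ("Lethal, partial dominant", "Cs^-, Ts^-, recessive", ...).
#' Classes are recovered case-insensitively after stripping punctuation,
#' superscript markers and the redundant "recessive" qualifier; anything
#' unrecognised maps to `"other"`.
#'
#' @param x character vector of phenotype labels.
#' @return Character vector drawn from the closed phenotype vocabulary.
#' @export
normalize_phenotype <- function(x) {
  key <- gsub("−", "-", tolower(x))  # unicode minus
  key <- gsub("[^a-z-]+", " ", key)
  key <- gsub(" *- *", "- ", key)
  key <- gsub("\\s+", " ", trimws(key))
  out <- character(length(x))
  for (i in seq_along(key)) {
    k <- key[i]
    out[i] <-
      if (grepl("wild ?type", k)) "wild type"
      else if (grepl("lethal", k) && grepl("partial", k)) "lethal partial dominant"
      else if (grepl("lethal", k)) "lethal recessive"
      else if (grepl("cs ?-", k) && grepl("ts ?-", k)) "Cs- Ts-"
      else if (grepl("weak ts ?-", k)) "weak Ts-"
      else if (grepl("ts ?-", k) && grepl("weakly dominant", k)) "Ts- weakly dominant"
      else if (grepl("ts ?-", k)) "Ts-"
      else "other"
  }
  out
}

#' Normalise a location label
#'
#' @param x character vector of surface-location labels.
#' @return Character vector drawn from the closed location vocabulary;
#'   unknown labels raise an error.
#' @export
normalize_location <- function(x) {
  key <- tolower(trimws(x))
  map <- c("front" = "front", "back" = "back", "side" = "side",
           "top/bottom" = "top/bottom", "top-bottom" = "top/bottom",
           "atp cleft" = "ATP cleft", "nd" = "ND")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unknown location label: '", x[is.na(out)][1], "'", call. = FALSE)
  }
  out
}

#' Read / write allele annotation tables
#'
#' Tab-delimited with columns `allele_id`, `mutation_spec`, `phenotype`,
#' `location` and optionally `interactions` (the published per-allele
#' interaction count, retained when present). Phenotype and location are
#' normalised to the closed vocabularies on read.
#'
#' @param path file path.
#' @return A data frame of class `"chi_annotation"` with columns
#'   `allele_id`, `mutation_spec`, `phenotype`, `location` (and
#'   `interactions` if present); the parsed substitutions are available
#'   via [allele_substitutions()].
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("allele_id", "mutation_spec", "phenotype", "location")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$allele_id)) {
    stop("duplicate allele ids in annotation table", call. = FALSE)
  }
  ann$phenotype <- normalize_phenotype(ann$phenotype)
  ann$location <- normalize_location(ann$location)
  for (s in ann$mutation_spec) parse_mutation_spec(s)  # validate early
  class(ann) <- c("chi_annotation", class(ann))
  ann
}

#' @rdname read_annotations
#' @param ann annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Substitutions of every annotated allele
#'
#' @param ann annotation data frame (see [read_annotations()]).
#' @return A data frame with columns `allele_id`, `wild_type`, `position`,
#'   `mutant`: one row per substitution across all alleles.
#' @export
allele_substitutions <- function(ann) {
  subs <- lapply(seq_len(nrow(ann)), function(i) {
    cbind(allele_id = ann$allele_id[i],
          parse_mutation_spec(ann$mutation_spec[i]))
  })
  do.call(rbind, subs)
}

#' The act1 alanine-scan allele table
#'
#' The published annotation table for the 32 actin (act1) alanine-scan
#' query alleles used in yeast complex heterozygosity screening: mutation
#' specification, phenotype class, surface-location class and the number
#' of CHI interactions observed per allele. Bundled as the package's
#' reference annotation fixture.
#'
#' @return A `"chi_annotation"` data frame with 32 rows and columns
#'   `allele_id`, `mutation_spec`, `phenotype`, `location`,
#'   `interactions`.
#' @examples
#' ann <- act1_alleles()
#' mean(ann$interactions)
#' @export
act1_alleles <- function() {
  read_annotations(system.file("extdata", "act1_alleles.tsv",
                               package = "chiscreen", mustWork = TRUE))
}
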