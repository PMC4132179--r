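#' Read alpha-carbon coordinates from a PDB file
#'
#' Retains only Calpha atoms from ATOM records (first alternate location
#' wins; insertion codes are rejected so that residue sequence numbers
#' are unambiguous keys). Subunits are keyed by chain identifier.
#'
#' @param path PDB-format file.
#' @param chains optional character vector restricting the subunits kept.
#' @return An object of class `"chi_structure"`: a named list of
#'   subunits, each an `n x 3` coordinate matrix (columns x, y, z in
#'   Angstrom) with residue sequence numbers as row names.
#' @export
read_pdb_calpha <- function(path, chains = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!nrow(at)) {
    stop("no Calpha ATOM records in ", path, call. = FALSE)
  }
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes are not supported", call. = FALSE)
  }
  # first altloc wins
  at <- at[!duplicated(at[, c("chain", "resno")]), , drop = FALSE]
  if (!is.null(chains)) {
    at <- at[at$chain %in% chains, , drop = FALSE]
    if (!nrow(at)) {
      stop("no Calpha atoms in requested chains", call. = FALSE)
    }
  }
  subunits <- lapply(split(at, at$chain), function(a) {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    rownames(xyz) <- a$resno
    xyz
  })
  structure(subunits, class = "chi_structure")
}

#' @export
print.chi_structure <- function(x, ...) {
  cat(sprintf("structure model: %d subunit(s) [%s], %s residues\n",
              length(x), paste(names(x), collapse = ", "),
              paste(vapply(x, nrow, integer(1)), collapse = "/")))
  invisible(x)
}

#' Declared filament topology
#'
#' Which subunit pairs of a filament model are intrastrand ("stacked",
#' long-pitch neighbours) and which are interstrand ("backed") is
#' explicit configuration: deposited filament models do not name their
#' neighbour relations, and every distance below depends on the choice.
#'
#' @param stacked_pairs,backed_pairs two-column character matrices (or
#'   data frames) of subunit-id pairs.
#' @param model optional `"chi_structure"`; if given, all referenced
#'   subunits must exist in it.
#' @return A list of class `"chi_topology"`.
#' @export
filament_topology <- function(stacked_pairs, backed_pairs, model = NULL) {
  as_pairs <- function(p) {
    p <- as.matrix(p)
    if (!is.null(p) && length(p) && ncol(p) != 2L) {
      stop("subunit pairs must have two columns", call. = FALSE)
    }
    storage.mode(p) <- "character"
    p
  }
  topo <- structure(list(stacked_pairs = as_pairs(stacked_pairs),
                         backed_pairs = as_pairs(backed_pairs)),
                    class = "chi_topology")
  if (!is.null(model)) {
    ids <- unique(c(topo$stacked_pairs, topo$backed_pairs))
    unknown <- setdiff(ids, names(model))
    if (length(unknown)) {
      stop("topology references unknown subunit(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  topo
}

#' @rdname filament_topology
#' @param path tab-delimited topology file with columns `kind`
#'   (`stacked`/`backed`), `subunit_a`, `subunit_b`.
#' @export
read_topology <- function(path, model = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  filament_topology(df[df$kind == "stacked", c("subunit_a", "subunit_b")],
                    df[df$kind == "backed", c("subunit_a", "subunit_b")],
                    model = model)
}

#' @rdname filament_topology
#' @param topo a `"chi_topology"`.
#' @export
write_topology <- function(topo, path) {
  df <- rbind(
    data.frame(kind = "stacked", subunit_a = topo$stacked_pairs[, 1],
               subunit_b = topo$stacked_pairs[, 2]),
    data.frame(kind = "backed", subunit_a = topo$backed_pairs[, 1],
               subunit_b = topo$backed_pairs[, 2]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map an allele's mutated residues to Calpha coordinates
#'
#' @param mutation_spec mutation string, e.g. `"D363A,E364A"` (see
#'   [parse_mutation_spec()]).
#' @param model a `"chi_structure"`.
#' @param subunit subunit (chain) id to map onto.
#' @return A list with `coords` (matrix of found Calpha positions, one
#'   row per resolved substitution), `unresolved` (positions absent from
#'   the model) and `usable` (`TRUE` if at least one residue resolved).
#'   Alleles whose residues are all unresolved are unusable for distance
#'   analysis.
#' @export
map_allele_residues <- function(mutation_spec, model, subunit) {
  if (!subunit %in% names(model)) {
    stop("unknown subunit: ", subunit, call. = FALSE)
  }
  pos <- parse_mutation_spec(mutation_spec)$position
  xyz <- model[[subunit]]
  hit <- as.character(pos) %in% rownames(xyz)
  coords <- xyz[as.character(pos[hit]), , drop = FALSE]
  list(coords = coords, unresolved = pos[!hit], usable = any(hit))
}

#' Minimum Calpha--Calpha distance between two residue sets
#'
#' The shortest straight-line distance between the alpha carbons of the
#' two nearest residues, one drawn from each set.
#'
#' @param a,b non-empty coordinate matrices (columns x, y, z).
#' @return Distance in Angstrom.
#' @export
min_ca_distance <- function(a, b) {
  a <- rbind(a)
  b <- rbind(b)
  if (!nrow(a) || !nrow(b)) {
    stop("empty coordinate set", call. = FALSE)
  }
  # squared cross-distances via the expansion |a - b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Distance between two alleles in a given subunit configuration
#'
#' In the `monomer` configuration both alleles' residues live on one
#' subunit. In the `stacked` and `backed` configurations the two alleles
#' sit on two different subunits: for every declared subunit pair of the
#' requested kind the minimum Calpha distance is computed with allele 1
#' on the first subunit and allele 2 on the second *and* vice versa, and
#' the overall minimum is returned, so the result is symmetric in the
#' two alleles by construction.
#'
#' @param spec1,spec2 mutation specification strings of the two alleles.
#' @param config one of `"monomer"`, `"stacked"`, `"backed"`.
#' @param model a `"chi_structure"`.
#' @param topo a `"chi_topology"` (required for dimer configurations).
#' @param monomer_subunit subunit used for the monomer configuration
#'   (default: first subunit of the model).
#' @return Distance in Angstrom, or `NA` if either allele has no
#'   resolved residue on a required subunit.
#' @export
pair_distance <- function(spec1, spec2,
                          config = c("monomer", "stacked", "backed"),
                          model, topo = NULL,
                          monomer_subunit = names(model)[1]) {
  config <- match.arg(config)
  if (config == "monomer") {
    m1 <- map_allele_residues(spec1, model, monomer_subunit)
    m2 <- map_allele_residues(spec2, model, monomer_subunit)
    if (!m1$usable || !m2$usable) return(NA_real_)
    return(min_ca_distance(m1$coords, m2$coords))
  }
  if (is.null(topo)) {
    stop("dimer configurations need a filament topology", call. = FALSE)
  }
  pairs <- if (config == "stacked") topo$stacked_pairs else topo$backed_pairs
  if (!length(pairs)) {
    stop("no declared ", config, " subunit pairs", call. = FALSE)
  }
  best <- Inf
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1]
    v <- pairs[r, 2]
    for (orient in 1:2) {
      s1 <- if (orient == 1L) u else v
      s2 <- if (orient == 1L) v else u
      m1 <- map_allele_residues(spec1, model, s1)
      m2 <- map_allele_residues(spec2, model, s2)
      if (m1$usable && m2$usable) {
        best <- min(best, min_ca_distance(m1$coords, m2$coords))
      }
    }
  }
  if (is.infinite(best)) NA_real_ else best
}

#' Pairwise allele table: profile similarity and structural distances
#'
#' For every unordered pair of usable alleles, the uncentered Pearson
#' similarity of their weighted interaction profiles together with the
#' monomer, stacked and backed minimum Calpha distances. Alleles with no
#' resolved residue are excluded and listed.
#'
#' @param ann annotation data frame (`allele_id`, `mutation_spec`).
#' @param w weight-reversed interaction matrix whose rows cover the
#'   annotated alleles.
#' @param model a `"chi_structure"` filament model.
#' @param topo a `"chi_topology"`.
#' @param monomer_subunit see [pair_distance()].
#' @return A list of class `"chi_pair_table"` with `pairs` (data frame:
#'   `allele_a`, `allele_b`, `similarity`, `d_monomer`, `d_stacked`,
#'   `d_backed`) and `excluded` (unusable allele ids).
#' @export
distance_table <- function(ann, w, model, topo,
                           monomer_subunit = names(model)[1]) {
  usable <- vapply(ann$mutation_spec, function(s) {
    map_allele_residues(s, model, monomer_subunit)$usable
  }, logical(1))
  excluded <- ann$allele_id[!usable]
  ann <- ann[usable, , drop = FALSE]
  if (nrow(ann) < 3L) {
    stop("need at least 3 usable alleles", call. = FALSE)
  }
  missing_rows <- setdiff(ann$allele_id, rownames(w))
  if (length(missing_rows)) {
    stop("alleles absent from the weighted matrix: ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  }
  a <- unclass(w)[ann$allele_id, , drop = FALSE]
  sim <- row_similarity(a)
  combs <- utils::combn(nrow(ann), 2)
  pairs <- data.frame(
    allele_a = ann$allele_id[combs[1, ]],
    allele_b = ann$allele_id[combs[2, ]],
    similarity = sim[t(combs)],
    stringsAsFactors = FALSE)

  # resolve every allele's coordinates on every subunit once
  coords <- lapply(names(model), function(su) {
    lapply(ann$mutation_spec, function(s) {
      mp <- map_allele_residues(s, model, su)
      if (mp$usable) mp$coords else NULL
    })
  })
  names(coords) <- names(model)
  min_or_na <- function(c1, c2) {
    if (is.null(c1) || is.null(c2)) NA_real_ else min_ca_distance(c1, c2)
  }
  dimer_min <- function(i, j, subunit_pairs) {
    best <- Inf
    for (r in seq_len(nrow(subunit_pairs))) {
      u <- subunit_pairs[r, 1]
      v <- subunit_pairs[r, 2]
      d1 <- min_or_na(coords[[u]][[i]], coords[[v]][[j]])
      d2 <- min_or_na(coords[[v]][[i]], coords[[u]][[j]])
      best <- min(best, d1, d2, na.rm = TRUE)
    }
    if (is.infinite(best)) NA_real_ else best
  }
  np <- ncol(combs)
  d_mon <- d_stk <- d_bck <- numeric(np)
  for (p in seq_len(np)) {
    i <- combs[1, p]
    j <- combs[2, p]
    d_mon[p] <- min_or_na(coords[[monomer_subunit]][[i]],
                          coords[[monomer_subunit]][[j]])
    d_stk[p] <- dimer_min(i, j, topo$stacked_pairs)
    d_bck[p] <- dimer_min(i, j, topo$backed_pairs)
  }
  pairs$d_monomer <- d_mon
  pairs$d_stacked <- d_stk
  pairs$d_backed <- d_bck
  structure(list(pairs = pairs, excluded = excluded),
            class = "chi_pair_table")
}

#' @export
print.chi_pair_table <- function(x, ...) {
  cat(sprintf("pairwise allele table: %d pairs (%d alleles excluded)\n",
              nrow(x$pairs), length(x$excluded)))
  invisible(x)
}

#' Export per-residue interaction degrees for a molecular viewer
#'
#' Writes an attribute file assigning every mutated residue the
#' interaction degree of its allele, suitable for heat-map colouring of
#' a molecular surface. Format: one `attribute:` header block followed by
#' lines `"\t:<resnum>\t<value>"`.
#'
#' @param degrees degree table (`id`, `degree`) from [allele_degrees()].
#' @param ann annotation data frame covering the alleles in `degrees`.
#' @param path output path.
#' @param name attribute name written in the header.
#' @return Invisibly, the number of residue lines written.
#' @export
export_residue_attributes <- function(degrees, ann, path,
                                      name = "chiDegree") {
  ann <- ann[ann$allele_id %in% degrees$id, , drop = FALSE]
  subs <- if (nrow(ann)) allele_substitutions(ann) else
    data.frame(allele_id = character(), position = integer())
  if (anyDuplicated(subs$position)) {
    dup <- subs$position[duplicated(subs$position)][1]
    stop("residue ", dup, " is claimed by two alleles", call. = FALSE)
  }
  deg <- degrees$degree[match(subs$allele_id, degrees$id)]
  header <- c(sprintf("attribute: %s", name),
              "match mode: 1-to-1", "recipient: residues")
  lines <- sprintf("\t:%d\t%d", subs$position, deg)
  writeLines(c(header, lines), path)
  invisible(length(lines))
}
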