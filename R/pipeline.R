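#' Simulate a complete screen dataset to disk
#'
#' Generates a synthetic filament, planted interaction matrix, allele
#' annotations and replicate screens, and writes them in exactly the
#' formats the pipeline reads: `matrix.tsv`, `annotations.tsv`,
#' `filament.pdb`, `topology.tsv`, `replicates/replicate_<i>.tsv`, an
#' extra independent screen `independent.tsv`, and `truth.tsv` (planted
#' cluster labels, for evaluation only).
#'
#' @param dir output directory (created if needed).
#' @param cfg a [synthetic_config()].
#' @param seed RNG seed; everything written is a pure function of
#'   `(cfg, seed)`.
#' @return Invisibly, a named list of the paths written.
#' @export
simulate_screen <- function(dir, cfg = synthetic_config(), seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_dir <- file.path(dir, "replicates")
  dir.create(rep_dir, showWarnings = FALSE)

  fil <- generate_filament(cfg, seed = seed)
  planted <- plant_alleles_and_matrix(fil, seed = seed + 1L)
  reps <- generate_replicates(planted$truth, cfg, seed = seed + 2L)
  indep <- generate_replicates(planted$truth, cfg, seed = seed + 3L, n = 1L)

  paths <- list(
    matrix = file.path(dir, "matrix.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    pdb = file.path(dir, "filament.pdb"),
    topology = file.path(dir, "topology.tsv"),
    replicates = file.path(rep_dir,
                           sprintf("replicate_%d.tsv",
                                   seq_along(reps$replicates))),
    independent = file.path(dir, "independent.tsv"),
    truth = file.path(dir, "truth.tsv"))

  write_chi_matrix(planted$matrix, paths$matrix)
  write_annotations(planted$annotations, paths$annotations)
  write_structure_pdb(fil$model, paths$pdb)
  write_topology(fil$topology, paths$topology)
  for (i in seq_along(reps$replicates)) {
    write_pairs(reps$replicates[[i]], paths$replicates[i])
  }
  write_pairs(indep$replicates[[1]], paths$independent)
  utils::write.table(
    data.frame(allele_id = names(planted$truth$allele_cluster),
               cluster = planted$truth$allele_cluster),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Run the CHI analysis pipeline end to end
#'
#' Reads an interaction matrix, allele annotations, a filament model and
#' topology, and replicate screens; produces degree tables, the
#' replicate-based validation report, two-way clustering with
#' TreeView-compatible export, the pairwise similarity/distance table,
#' similarity-distance correlations for all three configurations, the
#' surface-region rank-sum comparison, a residue attribute file and a
#' key-value summary. Every stochastic step uses `seed`, so two runs
#' with identical inputs and seed produce byte-identical outputs.
#'
#' @param matrix_path,annotations_path,pdb_path,topology_path input file
#'   paths (formats as written by [simulate_screen()]).
#' @param replicate_paths character vector of replicate edge-list files
#'   (>= 2) used to build the gold standard.
#' @param independent_path edge list of the independent screen evaluated
#'   against the standard (excluded from standard construction).
#' @param out_dir output directory.
#' @param k_clusters clusters to extract from the allele dendrogram.
#' @param n_perm Mantel permutations.
#' @param seed RNG seed for the permutation tests.
#' @param min_support replicate support needed for the gold standard.
#' @return Invisibly, a list with all computed objects (`degrees`,
#'   `validation`, `clustering`, `allele_clusters`, `pair_table`,
#'   `mantel`, `regions`, `rank_sum`, `summary_path`).
#' @export
run_chi_pipeline <- function(matrix_path, annotations_path, pdb_path,
                             topology_path, replicate_paths,
                             independent_path, out_dir,
                             k_clusters = 9L, n_perm = 10000L, seed,
                             min_support = 2L) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  m <- stage("read matrix", read_chi_matrix(matrix_path))
  ann <- stage("read annotations", read_annotations(annotations_path))
  model <- stage("read structure", read_pdb_calpha(pdb_path))
  topo <- stage("read topology", read_topology(topology_path, model = model))

  deg <- stage("degrees", allele_degrees(m))
  utils::write.table(deg, file.path(out_dir, "allele_degrees.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hist <- stage("degree histogram", gene_degree_histogram(m))
  utils::write.table(hist, file.path(out_dir, "gene_degree_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pheno <- stage("phenotype summary", phenotype_class_summary(deg, ann))
  utils::write.table(pheno, file.path(out_dir, "phenotype_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  reps <- stage("read replicates",
                read_replicates(replicate_paths, min_support = min_support))
  standard <- stage("gold standard", build_standard(reps))
  indep <- stage("read independent screen",
                 utils::read.delim(independent_path,
                                   stringsAsFactors = FALSE))
  val <- stage("precision/recall", precision_recall(indep, standard))
  write_pairs(standard, file.path(out_dir, "standard.tsv"))

  w <- reverse_weights(m)
  tw <- stage("two-way clustering", suppressWarnings(two_way_cluster(w)))
  stage("treeview export",
        write_cdt_gtr_atr(tw, file.path(out_dir, "clustered.cdt"),
                          file.path(out_dir, "clustered.gtr"),
                          file.path(out_dir, "clustered.atr")))
  clusters <- stage("cluster extraction", cut_clusters(tw$rows, k_clusters))
  utils::write.table(
    data.frame(allele_id = names(clusters), cluster = unname(clusters)),
    file.path(out_dir, "allele_clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  pt <- stage("distance table", distance_table(ann, w, model, topo))
  utils::write.table(
    cbind(pt$pairs[1:2],
          lapply(pt$pairs[3:6], function(x) sprintf("%.6f", x))),
    file.path(out_dir, "pairwise_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  mantel <- lapply(c(stacked = "stacked", monomer = "monomer",
                     backed = "backed"), function(cfg_name) {
    stage(paste0("mantel ", cfg_name),
          similarity_distance_correlation(pt, config = cfg_name,
                                          n_perm = n_perm, seed = seed))
  })
  mantel_df <- do.call(rbind, lapply(mantel, function(x) {
    data.frame(config = x$config, n_pairs = x$n_pairs,
               r = sprintf("%.6f", x$r),
               p_analytic = sprintf("%.6g", x$p_analytic),
               p_permutation = sprintf("%.6g", x$p_permutation))
  }))
  utils::write.table(mantel_df, file.path(out_dir, "mantel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  grp <- stage("region groups", region_groups(ann))
  rs <- if (length(grp$front_top_bottom) && length(grp$back_side)) {
    stage("rank-sum test", rank_sum_test(
      deg$degree[match(grp$front_top_bottom, deg$id)],
      deg$degree[match(grp$back_side, deg$id)]))
  } else NULL

  stage("residue attributes",
        export_residue_attributes(deg, ann,
                                  file.path(out_dir, "residue_degrees.txt")))

  summary_path <- file.path(out_dir, "summary.txt")
  lines <- c(
    sprintf("n_alleles\t%d", nrow(m)),
    sprintf("n_genes\t%d", ncol(m)),
    sprintf("n_interactions\t%d", sum(unclass(m) > 0L)),
    sprintf("mean_allele_degree\t%.4f", mean(deg$degree)),
    sprintf("n_noninteracting_genes\t%d", sum(colSums(unclass(m) > 0L) == 0L)),
    sprintf("precision\t%.6f", val$precision),
    sprintf("recall\t%.6f", val$recall),
    sprintf("n_standard\t%d", val$n_standard),
    sprintf("k_clusters\t%d", k_clusters),
    sprintf("mantel_stacked_r\t%.6f", mantel$stacked$r),
    sprintf("mantel_stacked_p_permutation\t%.6g",
            mantel$stacked$p_permutation),
    sprintf("mantel_monomer_p_permutation\t%.6g",
            mantel$monomer$p_permutation),
    sprintf("mantel_backed_p_permutation\t%.6g",
            mantel$backed$p_permutation),
    if (!is.null(rs)) sprintf("ranksum_p\t%.6g", rs$p),
    if (!is.null(rs)) sprintf("median_front_top_bottom\t%.4g", rs$median_a),
    if (!is.null(rs)) sprintf("median_back_side\t%.4g", rs$median_b),
    sprintf("n_perm\t%d", as.integer(n_perm)),
    sprintf("seed\t%d", as.integer(seed)))
  writeLines(lines, summary_path)

  invisible(list(matrix = m, annotations = ann, degrees = deg,
                 phenotype_summary = pheno, validation = val,
                 clustering = tw, allele_clusters = clusters,
                 pair_table = pt, mantel = mantel, regions = grp,
                 rank_sum = rs, summary_path = summary_path))
}
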