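test_that("PDB Calpha parsing keeps CA atoms, chains and first altlocs", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, 10, "A", 1, 2, 3),
               pdb_line(2, 10, "A", 0, 0, 0, elety = "CB"),
               pdb_line(3, 11, "A", 4, 5, 6),
               pdb_line(4, 12, "A", 7, 8, 9),
               pdb_line(5, 10, "B", -1, -2, -3),
               "END"), path)
  model <- read_pdb_calpha(path)
  expect_named(model, c("A", "B"))
  expect_equal(nrow(model$A), 3L)
  expect_equal(unname(model$A["10", ]), c(1, 2, 3))

  only_a <- read_pdb_calpha(path, chains = "A")
  expect_named(only_a, "A")

  # first altloc wins
  writeLines(c(pdb_line(1, 5, "A", 1, 1, 1, alt = "A"),
               pdb_line(2, 5, "A", 9, 9, 9, alt = "B"),
               "END"), path)
  m2 <- read_pdb_calpha(path)
  expect_equal(unname(m2$A["5", ]), c(1, 1, 1))

  writeLines(c(pdb_line(1, 5, "A", 1, 1, 1, elety = "CB"), "END"), path)
  expect_error(read_pdb_calpha(path), "no Calpha")
})

test_that("a synthetic filament survives the PDB round trip to 1e-3 A", {
  cfg <- small_synth_config(residues_per_subunit = 150L)
  fil <- generate_filament(cfg, seed = 41)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(fil$model, path)
  back <- read_pdb_calpha(path)
  expect_named(back, names(fil$model))
  for (ch in names(back)) {
    expect_equal(unname(back[[ch]]), unname(fil$model[[ch]]),
                 tolerance = 2e-3)
  }
})

test_that("minimum Calpha distance equals exhaustive search", {
  expect_equal(min_ca_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  shared <- rbind(c(1, 1, 1))
  expect_equal(min_ca_distance(rbind(shared, c(9, 9, 9)), shared), 0)

  set.seed(43)
  for (i in 1:50) {
    a <- matrix(rnorm(15), ncol = 3)
    b <- matrix(rnorm(21), ncol = 3)
    oracle <- Inf
    for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b))) {
      oracle <- min(oracle, sqrt(sum((a[p, ] - b[q, ])^2)))
    }
    expect_equal(min_ca_distance(a, b), oracle, tolerance = 1e-12)
  }
  expect_error(min_ca_distance(a[0, , drop = FALSE], b), "empty")
})

test_that("alleles map to resolved residues or are flagged unusable", {
  model <- structure(list(A = matrix(1:9, 3, 3,
                                     dimnames = list(c("363", "364", "100"),
                                                     c("x", "y", "z")))),
                    class = "chi_structure")
  full <- map_allele_residues("D363A,E364A", model, "A")
  expect_true(full$usable)
  expect_equal(nrow(full$coords), 2L)

  none <- map_allele_residues("D2A", model, "A")
  expect_false(none$usable)
  expect_equal(none$unresolved, 2L)

  part <- map_allele_residues("D363A,K999A", model, "A")
  expect_true(part$usable)
  expect_equal(part$unresolved, 999L)

  expect_error(map_allele_residues("D2A", model, "Z"), "unknown subunit")
})

test_that("dimer distances minimise over declared pairs and orientations", {
  cfg <- small_synth_config()
  fil <- generate_filament(cfg, seed = 47)
  planted <- plant_alleles_and_matrix(fil, seed = 48)
  ann <- planted$annotations
  model <- fil$model
  topo <- fil$topology

  s1 <- ann$mutation_spec[1]
  s2 <- ann$mutation_spec[2]
  expect_equal(pair_distance(s1, s2, "stacked", model, topo),
               pair_distance(s2, s1, "stacked", model, topo))
  expect_equal(pair_distance(s1, s1, "monomer", model), 0)

  # brute-force oracle over every declared pair and both orientations
  for (cfg_name in c("stacked", "backed")) {
    pairs <- if (cfg_name == "stacked") topo$stacked_pairs else
      topo$backed_pairs
    oracle <- Inf
    for (r in seq_len(nrow(pairs))) {
      for (o in 1:2) {
        su <- if (o == 1) pairs[r, ] else rev(pairs[r, ])
        c1 <- map_allele_residues(s1, model, su[1])$coords
        c2 <- map_allele_residues(s2, model, su[2])$coords
        oracle <- min(oracle, min_ca_distance(c1, c2))
      }
    }
    expect_equal(pair_distance(s1, s2, cfg_name, model, topo), oracle,
                 tolerance = 1e-12)
  }

  expect_error(pair_distance(s1, s2, "stacked", model), "topology")
  empty_topo <- filament_topology(topo$stacked_pairs[0, , drop = FALSE],
                                  topo$backed_pairs)
  expect_error(pair_distance(s1, s2, "stacked", model, empty_topo),
               "no declared")
})

test_that("the pairwise table is complete, symmetric-by-construction and consistent", {
  cfg <- small_synth_config()
  fil <- generate_filament(cfg, seed = 51)
  planted <- plant_alleles_and_matrix(fil, seed = 52)
  ann <- planted$annotations[1:4, ]
  w <- reverse_weights(planted$matrix)
  pt <- distance_table(ann, w, fil$model, fil$topology)
  expect_equal(nrow(pt$pairs), 6L)
  expect_length(pt$excluded, 0L)

  # similarity column equals the clustering module's uncentered Pearson
  a <- unclass(w)[ann$allele_id, ]
  for (p in seq_len(nrow(pt$pairs))) {
    expect_equal(pt$pairs$similarity[p],
                 uncentered_pearson(a[pt$pairs$allele_a[p], ],
                                    a[pt$pairs$allele_b[p], ]),
                 tolerance = 1e-12)
  }

  # an allele with no resolved residues is excluded and listed
  ann2 <- planted$annotations[1:5, ]
  ann2$mutation_spec[5] <- "D9999A"
  pt2 <- distance_table(ann2, w, fil$model, fil$topology)
  expect_equal(pt2$excluded, ann2$allele_id[5])
  expect_equal(nrow(pt2$pairs), 6L)

  expect_error(distance_table(ann[1:2, ], w, fil$model, fil$topology),
               "at least 3")
})

test_that("distances are invariant under rigid-body motion", {
  cfg <- small_synth_config()
  fil <- generate_filament(cfg, seed = 53)
  planted <- plant_alleles_and_matrix(fil, seed = 54)
  s1 <- planted$annotations$mutation_spec[1]
  s2 <- planted$annotations$mutation_spec[5]

  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  shift <- c(11, -7, 3.5)
  moved <- fil$model
  for (ch in names(moved)) {
    moved[[ch]] <- sweep(moved[[ch]] %*% t(rot), 2, -shift)
  }
  for (cf in c("monomer", "stacked", "backed")) {
    d0 <- pair_distance(s1, s2, cf, fil$model, fil$topology)
    d1 <- pair_distance(s1, s2, cf, moved, fil$topology)
    expect_equal(d0, d1, tolerance = 1e-9)
  }
})

test_that("opposite-pole interface patches are stacked-close but monomer-far", {
  # the geometric premise behind interpreting a profile cluster as a
  # filament contact: a patch at the top interface pole and its contact
  # patch on the stacked neighbour's bottom pole are nearly touching in
  # the stacked dimer yet nearly a subunit diameter apart in the monomer
  cfg <- synthetic_config()
  fil <- generate_filament(cfg, seed = 55)
  model <- fil$model
  a <- model$A
  ctr_a <- colMeans(a)
  ctr_c <- colMeans(model$C)
  axis <- (ctr_c - ctr_a) / sqrt(sum((ctr_c - ctr_a)^2))
  proj <- as.vector((a - matrix(ctr_a, nrow(a), 3, byrow = TRUE)) %*% axis)
  top <- a[order(-proj)[1:4], , drop = FALSE]
  bottom_c <- model$C[order(as.vector(
    (model$C - matrix(ctr_c, nrow(model$C), 3, byrow = TRUE)) %*% axis))[1:4],
    , drop = FALSE]
  # same residues on the single subunit A
  bottom_a <- a[rownames(bottom_c), , drop = FALSE]

  d_monomer <- min_ca_distance(top, bottom_a)
  d_stacked <- min_ca_distance(top, bottom_c)
  expect_lt(d_stacked, d_monomer)
  expect_lte(d_monomer, 2 * cfg$subunit_radius)
})

test_that("residue attribute export writes one line per substitution", {
  ann <- act1_alleles()
  deg <- data.frame(id = ann$allele_id, degree = ann$interactions)
  path <- withr::local_tempfile(fileext = ".txt")
  n <- export_residue_attributes(deg, ann, path)
  expect_equal(n, 66L)
  lines <- readLines(path)
  expect_match(lines[1], "^attribute: ")
  expect_true(all(grepl("^\t:\\d+\t\\d+$", lines[-(1:3)])))
  # act1-105 (degree 113) covers residues 311 and 312
  expect_true(all(c("\t:311\t113", "\t:312\t113") %in% lines))

  empty <- export_residue_attributes(deg[0, ], ann[0, ], path)
  expect_equal(empty, 0L)
  expect_length(readLines(path), 3L)

  dup <- ann[1:2, ]
  dup$mutation_spec[2] <- "D363A"  # claims a residue of allele 1
  expect_error(export_residue_attributes(deg[1:2, ], dup, path), "claimed")
})
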