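test_that("filament geometry follows the declared helix", {
  cfg <- synthetic_config()
  fil <- generate_filament(cfg, seed = 81)
  centres <- t(sapply(fil$model, colMeans))
  gaps <- sqrt(rowSums(diff(centres)^2))
  expected <- sqrt(cfg$rise_per_subunit^2 +
                     (2 * cfg$helix_radius *
                        sin(abs(cfg$twist_per_subunit) * pi / 360))^2)
  # residue-sampling noise shifts the centroids slightly off the helix
  expect_true(all(abs(gaps - expected) < 4))

  # screw symmetry: internal geometry identical in every subunit
  ref <- dist(fil$model$A[1:20, ])
  for (ch in names(fil$model)[-1]) {
    expect_equal(as.vector(dist(fil$model[[ch]][1:20, ])), as.vector(ref),
                 tolerance = 1e-9)
  }

  # stacked partners share strand parity, backed partners never do
  parity <- setNames(seq_along(fil$model) %% 2, names(fil$model))
  st <- fil$topology$stacked_pairs
  bk <- fil$topology$backed_pairs
  expect_true(all(parity[st[, 1]] == parity[st[, 2]]))
  expect_true(all(parity[bk[, 1]] != parity[bk[, 2]]))

  expect_error(generate_filament(synthetic_config(n_subunits = 2), seed = 1),
               "at least 3")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_synth_config()
  f1 <- generate_filament(cfg, seed = 83)
  f2 <- generate_filament(cfg, seed = 83)
  expect_identical(f1$model, f2$model)

  p1 <- plant_alleles_and_matrix(f1, seed = 84)
  p2 <- plant_alleles_and_matrix(f2, seed = 84)
  expect_identical(unclass(p1$matrix), unclass(p2$matrix))
  expect_identical(p1$truth$allele_positions, p2$truth$allele_positions)

  r1 <- generate_replicates(p1$truth, cfg, seed = 85)
  r2 <- generate_replicates(p2$truth, cfg, seed = 85)
  expect_identical(r1$replicates, r2$replicates)

  f3 <- generate_filament(cfg, seed = 99)
  expect_false(identical(f1$model, f3$model))
})

test_that("the noise-free limit reproduces the planted truth exactly", {
  cfg <- small_synth_config(p_signal = 1, p_background = 0)
  fil <- generate_filament(cfg, seed = 87)
  planted <- plant_alleles_and_matrix(fil, seed = 88)
  m <- unclass(planted$matrix)
  truth <- planted$truth
  for (i in rownames(m)) {
    genes_hit <- colnames(m)[m[i, ] > 0]
    expect_setequal(genes_hit, truth$cluster_genes[[truth$allele_cluster[i]]])
  }
})

test_that("edge counts and severity draws match their planted rates", {
  cfg <- synthetic_config()
  fil <- generate_filament(cfg, seed = 89)
  planted <- plant_alleles_and_matrix(fil, seed = 90)
  m <- unclass(planted$matrix)

  n_cluster_cells <- cfg$n_alleles * cfg$genes_per_cluster
  n_bg_cells <- cfg$n_alleles * cfg$n_genes - n_cluster_cells
  expected <- n_cluster_cells * cfg$p_signal + n_bg_cells * cfg$p_background
  sd_bound <- sqrt(n_cluster_cells * cfg$p_signal * (1 - cfg$p_signal) +
                     n_bg_cells * cfg$p_background * (1 - cfg$p_background))
  observed <- sum(m > 0)
  expect_lt(abs(observed - expected), 2.58 * sd_bound + 1)

  # severity histogram within 99% binomial bounds per class
  sev <- m[m > 0]
  for (s in 1:3) {
    bounds <- qbinom(c(0.005, 0.995), length(sev), cfg$severity_weights[s])
    expect_gte(sum(sev == s), bounds[1])
    expect_lte(sum(sev == s), bounds[2])
  }
})

test_that("planted annotations are well-formed and collision-free", {
  cfg <- synthetic_config()
  fil <- generate_filament(cfg, seed = 91)
  planted <- plant_alleles_and_matrix(fil, seed = 92)
  ann <- planted$annotations
  subs <- allele_substitutions(ann)
  # one residue at each interface pole per allele
  expect_equal(nrow(subs), 2L * cfg$n_alleles)
  # no residue claimed by two alleles
  expect_false(anyDuplicated(subs$position) > 0)
  # specs agree with the recorded truth
  for (i in seq_len(nrow(ann))) {
    expect_equal(sort(subs$position[subs$allele_id == ann$allele_id[i]]),
                 planted$truth$allele_positions[[ann$allele_id[i]]])
  }
  expect_true(all(ann$location %in%
                    c("front", "back", "side", "top/bottom")))
})

test_that("replicate generation obeys its limiting cases", {
  cfg <- small_synth_config(detection_prob = 1, replicate_fp_rate = 0)
  fil <- generate_filament(cfg, seed = 93)
  planted <- plant_alleles_and_matrix(fil, seed = 94)
  truth_keys <- paste(planted$truth$edges$allele, planted$truth$edges$gene)
  reps <- generate_replicates(planted$truth, cfg, seed = 95)
  for (r in reps$replicates) {
    expect_setequal(paste(r$allele, r$gene), truth_keys)
  }

  cfg0 <- small_synth_config(detection_prob = 0, replicate_fp_rate = 0)
  reps0 <- generate_replicates(planted$truth, cfg0, seed = 96)
  expect_true(all(vapply(reps0$replicates, nrow, integer(1)) == 0L))
})

test_that("replicate precision and recall match closed-form expectations", {
  cfg <- synthetic_config()
  q <- cfg$detection_prob
  fil <- generate_filament(cfg, seed = 97)
  planted <- plant_alleles_and_matrix(fil, seed = 98)
  reps <- generate_replicates(planted$truth, cfg, seed = 99)
  std <- build_standard(reps)
  indep <- generate_replicates(planted$truth, cfg, seed = 100, n = 1)
  v <- precision_recall(indep$replicates[[1]], std)

  truth_keys <- paste(planted$truth$edges$allele, planted$truth$edges$gene)
  std_keys <- paste(std$allele, std$gene)
  called_keys <- paste(indep$replicates[[1]]$allele,
                       indep$replicates[[1]]$gene)

  # recall: every true pair in the standard is re-detected with
  # probability q, independently of how the standard was built
  n_std_true <- sum(std_keys %in% truth_keys)
  overlap_true <- sum(called_keys %in% intersect(std_keys, truth_keys))
  bounds <- qbinom(c(0.005, 0.995), n_std_true, q)
  expect_gte(overlap_true, bounds[1])
  expect_lte(overlap_true, bounds[2])

  # precision: a called true pair is in the >=2-of-4 standard with
  # probability P2 = 1 - (1-q)^4 - 4 q (1-q)^3
  p2 <- 1 - (1 - q)^4 - 4 * q * (1 - q)^3
  n_called_true <- sum(called_keys %in% truth_keys)
  bounds2 <- qbinom(c(0.005, 0.995), n_called_true, p2)
  expect_gte(overlap_true, bounds2[1])
  expect_lte(overlap_true, bounds2[2])

  # and the headline numbers land near the planted rates
  expect_equal(v$recall, q * p2 * length(truth_keys) / v$n_standard,
               tolerance = 0.12)
})
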