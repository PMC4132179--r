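# small builders shared across test files

tiny_matrix <- function() {
  chi_matrix(matrix(c(1L, 0L, 0L, 0L, 2L, 3L), nrow = 2, byrow = TRUE,
                    dimnames = list(c("a1", "a2"), c("g1", "g2", "g3"))))
}

random_chi_matrix <- function(n_alleles, n_genes, density = 0.3) {
  m <- matrix(sample(0:3, n_alleles * n_genes, replace = TRUE,
                     prob = c(1 - density, density / 3, density / 3,
                              density / 3)),
              n_alleles, n_genes,
              dimnames = list(sprintf("a%02d", seq_len(n_alleles)),
                              sprintf("g%02d", seq_len(n_genes))))
  chi_matrix(m)
}

# symmetric distance matrix with distinct entries (no UPGMA ties)
random_dist_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 10)
  d <- d + t(d)
  dimnames(d) <- list(letters[seq_len(n)], letters[seq_len(n)])
  d
}

# a minimal PDB file as text lines
pdb_line <- function(serial, resno, chain, x, y, z, elety = "CA",
                     alt = " ", insert = " ") {
  sprintf("ATOM  %5d  %-3s%sGLY %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, elety, alt, chain, resno, insert, x, y, z)
}

small_synth_config <- function(...) {
  synthetic_config(n_alleles = 16L, n_genes = 80L, k_clusters = 4L,
                   genes_per_cluster = 15L, n_subunits = 5L, ...)
}
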