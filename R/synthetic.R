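#' Configuration for the synthetic screen generator
#'
#' Defaults emulate the study conditions of an actin alanine-scan CHI
#' screen: 32 query alleles against 238 genes, nine planted allele
#' clusters, and an idealised two-start helical filament with
#' actin-like geometry (rise 27.5 A and twist -166.7 degrees per
#' subunit, ~30 A subunit radius) so that distance scales resemble the
#' real system.
#'
#' @param n_alleles,n_genes matrix dimensions.
#' @param k_clusters number of planted allele clusters.
#' @param genes_per_cluster size of each cluster-specific gene set.
#' @param p_signal probability that a cluster allele hits a cluster gene.
#' @param p_background off-cluster (false positive) hit probability.
#' @param severity_weights probabilities of severity scores 1, 2, 3 for
#'   a hit (1 = lethal is the rarest call in a typical screen; mild
#'   defects dominate).
#' @param n_subunits number of filament subunits (>= 3).
#' @param rise_per_subunit axial rise per subunit, Angstrom.
#' @param twist_per_subunit rotation per subunit, degrees.
#' @param helix_radius radius of the subunit-centre helix, Angstrom.
#' @param subunit_radius radius of the spherical subunit, Angstrom.
#' @param residues_per_subunit number of residues per subunit.
#' @param patch_radius capture radius around an interface anchor within
#'   which an allele's mutated residue is drawn, Angstrom. Small values
#'   keep planted contacts tight.
#' @param residues_per_site mutated residues per interface site; every
#'   allele occupies one site at each subunit pole, so it carries
#'   `2 * residues_per_site` substitutions (alanine-scan alleles
#'   substitute small charge clusters, typically 2).
#' @param detection_prob per-replicate probability that a true
#'   interaction is called.
#' @param replicate_fp_rate per-replicate probability that a non-pair is
#'   spuriously called.
#' @param n_replicates replicates used to build the gold standard.
#' @return A list of class `"chi_synth_config"`.
#' @export
synthetic_config <- function(n_alleles = 32L, n_genes = 238L,
                             k_clusters = 9L, genes_per_cluster = 22L,
                             p_signal = 0.8, p_background = 0.02,
                             severity_weights = c(0.25, 0.35, 0.40),
                             n_subunits = 7L, rise_per_subunit = 27.5,
                             twist_per_subunit = -166.7,
                             helix_radius = 30, subunit_radius = 30,
                             residues_per_subunit = 375L,
                             patch_radius = 4,
                             residues_per_site = 1L,
                             detection_prob = 0.7,
                             replicate_fp_rate = 0.002,
                             n_replicates = 4L) {
  cfg <- list(n_alleles = as.integer(n_alleles), n_genes = as.integer(n_genes),
              k_clusters = as.integer(k_clusters),
              genes_per_cluster = as.integer(genes_per_cluster),
              p_signal = p_signal, p_background = p_background,
              severity_weights = severity_weights / sum(severity_weights),
              n_subunits = as.integer(n_subunits),
              rise_per_subunit = rise_per_subunit,
              twist_per_subunit = twist_per_subunit,
              helix_radius = helix_radius, subunit_radius = subunit_radius,
              residues_per_subunit = as.integer(residues_per_subunit),
              patch_radius = patch_radius,
              residues_per_site = as.integer(residues_per_site),
              detection_prob = detection_prob,
              replicate_fp_rate = replicate_fp_rate,
              n_replicates = as.integer(n_replicates))
  stopifnot(cfg$k_clusters <= cfg$n_alleles,
            cfg$genes_per_cluster * cfg$k_clusters <= cfg$n_genes,
            cfg$rise_per_subunit > 0,
            all(c(cfg$p_signal, cfg$p_background, cfg$detection_prob,
                  cfg$replicate_fp_rate) >= 0),
            all(c(cfg$p_signal, cfg$p_background, cfg$detection_prob,
                  cfg$replicate_fp_rate) <= 1))
  class(cfg) <- "chi_synth_config"
  cfg
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' Generate an idealised helical filament
#'
#' Subunit k (k = 0, 1, ...) is centred on a helix at angle `k * twist`
#' and height `k * rise`; every subunit carries the same local residue
#' layout (points on a sphere of `subunit_radius`, mostly uniform but
#' enriched on the two stacked-interface bands where subunit-contact
#' residues concentrate), rotated with the subunit, so the filament has
#' exact screw symmetry.
#' In a two-start helix consecutive subunits alternate strands:
#' intrastrand ("stacked") neighbours are (k, k+2) and interstrand
#' ("backed") neighbours are (k, k+1).
#'
#' @param cfg a [synthetic_config()].
#' @param seed RNG seed; the same seed gives bitwise-identical
#'   coordinates.
#' @return A list with `model` (a `"chi_structure"`, subunits named
#'   A, B, ...), `topology` (a `"chi_topology"`) and `geometry`
#'   (internal layout used by [plant_alleles_and_matrix()]).
#' @export
generate_filament <- function(cfg, seed) {
  stopifnot(inherits(cfg, "chi_synth_config"))
  if (cfg$n_subunits < 3L) {
    stop("need at least 3 subunits", call. = FALSE)
  }
  n <- cfg$n_subunits
  c0_pre <- c(cfg$helix_radius, 0, 0)
  local <- with_local_seed(seed, {
    # surface layout: mostly uniform on the sphere, but enriched at the
    # two stacked-interface bands (the rings facing the intrastrand
    # neighbours), as a protein's subunit-contact surfaces are where
    # interface residues concentrate
    n_band <- min(60L, cfg$residues_per_subunit %/% 6L)
    n_unif <- cfg$residues_per_subunit - 2L * n_band
    z <- stats::runif(n_unif, -1, 1)
    phi <- stats::runif(n_unif, 0, 2 * pi)
    r_xy <- sqrt(1 - z^2)
    unif <- cfg$subunit_radius *
      cbind(x = r_xy * cos(phi), y = r_xy * sin(phi), z = z)
    # top interface band: polar angle 15-25 degrees off the direction of
    # the stacked neighbour above
    g2 <- drop(rot_z(2 * cfg$twist_per_subunit) %*% c0_pre) +
      c(0, 0, 2 * cfg$rise_per_subunit)
    u <- g2 - c0_pre
    u <- u / sqrt(sum(u^2))
    e1 <- c(-u[2], u[1], 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    ca <- stats::runif(n_band, cos(25 * pi / 180), cos(15 * pi / 180))
    ph <- stats::runif(n_band, 0, 2 * pi)
    sa <- sqrt(1 - ca^2)
    top_band <- cfg$subunit_radius *
      (outer(ca, u) + outer(sa * cos(ph), e1) + outer(sa * sin(ph), e2))
    # bottom interface band: the exact stacked-contact partners of a
    # matching draw on the top ring
    ca2 <- stats::runif(n_band, cos(25 * pi / 180), cos(15 * pi / 180))
    ph2 <- stats::runif(n_band, 0, 2 * pi)
    sa2 <- sqrt(1 - ca2^2)
    top_like <- cfg$subunit_radius *
      (outer(ca2, u) + outer(sa2 * cos(ph2), e1) + outer(sa2 * sin(ph2), e2))
    bottom_band <- t(apply(top_like, 1, function(p) {
      stacked_partner_local(c0_pre + p, cfg, c0_pre)
    }))
    out <- rbind(unif, top_band, bottom_band)
    colnames(out) <- c("x", "y", "z")
    out
  })
  rownames(local) <- seq_len(cfg$residues_per_subunit)

  c0 <- c(cfg$helix_radius, 0, 0)
  subunits <- lapply(seq_len(n) - 1L, function(k) {
    g <- t(rot_z(k * cfg$twist_per_subunit) %*% t(sweep(local, 2, -c0)))
    g[, 3] <- g[, 3] + k * cfg$rise_per_subunit
    dimnames(g) <- dimnames(local)
    g
  })
  ids <- LETTERS[seq_len(n)]
  names(subunits) <- ids
  model <- structure(subunits, class = "chi_structure")

  stacked <- cbind(ids[seq_len(n - 2L)], ids[seq_len(n - 2L) + 2L])
  backed <- cbind(ids[seq_len(n - 1L)], ids[seq_len(n - 1L) + 1L])
  topo <- filament_topology(stacked, backed, model = model)

  geometry <- list(local = local, c0 = c0, cfg = cfg)
  list(model = model, topology = topo, geometry = geometry)
}

# local coordinates (subunit 0 frame) of the residue-layout point that,
# in the stacked partner two subunits up, coincides with global point g
stacked_partner_local <- function(g, cfg, c0) {
  p <- drop(rot_z(-2 * cfg$twist_per_subunit) %*%
              (g - c(0, 0, 2 * cfg$rise_per_subunit))) - c0
  p / sqrt(sum(p^2)) * cfg$subunit_radius
}

#' Plant allele clusters and draw an interaction matrix
#'
#' Alleles are assigned round-robin to `k_clusters` clusters and every
#' allele mutates one residue site near each pole of the subunit: one
#' on the ring facing the intrastrand (stacked) neighbour above, one on
#' the ring facing the neighbour below. Within a cluster the alleles
#' form a *chain of stacked contacts*: the top site of allele j is
#' placed at an interface azimuth whose exact contact point on the
#' stacked neighbour's bottom ring becomes the bottom site of allele
#' j+1. Consecutive cluster members therefore touch across the stacked
#' interface (small stacked distance), while all remaining azimuths are
#' independent and uniform, so for every other pair -- same cluster or
#' not -- the monomer, stacked and backed distances are draws from one
#' and the same distribution. The spatial signal is thereby planted
#' exclusively in the stacked configuration; monomer and backed
#' distances are distribution-identical between within-cluster and
#' cross-cluster pairs by construction, not by numerical cancellation.
#'
#' Interaction scores are drawn independently per cell: a cluster allele
#' hits a gene of its own cluster set with probability `p_signal` and
#' any other gene with `p_background`; severity is sampled from
#' `severity_weights`.
#'
#' @param filament output of [generate_filament()].
#' @param seed RNG seed.
#' @return A list with `matrix` (a [chi_matrix()]), `annotations` (a
#'   `"chi_annotation"` data frame) and `truth` (planted cluster labels,
#'   cluster gene sets, allele residue positions and the true
#'   interaction edge list).
#' @export
plant_alleles_and_matrix <- function(filament, seed) {
  cfg <- filament$geometry$cfg
  local <- filament$geometry$local
  c0 <- filament$geometry$c0
  k <- cfg$k_clusters

  with_local_seed(seed, {
    # direction from subunit 0 towards its stacked partner, in local coords
    g2 <- drop(rot_z(2 * cfg$twist_per_subunit) %*% c0) +
      c(0, 0, 2 * cfg$rise_per_subunit)
    u <- g2 - c0
    u <- u / sqrt(sum(u^2))
    e1 <- c(-u[2], u[1], 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    top_point <- function(alpha, phi) {
      cfg$subunit_radius *
        (cos(alpha) * u + sin(alpha) * (cos(phi) * e1 + sin(phi) * e2))
    }

    cluster_alleles <- split(seq_len(cfg$n_alleles),
                             rep_len(seq_len(k), cfg$n_alleles))
    allele_ids <- sprintf("allele%02d", seq_len(cfg$n_alleles))
    gene_ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
    allele_cluster <- integer(cfg$n_alleles)
    allele_top <- vector("list", cfg$n_alleles)
    allele_bottom <- vector("list", cfg$n_alleles)
    claimed <- integer(0)  # residues already assigned to some allele

    # residues within patch_radius of an anchor, not yet claimed
    pool_at <- function(anchor) {
      setdiff(which(sqrt(colSums((t(local) - anchor)^2)) <=
                      cfg$patch_radius), claimed)
    }
    draw_site <- function(anchor) {
      pool <- pool_at(anchor)
      if (length(pool) < cfg$residues_per_site) return(NULL)
      sort(pool[sample.int(length(pool), cfg$residues_per_site)])
    }

    for (c_i in seq_len(k)) {
      members <- cluster_alleles[[c_i]]
      m <- length(members)
      # contact azimuths chain members j and j+1; the free ends get
      # independent azimuths
      for (j in seq_len(m)) {
        i <- members[j]
        placed <- FALSE
        for (try in seq_len(200L)) {
          alpha <- stats::runif(1, 17, 23) * pi / 180
          phi <- stats::runif(1, 0, 2 * pi)
          t_anchor <- top_point(alpha, phi)
          b_anchor <- stacked_partner_local(c0 + t_anchor, cfg, c0)
          top_site <- draw_site(t_anchor)
          if (is.null(top_site)) next
          if (j < m) {
            # this azimuth is a contact: the partner's bottom site must
            # also be available before we commit
            claimed_before <- claimed
            claimed <- c(claimed, top_site)
            bottom_next <- draw_site(b_anchor)
            if (is.null(bottom_next)) {
              claimed <- claimed_before
              next
            }
            claimed <- c(claimed, bottom_next)
            allele_top[[i]] <- top_site
            allele_bottom[[members[j + 1]]] <- bottom_next
          } else {
            claimed <- c(claimed, top_site)
            allele_top[[i]] <- top_site
          }
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place an interface site for cluster ", c_i,
               "; increase patch_radius or residues_per_subunit",
               call. = FALSE)
        }
        allele_cluster[i] <- c_i
      }
      # free bottom end of the chain's first member
      i1 <- members[1]
      placed <- FALSE
      for (try in seq_len(200L)) {
        alpha <- stats::runif(1, 17, 23) * pi / 180
        phi <- stats::runif(1, 0, 2 * pi)
        b_anchor <- stacked_partner_local(c0 + top_point(alpha, phi), cfg, c0)
        bottom_site <- draw_site(b_anchor)
        if (!is.null(bottom_site)) {
          claimed <- c(claimed, bottom_site)
          allele_bottom[[i1]] <- bottom_site
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place an interface site for cluster ", c_i,
             "; increase patch_radius or residues_per_subunit",
             call. = FALSE)
      }
    }
    allele_positions <- lapply(seq_len(cfg$n_alleles), function(i) {
      sort(c(allele_top[[i]], allele_bottom[[i]]))
    })

    # synthesized mutation specs: charged wild-type residues to alanine
    specs <- vapply(allele_positions, function(pos) {
      wt <- sample(c("D", "E", "K", "R"), length(pos), replace = TRUE)
      paste0(wt, pos, "A", collapse = ",")
    }, character(1))

    location <- vapply(allele_positions, function(pos) {
      p <- colMeans(local[pos, , drop = FALSE])
      dz <- p[3] / cfg$subunit_radius
      if (abs(dz) >= 0.6) return("Top/bottom")
      out <- sum(p[1:2] * c0[1:2]) /
        (sqrt(sum(p[1:2]^2)) * sqrt(sum(c0[1:2]^2)))
      if (out >= 0.5) "Front" else if (out <= -0.5) "Back" else "Side"
    }, character(1))
    phenotype <- sample(c("Wild type", "Ts-, recessive",
                          "Cs-, Ts-, recessive", "Lethal, recessive",
                          "Lethal, partial dominant"),
                        cfg$n_alleles, replace = TRUE,
                        prob = c(0.25, 0.3, 0.2, 0.15, 0.1))

    cluster_genes <- split(gene_ids[seq_len(k * cfg$genes_per_cluster)],
                           rep(seq_len(k), each = cfg$genes_per_cluster))
    in_cluster <- matrix(FALSE, cfg$n_alleles, cfg$n_genes)
    for (i in seq_len(cfg$n_alleles)) {
      in_cluster[i, match(cluster_genes[[allele_cluster[i]]], gene_ids)] <- TRUE
    }
    p_hit <- ifelse(in_cluster, cfg$p_signal, cfg$p_background)
    hit <- matrix(stats::runif(length(p_hit)) < p_hit,
                  cfg$n_alleles, cfg$n_genes)
    sev <- matrix(sample(1:3, length(p_hit), replace = TRUE,
                         prob = cfg$severity_weights),
                  cfg$n_alleles, cfg$n_genes)
    score <- ifelse(hit, sev, 0L)
    dimnames(score) <- list(allele_ids, gene_ids)
    m <- chi_matrix(score)

    ann <- data.frame(allele_id = allele_ids, mutation_spec = specs,
                      phenotype = normalize_phenotype(phenotype),
                      location = normalize_location(location),
                      stringsAsFactors = FALSE)
    class(ann) <- c("chi_annotation", class(ann))

    names(allele_cluster) <- allele_ids
    names(allele_positions) <- allele_ids
    truth <- list(allele_cluster = allele_cluster,
                  allele_positions = allele_positions,
                  cluster_genes = cluster_genes,
                  edges = to_edge_list(m))
    list(matrix = m, annotations = ann, truth = truth)
  })
}

#' Generate replicate screens from a planted truth
#'
#' Each replicate calls every true interaction independently with
#' probability `detection_prob` and adds false positives over the
#' non-interacting cells with probability `replicate_fp_rate`.
#'
#' @param truth the `truth` element of [plant_alleles_and_matrix()] (its
#'   `edges` are the true pairs) together with the axes implied by it.
#' @param cfg a [synthetic_config()].
#' @param seed RNG seed.
#' @param n number of replicates (default `cfg$n_replicates`).
#' @return A [chi_replicates()] object with `min_support = 2`.
#' @export
generate_replicates <- function(truth, cfg, seed, n = cfg$n_replicates) {
  allele_ids <- names(truth$allele_cluster)
  gene_ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
  true_keys <- paste(truth$edges$allele, truth$edges$gene, sep = "\r")
  all_keys <- as.vector(outer(allele_ids, gene_ids, paste, sep = "\r"))
  non_keys <- setdiff(all_keys, true_keys)

  reps <- with_local_seed(seed, {
    lapply(seq_len(n), function(r) {
      hit <- true_keys[stats::runif(length(true_keys)) < cfg$detection_prob]
      fp <- non_keys[stats::runif(length(non_keys)) < cfg$replicate_fp_rate]
      keys_to_pairs(sort(c(hit, fp)))
    })
  })
  chi_replicates(reps, min_support = min(2L, n))
}

#' Write a structure model to a PDB file
#'
#' Emits one Calpha ATOM record per residue (glycine placeholders),
#' chains in subunit order, suitable for round-tripping through
#' [read_pdb_calpha()].
#'
#' @param model a `"chi_structure"`.
#' @param path output path.
#' @export
write_structure_pdb <- function(model, path) {
  xyz <- do.call(rbind, lapply(model, identity))
  n <- nrow(xyz)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    type = rep("ATOM", n),
    resno = unlist(lapply(model, function(s) as.integer(rownames(s)))),
    resid = rep("GLY", n),
    eleno = seq_len(n),
    elety = rep("CA", n),
    chain = rep(names(model), vapply(model, nrow, integer(1))))
  invisible(path)
}
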