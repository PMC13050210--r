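# Whole-genome meiosis simulator: the Monte-Carlo truth oracle for family
# means, variances and diversity experiments.
#
# Internal representation: a cohort of N individuals is a list of `ploidy`
# haplotype matrices (loci x N); column j across the list is individual j.
# Crossovers follow the Haldane model (independent recombination per adjacent
# interval); chromosome starts use c = 0.5 so each chromosome begins on a
# random homolog.

# One meiosis per column from a diploid pair of haplotypes.
# h1, h2: loci-vectors (fixed genotype) or loci x N matrices (per-column
# genotypes). Returns loci x N gamete matrix. The inner loop is compiled
# (src/meiosis.cpp) and draws from R's RNG.
meiosis_gametes <- function(h1, h2, cadj, n) {
  if (!is.matrix(h1)) h1 <- matrix(h1, ncol = 1)
  if (!is.matrix(h2)) h2 <- matrix(h2, ncol = 1)
  meiosis_gametes_cpp(h1, h2, cadj, n)
}

# Tetraploid meiosis: random bivalent pairing (3 pairings equally likely),
# one recombinant product per bivalent, gamete = 2 chromosomes.
# H: list of 4 haplotype vectors or matrices. Returns list of 2 matrices.
tetra_gametes <- function(H, cadj, n) {
  pc <- sample.int(3L, n, replace = TRUE)  # pairing: 1|2+3|4, 1|3+2|4, 1|4+2|3
  H <- lapply(H, function(h) if (is.matrix(h)) h else matrix(h, ncol = 1))
  tetra_gametes_cpp(H[[1]], H[[2]], H[[3]], H[[4]], cadj, pc)
}

# Haplotypes of one parent as a list of `ploidy` loci-vectors. Falls back to a
# uniformly random consistent phase (with a warning) for heterozygous parents
# without phased data.
parent_haplotypes <- function(panel, i) {
  phi <- panel$ploidy
  if (!is.null(panel$haplotypes)) {
    h <- panel$haplotypes[[i]]
    return(lapply(seq_len(phi), function(r) h[r, ]))
  }
  m <- panel$dosages[i, ]
  if (all(m %in% c(0, phi))) {
    hap <- m / phi
    return(rep(list(unname(hap)), phi))
  }
  warning(sprintf(
    "parent '%s' is heterozygous but unphased; using a random consistent phase",
    rownames(panel$dosages)[i]), call. = FALSE)
  nj <- panel$n_loci
  H <- matrix(0, phi, nj)
  for (j in seq_len(nj)) {
    if (m[j] > 0) H[sample.int(phi, m[j]), j] <- 1
  }
  lapply(seq_len(phi), function(r) H[r, ])
}

# Cohort of gametes from a cohort (or fixed parent): list of phi/2 matrices.
cohort_gametes <- function(ind, cadj, n, ploidy) {
  if (ploidy == 2) {
    list(meiosis_gametes(ind[[1]], ind[[2]], cadj, n))
  } else {
    tetra_gametes(ind, cadj, n)
  }
}

#' Simulate progeny of one cross under a breeding scheme
#'
#' Simulates whole-genome meioses with recombination fractions from the map's
#' Haldane distances (no interference), carrying each progeny lineage through
#' the scheme generation by generation: selfing chains simulate every
#' intermediate individual (single-seed descent), DH doubles one sampled F1
#' gamete, clonal evaluation returns the F1 itself, and testcross schemes mate
#' each end individual to the tester.
#'
#' Parents must be phased or fully homozygous (phase trivial); heterozygous
#' unphased parents get a uniformly random consistent phase with a warning.
#'
#' @param panel a [parent_panel()].
#' @param pair integer vector `c(k, l)` of parent indices.
#' @param scheme a [cross_scheme()]; a tester set must hold one tester here
#'   (loop and average externally for several).
#' @param n_progeny number of progeny lineages to simulate.
#' @param seed optional integer seed for reproducibility.
#' @param tester optional single tester index overriding `scheme$testers`.
#' @return `n_progeny x n_loci` dosage matrix of the evaluated generation,
#'   with the cohort haplotype list attached as attribute `"haplotypes"`.
#' @export
simulate_progeny <- function(panel, pair, scheme, n_progeny, seed = NULL,
                             tester = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phi <- panel$ploidy
  if (scheme$pipeline == "DH") assert_that(phi == 2, "DH requires ploidy 2")
  cadj <- adjacent_recomb(panel$map)
  n <- n_progeny
  hk <- parent_haplotypes(panel, pair[1])
  hl <- parent_haplotypes(panel, pair[2])
  ind <- c(cohort_gametes(hk, cadj, n, phi), cohort_gametes(hl, cadj, n, phi))
  if (scheme$pipeline == "SELF" && scheme$t > 0) {
    for (g in seq_len(scheme$t)) {
      ind <- c(cohort_gametes(ind, cadj, n, phi),
               cohort_gametes(ind, cadj, n, phi))
    }
  } else if (scheme$pipeline == "DH") {
    gam <- meiosis_gametes(ind[[1]], ind[[2]], cadj, n)
    ind <- list(gam, gam)
  }
  tester <- tester %||% scheme$testers
  if (!is.null(tester)) {
    assert_that(length(tester) == 1,
                "simulate_progeny handles one tester at a time")
    ht <- parent_haplotypes(panel, tester)
    ind <- c(cohort_gametes(ind, cadj, n, phi),
             cohort_gametes(ht, cadj, n, phi))
  }
  dos <- t(Reduce(`+`, ind))
  colnames(dos) <- colnames(panel$dosages)
  attr(dos, "haplotypes") <- ind
  dos
}

#' Genotypic values from a dosage matrix
#'
#' g_i = sum_j m(M[i,j]) a_j + w(M[i,j]) d_j with class scores from `cvm`.
#'
#' @param dosages `n x n_loci` dosage matrix.
#' @param effects a [trait_effects()].
#' @param cvm a [class_value_map()]; the diploid default is used when NULL and
#'   `ploidy` is 2.
#' @param ploidy ploidy of the dosages (used only when `cvm` is NULL).
#' @return numeric vector of genotypic values.
#' @export
genotypic_value <- function(dosages, effects, cvm = NULL, ploidy = 2) {
  if (is.null(cvm)) cvm <- default_cvm(ploidy)
  M <- matrix(cvm$additive[dosages + 1], nrow(dosages))
  W <- matrix(cvm$dominance[dosages + 1], nrow(dosages))
  drop(M %*% effects$additive + W %*% effects$dominance)
}
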