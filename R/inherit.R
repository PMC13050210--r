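# Per-locus gamete and genotype-class probability engines.
#
# All distributions are plain numeric probability vectors: a gamete
# distribution has length ploidy/2 + 1 (gamete dosage 0..phi/2), a genotype
# distribution length ploidy + 1 (dosage 0..phi). Matrix variants put loci in
# columns so whole-genome pipelines stay vectorized.

#' Gamete dosage distribution of one parent at one locus
#'
#' Diploids transmit the effect allele with probability dosage/2. For
#' autotetraploids the gamete receives 2 of the 4 homologous chromosomes at
#' random (random bivalent pairing, polysomic inheritance, no double
#' reduction), i.e. a hypergeometric draw:
#' P(g = k) = C(m, k) C(phi - m, phi/2 - k) / C(phi, phi/2).
#'
#' @param dosage parental dosage, integer in 0..ploidy.
#' @param ploidy 2 or 4.
#' @return numeric vector of length ploidy/2 + 1 over gamete dosages.
#' @examples
#' gamete_dist(1, 2)   # (1/2, 1/2)
#' gamete_dist(2, 4)   # (1/6, 4/6, 1/6)
#' @export
gamete_dist <- function(dosage, ploidy = 2) {
  assert_that(is_count(dosage, 0) && dosage <= ploidy,
              sprintf("dosage must be an integer in 0..%d", ploidy))
  g <- ploidy / 2
  k <- 0:g
  p <- choose(dosage, k) * choose(ploidy - dosage, g - k) / choose(ploidy, g)
  p / sum(p)
}

# Gamete distributions for a vector of dosages: (phi/2 + 1) x n matrix.
gamete_dist_matrix <- function(dosages, ploidy) {
  g <- ploidy / 2
  lut <- vapply(0:ploidy, gamete_dist, numeric(g + 1), ploidy = ploidy)
  lut[, dosages + 1, drop = FALSE]
}

# Convolve two distributions given as (len) vectors or (len x n) matrices.
convolve_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  la <- nrow(a); lb <- nrow(b)
  out <- matrix(0, la + lb - 1, ncol(a))
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1)
    out[idx, ] <- out[idx, ] + b * rep(a[i, ], each = lb)
  }
  out
}

#' F1 genotype-class distribution from two gamete distributions
#'
#' @param gk,gl gamete distributions (vectors over 0..phi/2) of the two
#'   parents; may be matrices with loci in columns.
#' @return distribution over offspring dosage 0..phi (vector, or matrix with
#'   loci in columns).
#' @export
f1_locus_dist <- function(gk, gl) {
  out <- convolve_dist(gk, gl)
  if (is.null(dim(gk)) && is.null(dim(gl))) drop(out) else out
}

# Selfing transition matrix: class k -> conv(gamete(k), gamete(k)).
# Columns index the parent class, rows the offspring class.
selfing_transition <- function(ploidy) {
  vapply(0:ploidy, function(k) {
    g <- gamete_dist(k, ploidy)
    drop(convolve_dist(g, g))
  }, numeric(ploidy + 1))
}

#' Selfing recursion on a genotype-class distribution
#'
#' Applies `t` generations of selfing: each dosage class is selfed through its
#' own gamete distribution and the results are mixed by class frequency
#' (a Markov recursion on dosage classes).
#'
#' @param dist distribution over 0..phi (vector, or matrix loci-in-columns).
#' @param t number of selfing generations, integer >= 0.
#' @param ploidy 2 or 4.
#' @return distribution of the same shape.
#' @export
self_locus_dist <- function(dist, t, ploidy = 2) {
  assert_that(is_count(t, 0), "t must be a non-negative integer")
  if (t == 0) return(dist)
  Tm <- selfing_transition(ploidy)
  out <- as.matrix(dist)
  for (i in seq_len(t)) out <- Tm %*% out
  if (is.null(dim(dist))) drop(out) else out
}

#' Doubled-haploid distribution from an F1 class distribution
#'
#' Pools gametes over F1 classes and doubles them; mass lands on dosages 0 and
#' phi only. Diploids only.
#'
#' @param f1 distribution over 0..2 (vector or matrix loci-in-columns).
#' @return distribution with support {0, 2}.
#' @export
dh_locus_dist <- function(f1) {
  f1m <- as.matrix(f1)
  assert_that(nrow(f1m) == 3, "doubled haploids require ploidy 2")
  p1 <- unname(colSums(f1m * c(0, 0.5, 1)))  # pooled gamete allele probability
  out <- rbind(1 - p1, 0, p1, deparse.level = 0)
  if (is.null(dim(f1))) drop(out) else out
}

#' Testcross hybrid distribution
#'
#' Pools gametes over the family's dosage classes and convolves them with the
#' tester's gamete distribution.
#'
#' @param family distribution over 0..phi (vector or matrix loci-in-columns).
#' @param tester_dosage tester dosage(s), integer in 0..phi (recycled across
#'   loci when scalar).
#' @param ploidy 2 or 4.
#' @return hybrid distribution over 0..phi.
#' @export
testcross_locus_dist <- function(family, tester_dosage, ploidy = 2) {
  fm <- as.matrix(family)
  assert_that(nrow(fm) == ploidy + 1, "family distribution does not match ploidy")
  assert_that(all(tester_dosage >= 0 & tester_dosage <= ploidy &
                    tester_dosage == round(tester_dosage)),
              sprintf("tester dosage must be an integer in 0..%d", ploidy))
  glut <- gamete_dist_matrix(0:ploidy, ploidy)      # (g+1) x (phi+1)
  fam_gam <- glut %*% fm                            # pooled family gametes
  if (length(tester_dosage) == 1)
    tester_dosage <- rep(tester_dosage, ncol(fm))
  tg <- gamete_dist_matrix(tester_dosage, ploidy)
  out <- convolve_dist(fam_gam, tg)
  if (is.null(dim(family))) drop(out) else out
}

#' Per-locus genotype-class distributions for a family under a scheme
#'
#' Composes gamete formation, F1, and the scheme's pipeline (selfing chain,
#' doubled haploids, or clonal evaluation of the F1), then an optional
#' testcross, independently at every locus. Loci are treated marginally here;
#' cross-locus structure is the business of the LD variance models and the
#' meiosis simulator.
#'
#' @param panel a [parent_panel()].
#' @param pair integer vector `c(k, l)` of parent indices.
#' @param scheme a [cross_scheme()].
#' @param tester optional single tester index overriding `scheme$testers`
#'   (used when averaging over testers).
#' @return `(ploidy + 1) x n_loci` matrix of class probabilities; columns sum
#'   to 1.
#' @export
family_locus_dists <- function(panel, pair, scheme, tester = NULL) {
  phi <- panel$ploidy
  assert_that(length(pair) == 2 && all(pair >= 1 & pair <= panel$n_parents),
              "pair must hold two valid parent indices")
  if (scheme$pipeline == "DH") assert_that(phi == 2, "DH requires ploidy 2")
  gk <- gamete_dist_matrix(panel$dosages[pair[1], ], phi)
  gl <- gamete_dist_matrix(panel$dosages[pair[2], ], phi)
  d <- f1_locus_dist(gk, gl)
  d <- switch(scheme$pipeline,
              F1 = d,
              CLONE = d,
              SELF = self_locus_dist(d, scheme$t, phi),
              DH = dh_locus_dist(d))
  tester <- tester %||% scheme$testers
  if (!is.null(tester)) {
    assert_that(length(tester) == 1,
                "family_locus_dists handles one tester at a time")
    d <- testcross_locus_dist(d, panel$dosages[tester, ], phi)
  }
  colnames(d) <- colnames(panel$dosages)
  d
}
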