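# Diversity control: genomic relationships, the expected-sample-SD estimator,
# and the proportion of additive standard deviation lost (PropSD).
#
# The additive values of a set of parents are modeled as u ~ N(0, G sigma^2).
# The expected sample SD of u has a closed form via a gamma moment match of
# the sample variance; PropSD = 1 - E(s_selected)/E(s_pool) then estimates the
# proportion of additive SD a mating plan gives up, without marker effects
# (the variance-component scale cancels).

#' Genomic relationship matrix
#'
#' Ploidy-generalized VanRaden construction: Z = M - ploidy * p (columns
#' centered at ploidy times the pool allele frequency),
#' G = Z Z' / (ploidy * sum_j p_j (1 - p_j)).
#'
#' @param panel a [parent_panel()] (or a dosage matrix plus `ploidy`).
#' @param ploidy used when `panel` is a bare matrix.
#' @return `n x n` symmetric relationship matrix with parent dimnames.
#' @export
grm <- function(panel, ploidy = 2) {
  M <- if (inherits(panel, "parent_panel")) panel$dosages else as.matrix(panel)
  phi <- if (inherits(panel, "parent_panel")) panel$ploidy else ploidy
  assert_that(nrow(M) >= 2, "GRM needs at least 2 parents")
  p <- colMeans(M) / phi
  poly <- p > 0 & p < 1
  assert_that(any(poly), "all loci are monomorphic")
  Z <- sweep(M[, poly, drop = FALSE], 2, phi * p[poly])
  tcrossprod(Z) / (phi * sum(p[poly] * (1 - p[poly])))
}

#' Expected sample standard deviation of additive values
#'
#' For u ~ N(0, G), the sample variance s^2 has mean
#' E(s^2) = [tr(G)/n - 1'G1/n^2] n/(n-1) and variance
#' var(s^2) = 1' Sigma2 1 / (n-1)^2 with
#' Sigma2 = 2 (Sigma1 o Sigma1), Sigma1[i,j] = G[i,j] + SEM^2 - rowmean_i -
#' rowmean_j, SEM = sqrt(1'G1)/n. Matching a gamma distribution
#' (alpha = E(s^2)^2 / var(s^2), beta = var(s^2)/E(s^2)) gives
#' E(s) = sqrt(beta) Gamma(alpha + 1/2) / Gamma(alpha). With G = I this is
#' exactly the classical c4(n) constant.
#'
#' @param G relationship (covariance-scale) matrix, n >= 2.
#' @return list of class `sd_estimate` with `expected_sd`, `alpha`, `beta`,
#'   `mean_s2`, `var_s2`, `sem`, and the audit matrices `sigma1`, `sigma2`.
#' @export
expected_sample_sd <- function(G) {
  G <- as.matrix(G)
  n <- nrow(G)
  assert_that(n >= 2 && ncol(G) == n, "G must be square with n >= 2")
  g1 <- sum(G)
  sem <- sqrt(max(g1, 0)) / n
  rm <- rowMeans(G)
  sigma1 <- G + sem^2 - outer(rm, rep(1, n)) - outer(rep(1, n), rm)
  sigma2 <- 2 * sigma1^2
  mean_s2 <- (sum(diag(G)) / n - g1 / n^2) * n / (n - 1)
  var_s2 <- sum(sigma2) / (n - 1)^2
  if (mean_s2 <= 0) {
    est <- 0; alpha <- NA_real_; beta <- NA_real_
  } else if (var_s2 <= 0) {
    est <- sqrt(mean_s2); alpha <- NA_real_; beta <- NA_real_
  } else {
    alpha <- mean_s2^2 / var_s2
    beta <- var_s2 / mean_s2
    est <- if (alpha > 1e7) {
      sqrt(mean_s2)  # gamma ratio overflows; degenerate limit
    } else {
      sqrt(beta) * exp(lgamma(alpha + 0.5) - lgamma(alpha))
    }
  }
  structure(list(expected_sd = est, alpha = alpha, beta = beta,
                 mean_s2 = mean_s2, var_s2 = var_s2, sem = sem,
                 sigma1 = sigma1, sigma2 = sigma2),
            class = "sd_estimate")
}

#' @export
print.sd_estimate <- function(x, ...) {
  cat(sprintf("<sd_estimate> E(s) = %.6g  (E(s^2) = %.6g, var(s^2) = %.6g, SEM = %.6g)\n",
              x$expected_sd, x$mean_s2, x$var_s2, x$sem))
  invisible(x)
}

#' Proportion of additive standard deviation lost
#'
#' PropSD = 1 - E(s_m)/E(s), comparing the expected additive sample SD of the
#' selected parents (submatrix G_m) with that of the whole pool. `selected`
#' is a multiset: with `weighting = "contribution"` (default) a parent
#' repeated across matings is duplicated once per mating; `"unique"` keeps
#' each selected parent once.
#'
#' @param G_pool relationship matrix of the parental pool.
#' @param selected integer indices of selected parents (repeats allowed).
#' @param weighting `"contribution"` or `"unique"`.
#' @return numeric in (-Inf, 1]; 1 (complete loss) when fewer than 2 entries
#'   remain.
#' @export
prop_sd <- function(G_pool, selected, weighting = c("contribution", "unique")) {
  weighting <- match.arg(weighting)
  assert_that(length(selected) >= 1, "selected set must be non-empty")
  assert_that(all(selected >= 1 & selected <= nrow(G_pool)),
              "selected indices out of range")
  if (weighting == "unique") selected <- unique(selected)
  if (length(selected) < 2) return(1)
  e_pool <- expected_sample_sd(G_pool)$expected_sd
  e_sel <- expected_sample_sd(G_pool[selected, selected, drop = FALSE])$expected_sd
  1 - e_sel / e_pool
}

#' Realized loss of additive variability
#'
#' 1 - sd(u_selected)/sd(u_pool) on realized additive values (sample SDs).
#'
#' @param u_pool,u_sel numeric vectors of additive values (length >= 2).
#' @return numeric scalar (negative when the selection increases the SD).
#' @export
realized_prop_sd <- function(u_pool, u_sel) {
  assert_that(length(u_pool) >= 2 && length(u_sel) >= 2,
              "need at least 2 values in pool and selection")
  sp <- sd(u_pool)
  assert_that(sp > 0, "pool additive values have zero variance")
  1 - sd(u_sel) / sp
}

#' Genic additive standard deviation (LD-free)
#'
#' sqrt(sum_j a_j^2 var_j) with var_j the per-locus dosage (sample) variance
#' across the subset; ignores all cross-locus covariances.
#'
#' @param dosages dosage matrix of the subset (individuals x loci).
#' @param effects a [trait_effects()] (additive part used).
#' @return numeric scalar.
#' @export
genic_sd <- function(dosages, effects) {
  assert_that(nrow(dosages) >= 2, "need at least 2 individuals")
  v <- apply(dosages, 2, var)
  sqrt(sum(effects$additive^2 * v))
}

#' Genetic additive standard deviation (includes LD)
#'
#' Sample SD of the per-individual additive values sum_j M[i, j] a_j.
#'
#' @inheritParams genic_sd
#' @return numeric scalar.
#' @export
genetic_sd <- function(dosages, effects) {
  assert_that(nrow(dosages) >= 2, "need at least 2 individuals")
  sd(drop(dosages %*% effects$additive))
}

#' Write / read a GRM as TSV
#'
#' @param G relationship matrix with dimnames.
#' @param path output path.
#' @return `write_grm` the path invisibly; `read_grm` the matrix.
#' @export
write_grm <- function(G, path) {
  utils::write.table(data.frame(parent = rownames(G), G, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  tab <- read_table_auto(path)
  G <- as.matrix(tab[, -1, drop = FALSE])
  rownames(G) <- as.character(tab[[1]])
  G
}
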