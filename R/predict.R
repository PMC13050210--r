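# Family mean, within-family variance under three LD models, and the
# usefulness criterion.
#
# Per-locus means/variances come exactly from the genotype-class distributions
# of the evaluated generation (inherit.R). Cross-locus structure enters only
# through a correlation matrix C_F of genotypic effects:
#   independent: C_F = I
#   approx:      C_F propagated from unphased source-population covariances
#   full:        C_F propagated from phased parental haplotypes
# Propagation runs a two-locus association recursion on the pair
# (P, Q) = (within-homolog, cross-homolog) association, elementwise in the
# recombination-fraction matrix:
#   diploid meiosis:    P' = (1-c) P + c Q         Q' = (P + Q) / 2
#   tetraploid meiosis: P' = (1-c) P + (c/3) Q     Q' = P/2 + (5/6) Q
# The dosage covariance of a generation is P + Q; doubled haploids replace
# both P and Q by (1-c) P + c Q (a doubled gamete); the covariance of the
# gametes a generation transmits (testcross stage) is
#   diploid:    (1-c)/2 P + (c/2) Q
#   tetraploid: (1-c)/2 P + (1+c)/6 Q

# ---------------------------------------------------------------------------
# per-locus summaries

# Vectorized per-locus moments under class distributions D ((phi+1) x nj).
locus_stats <- function(D, effects, cvm) {
  va <- cvm$additive; w <- cvm$dominance
  a <- effects$additive; d <- effects$dominance
  A1 <- colSums(D * va); A2 <- colSums(D * va^2)
  W1 <- colSums(D * w);  W2 <- colSums(D * w^2)
  AW <- colSums(D * (va * w))
  mu <- A1 * a + W1 * d
  var_a <- pmax(a^2 * (A2 - A1^2), 0)
  var_d <- pmax(d^2 * (W2 - W1^2), 0)
  cov_ad <- a * d * (AW - A1 * W1)
  var_tot <- pmax(var_a + var_d + 2 * cov_ad, 0)
  sd_a <- sqrt(var_a); sd_d <- sqrt(var_d)
  rho <- ifelse(sd_a * sd_d > 0, cov_ad / (sd_a * sd_d), 0)
  rho <- pmin(pmax(rho, -1), 1)
  list(mu = mu, var_tot = var_tot, var_a = var_a, var_d = var_d,
       sd_a = sd_a, sd_d = sd_d, rho = rho)
}

#' Per-locus family mean
#'
#' mu_F,j = sum_k P(k) (m(k) a_j + w(k) d_j): the arithmetic mean of the class
#' values under the family's genotype-class distribution.
#'
#' @param dist probability vector over dosage classes 0..phi.
#' @param a_j,d_j additive and dominance effect at the locus.
#' @param cvm a [class_value_map()] (diploid default when NULL).
#' @return numeric scalar.
#' @export
locus_mean <- function(dist, a_j, d_j = 0, cvm = NULL) {
  if (is.null(cvm)) cvm <- default_cvm(length(dist) - 1)
  sum(dist * (cvm$additive * a_j + cvm$dominance * d_j))
}

#' Per-locus within-family variance
#'
#' Population variance of the class values under the family's genotype-class
#' distribution; `component` zeroes the other effect to isolate the additive
#' or dominance part.
#'
#' @inheritParams locus_mean
#' @param component `"total"`, `"additive_only"`, or `"dominance_only"`.
#' @return numeric scalar.
#' @export
locus_variance <- function(dist, a_j, d_j = 0, cvm = NULL,
                           component = c("total", "additive_only", "dominance_only")) {
  component <- match.arg(component)
  if (is.null(cvm)) cvm <- default_cvm(length(dist) - 1)
  if (component == "additive_only") d_j <- 0
  if (component == "dominance_only") a_j <- 0
  v <- cvm$additive * a_j + cvm$dominance * d_j
  sum(dist * v^2) - sum(dist * v)^2
}

#' Per-locus additive/dominance decomposition
#'
#' Splits the per-locus variance into additive and dominance parts and their
#' correlation: cov = (sigma^2 - sigma_a^2 - sigma_d^2)/2,
#' rho = cov/(sigma_a sigma_d), with rho := 0 for a degenerate denominator.
#'
#' @inheritParams locus_mean
#' @return one-row tibble with `mean`, `total_var`, `additive_var`,
#'   `dominance_var`, `ad_correlation`.
#' @export
locus_ad_decomposition <- function(dist, a_j, d_j = 0, cvm = NULL) {
  if (is.null(cvm)) cvm <- default_cvm(length(dist) - 1)
  st <- locus_stats(matrix(dist, ncol = 1),
                    trait_effects(a_j, d_j), cvm)
  tibble::tibble(mean = st$mu, total_var = st$var_tot,
                 additive_var = st$var_a, dominance_var = st$var_d,
                 ad_correlation = st$rho)
}

#' Expected genotypic value of a family
#'
#' Sums the per-locus means of the scheme's evaluated generation over the
#' genome.
#'
#' @param panel a [parent_panel()].
#' @param pair integer vector `c(k, l)` of parent indices.
#' @param scheme a [cross_scheme()]; multi-tester schemes are averaged over
#'   testers.
#' @param effects a [trait_effects()].
#' @param cvm a [class_value_map()] (diploid default when NULL).
#' @return numeric scalar.
#' @export
family_mean <- function(panel, pair, scheme, effects, cvm = NULL) {
  if (is.null(cvm)) cvm <- default_cvm(panel$ploidy)
  testers <- scheme$testers %||% NA
  mean(vapply(testers, function(tt) {
    D <- family_locus_dists(panel, pair, scheme,
                            tester = if (is.na(tt)) NULL else tt)
    sum(locus_stats(D, effects, cvm)$mu)
  }, numeric(1)))
}

#' Legacy F1 mean (population-frequency formula)
#'
#' The classical two-population F1 expectation
#' mu = a (p - q - y) + d (2 p q + y (p - q)). Exposed only as a comparator:
#' it does not reproduce the genotype-frequency expectation beyond its narrow
#' assumptions and is never used in prediction.
#'
#' @param p,q effect-allele frequencies in the two parental populations.
#' @param y frequency difference parameter of the classical formula.
#' @param a,d additive and dominance effects.
#' @return numeric scalar.
#' @export
falconer_f1_mean <- function(p, q, y, a, d) {
  a * (p - q - y) + d * (2 * p * q + y * (p - q))
}

# ---------------------------------------------------------------------------
# LD propagation

prop_step <- function(st, cmat, ploidy) {
  if (ploidy == 2) {
    list(P = (1 - cmat) * st$P + cmat * st$Q,
         Q = (st$P + st$Q) / 2)
  } else {
    list(P = (1 - cmat) * st$P + (cmat / 3) * st$Q,
         Q = st$P / 2 + (5 / 6) * st$Q)
  }
}

prop_dh <- function(st, cmat) {
  g <- (1 - cmat) * st$P + cmat * st$Q
  list(P = g, Q = g)
}

prop_gamete_cov <- function(st, cmat, ploidy) {
  if (ploidy == 2) {
    (1 - cmat) / 2 * st$P + cmat / 2 * st$Q
  } else {
    (1 - cmat) / 2 * st$P + (1 + cmat) / 6 * st$Q
  }
}

# Run a coefficient profile (P0, Q0) through the scheme; returns the final
# coefficient matrix for the dosage covariance (or transmitted-gamete
# covariance when the scheme ends in a testcross).
propagate_profile <- function(P0, Q0, cmat, scheme, ploidy) {
  st <- list(P = P0, Q = Q0)
  if (scheme$pipeline == "SELF" && scheme$t > 0) {
    for (i in seq_len(scheme$t)) st <- prop_step(st, cmat, ploidy)
  } else if (scheme$pipeline == "DH") {
    assert_that(ploidy == 2, "DH requires ploidy 2")
    st <- prop_dh(st, cmat)
  }
  if (!is.null(scheme$testers)) {
    prop_gamete_cov(st, cmat, ploidy)
  } else {
    st$P + st$Q
  }
}

#' Source-population covariance of per-locus genotypic effects
#'
#' Builds M*[i, j] = m(M[i, j]) a_j + w(M[i, j]) d_j for the members of one
#' subpopulation, centers columns, and returns t(Z) Z / n.
#'
#' @param panel a [parent_panel()].
#' @param pop subpopulation label (NULL uses the whole panel).
#' @param effects a [trait_effects()].
#' @param cvm a [class_value_map()] (diploid default when NULL).
#' @return `n_loci x n_loci` covariance matrix.
#' @export
source_pop_cov <- function(panel, pop = NULL, effects, cvm = NULL) {
  if (is.null(cvm)) cvm <- default_cvm(panel$ploidy)
  rows <- if (is.null(pop)) seq_len(panel$n_parents) else
    which(panel$subpop == pop)
  assert_that(length(rows) >= 2, "source population needs at least 2 members")
  pop_cov(panel$dosages[rows, , drop = FALSE], effects, cvm)
}

pop_cov <- function(M, effects, cvm) {
  Mstar <- sweep(matrix(cvm$additive[M + 1], nrow(M)), 2, effects$additive, "*") +
    sweep(matrix(cvm$dominance[M + 1], nrow(M)), 2, effects$dominance, "*")
  Z <- scale(Mstar, center = TRUE, scale = FALSE)
  crossprod(Z) / nrow(Z)
}

#' Propagate parental covariances to the family
#'
#' The unphased (approximate) LD model: the family covariance is obtained from
#' the two source-population covariance matrices by elementwise
#' recombination-dependent damping, initialized at the F1 as
#' Sigma_F = 1/2 (1 - 2c) (Sigma_k + Sigma_l) and carried through the scheme
#' by the two-locus association recursion described in the package vignette.
#'
#' @param sigma_k,sigma_l covariance matrices of the two source populations.
#' @param cmat recombination-fraction matrix (see [recombination_matrix()]).
#' @param scheme a [cross_scheme()].
#' @param ploidy 2 or 4.
#' @return `n_loci x n_loci` family covariance matrix.
#' @export
propagate_family_cov <- function(sigma_k, sigma_l, cmat, scheme, ploidy = 2) {
  assert_that(all(dim(sigma_k) == dim(sigma_l)) &&
                all(dim(sigma_k) == dim(cmat)),
              "covariance and recombination matrices must be conformable")
  K <- propagate_profile(0.5 * (1 - 2 * cmat), matrix(0, nrow(cmat), ncol(cmat)),
                         cmat, scheme, ploidy)
  K * (sigma_k + sigma_l)
}

#' Covariance to correlation
#'
#' C[i, j] = S[i, j] / sqrt(S[i, i] S[j, j]); rows/columns of zero-variance
#' loci are set to 0 off-diagonal with a unit diagonal (they contribute
#' nothing to the genome-wide variance).
#'
#' @param S square symmetric covariance matrix.
#' @param eps variances at or below this are treated as zero.
#' @return correlation matrix of the same shape.
#' @export
cov_to_corr <- function(S, eps = 1e-12) {
  d <- diag(S)
  inv <- ifelse(d > eps, 1 / sqrt(d), 0)
  C <- S * tcrossprod(inv)
  diag(C) <- 1
  C
}

#' Phased additive covariance of both parents
#'
#' Family allele frequencies are the average of the two parents' haplotype
#' means; each parent's haplotype rows are centered at those frequencies and
#' scaled by the additive effects: Sigma_a,k = t(Hk*) Hk* / ploidy. Dominance
#' never enters: phase carries purely additive information.
#'
#' @param Hk,Hl `ploidy x n_loci` 0/1 haplotype matrices.
#' @param effects a [trait_effects()].
#' @return list with `sigma_k`, `sigma_l`, and the family frequencies `p`.
#' @export
phased_additive_cov <- function(Hk, Hl, effects) {
  assert_that(is.matrix(Hk) && is.matrix(Hl) && all(dim(Hk) == dim(Hl)),
              "phased haplotype matrices must be conformable")
  p <- (colMeans(Hk) + colMeans(Hl)) / 2
  a <- effects$additive
  Hks <- sweep(Hk, 2, p) * rep(a, each = nrow(Hk))
  Hls <- sweep(Hl, 2, p) * rep(a, each = nrow(Hl))
  list(sigma_k = crossprod(Hks) / nrow(Hk),
       sigma_l = crossprod(Hls) / nrow(Hl),
       p = p)
}

# ---------------------------------------------------------------------------
# genome-wide variances

#' Genome-wide variance, independent-loci model
#'
#' @param var_tot vector of per-locus total variances.
#' @return numeric scalar: their sum.
#' @export
variance_independent <- function(var_tot) sum(var_tot)

#' Genome-wide variance, quadratic form in per-locus SDs
#'
#' Var(g_F) = s' C_F s with s the per-locus *standard deviations* (the
#' dimensionally consistent reading of the quadratic form) and C_F the
#' between-locus correlation of genotypic effects. Negative results are
#' clipped to 0 with a warning.
#'
#' @param sd_tot vector of per-locus total standard deviations.
#' @param CF between-locus correlation matrix.
#' @return numeric scalar.
#' @export
variance_approx <- function(sd_tot, CF) {
  assert_that(length(sd_tot) == nrow(CF), "dimension mismatch")
  v <- drop(crossprod(sd_tot, CF %*% sd_tot))
  if (v < 0) {
    warning("negative propagated variance clipped to 0")
    v <- 0
  }
  v
}

#' Genome-wide variance, full (phased) model with dominance paths
#'
#' Sums additive x additive, additive x dominance and dominance x dominance
#' covariance components through the additive correlation matrix `Ca` and the
#' per-locus additive-dominance correlations rho (path rule), with the
#' same-locus dominance term corrected so that a single-locus family reduces
#' exactly to the per-locus variance.
#'
#' @param sd_a,sd_d vectors of per-locus additive and dominance SDs.
#' @param rho vector of per-locus additive-dominance correlations.
#' @param Ca additive between-locus correlation matrix of the family.
#' @return numeric scalar.
#' @export
variance_full <- function(sd_a, sd_d, rho, Ca) {
  assert_that(length(sd_a) == nrow(Ca), "dimension mismatch")
  tau <- sd_a + rho * sd_d
  v <- drop(crossprod(tau, Ca %*% tau)) + sum(sd_d^2 * (1 - rho^2))
  if (v < 0) {
    warning("negative propagated variance clipped to 0")
    v <- 0
  }
  v
}

#' Usefulness criterion
#'
#' U_F = E(g_F) + i_F r sqrt(Var(g_F)) (standard-deviation convention;
#' `literal_var = TRUE` multiplies by the variance instead).
#'
#' @param mean family mean E(g_F).
#' @param variance within-family variance (>= 0).
#' @param i within-family selection intensity (see [selection_intensity()]).
#' @param r prediction accuracy in [0, 1].
#' @param literal_var use Var instead of SD.
#' @return numeric scalar.
#' @export
usefulness <- function(mean, variance, i, r = 1, literal_var = FALSE) {
  assert_that(all(variance >= 0), "variance must be non-negative")
  assert_that(all(r >= 0 & r <= 1), "accuracy must be in [0, 1]")
  mean + i * r * (if (literal_var) variance else sqrt(variance))
}

# ---------------------------------------------------------------------------
# fast per-pair engines

# Quadratic-form term: coefficient matrix K (lazy: shared across pairs) with
# low-rank factors; value(w) = sum_i s_i (w u_i)' K (w v_i).
quad_term <- function(K, U, V, signs) list(K = K, U = U, V = V, signs = signs)

eval_quad_terms <- function(terms, w) {
  tot <- 0
  for (tm in terms) {
    L <- tm$U * w   # columns are factors
    R <- tm$V * w
    tot <- tot + sum(tm$signs * colSums(L * (tm$K %*% R)))
  }
  tot
}

eval_diag_terms <- function(terms) {
  d <- 0
  for (tm in terms) {
    d <- d + drop((tm$U * tm$V) %*% tm$signs) * diag(tm$K)
  }
  d
}

# Dense reconstruction (small problems / tests).
dense_terms <- function(terms) {
  S <- 0
  for (tm in terms) {
    B <- 0
    for (i in seq_along(tm$signs))
      B <- B + tm$signs[i] * tcrossprod(tm$U[, i], tm$V[, i])
    S <- S + tm$K * B
  }
  S
}

# Coefficient matrices of the three phased basis types for one scheme.
# typeP: within-homolog association, typeQ: cross-homolog association within a
# parent, typeX: between-parent association. Derived by expanding the F1's
# homologs in terms of parental gametes (exact under the package's meiosis
# model); see the methods vignette.
full_profiles <- function(cmat, scheme, ploidy) {
  zero <- matrix(0, nrow(cmat), ncol(cmat))
  if (ploidy == 2) {
    list(P = propagate_profile((1 - cmat) / 2, zero, cmat, scheme, ploidy),
         Q = propagate_profile(cmat / 2, zero, cmat, scheme, ploidy),
         X = propagate_profile(zero, 0.25 + zero, cmat, scheme, ploidy))
  } else {
    list(P = propagate_profile((1 - cmat) / 2, zero, cmat, scheme, ploidy),
         Q = propagate_profile(cmat / 6, 1 / 6 + zero, cmat, scheme, ploidy),
         X = propagate_profile(zero, 0.25 + zero, cmat, scheme, ploidy))
  }
}

# Tester gamete-covariance coefficients (applied to the tester's own P/Q basis).
tester_profiles <- function(cmat, ploidy) {
  if (ploidy == 2) {
    list(P = (1 - cmat) / 2, Q = cmat / 2)
  } else {
    list(P = (1 - cmat) / 2, Q = (1 + cmat) / 6)
  }
}

# Quadratic-form terms of the family's additive cross-locus covariance under
# the full (phased) model for one pair (and optional tester).
full_cov_terms <- function(panel, pair, effects, profiles, tprofiles = NULL,
                           tester = NULL) {
  phi <- panel$ploidy
  hk <- parent_haplotypes(panel, pair[1])
  hl <- parent_haplotypes(panel, pair[2])
  p <- (panel$dosages[pair[1], ] + panel$dosages[pair[2], ]) / (2 * phi)
  a <- effects$additive
  Uk <- vapply(hk, function(h) (h - p) * a, numeric(panel$n_loci))
  Ul <- vapply(hl, function(h) (h - p) * a, numeric(panel$n_loci))
  sk <- rowSums(Uk); sl <- rowSums(Ul)
  rows <- cbind(Uk, Ul)
  terms <- list(
    quad_term(profiles$P, rows, rows, rep(1, 2 * phi)),
    quad_term(profiles$Q, cbind(sk, sl, rows), cbind(sk, sl, rows),
              c(1, 1, rep(-1, 2 * phi))),
    quad_term(profiles$X, cbind(sk, sl), cbind(sl, sk), c(1, 1))
  )
  if (!is.null(tester)) {
    ht <- parent_haplotypes(panel, tester)
    pt <- panel$dosages[tester, ] / phi
    Ut <- vapply(ht, function(h) (h - pt) * a, numeric(panel$n_loci))
    st <- rowSums(Ut)
    terms <- c(terms, list(
      quad_term(tprofiles$P, Ut, Ut, rep(1, phi)),
      quad_term(tprofiles$Q, cbind(st, Ut), cbind(st, Ut),
                c(1, rep(-1, phi)))
    ))
  }
  terms
}

# Family additive cross-locus covariance, dense (tests / small data).
family_cov_full <- function(panel, pair, scheme, effects, tester = NULL) {
  cmat <- recombination_matrix(panel$map)
  profiles <- full_profiles(cmat, scheme, panel$ploidy)
  tprofiles <- tester_profiles(cmat, panel$ploidy)
  tester <- tester %||% scheme$testers
  dense_terms(full_cov_terms(panel, pair, effects, profiles, tprofiles, tester))
}

# ---------------------------------------------------------------------------
# prediction driver

# Precomputed, pair-independent context for repeated predictions.
predict_context <- function(panel, scheme, effects, ld_model, cvm) {
  ctx <- new.env(parent = emptyenv())
  ctx$cvm <- cvm
  ctx$ld_model <- ld_model
  if (ld_model == "independent") return(ctx)
  ctx$cmat <- recombination_matrix(panel$map)
  if (ld_model == "full") {
    if (is.null(panel$haplotypes) &&
        !all(panel$dosages %in% c(0, panel$ploidy)))
      stop("full LD model requires phased haplotypes (or fully homozygous ",
           "parents); use ld_model = \"approx\"", call. = FALSE)
    ctx$profiles <- full_profiles(ctx$cmat, scheme, panel$ploidy)
    ctx$tprofiles <- tester_profiles(ctx$cmat, panel$ploidy)
  } else {
    pops <- panel$subpop %||% rep("pop", panel$n_parents)
    sig <- lapply(setNames(unique(pops), unique(pops)), function(pp) {
      rows <- which(pops == pp)
      if (length(rows) < 2) return(NULL)
      pop_cov(panel$dosages[rows, , drop = FALSE], effects, cvm)
    })
    ctx$pops <- pops
    ctx$pop_sigma <- sig
    ctx$approx_cache <- list()
  }
  ctx
}

# A = K * (Sigma_k + Sigma_l) for the approx model, cached per population pair.
approx_matrix <- function(ctx, panel, scheme, pop1, pop2) {
  key <- paste(sort(c(pop1, pop2)), collapse = "|")
  hit <- ctx$approx_cache[[key]]
  if (!is.null(hit)) return(hit)
  sk <- ctx$pop_sigma[[pop1]]; sl <- ctx$pop_sigma[[pop2]]
  assert_that(!is.null(sk) && !is.null(sl),
              "approx LD model needs >= 2 panel members per source population")
  A <- propagate_family_cov(sk, sl, ctx$cmat, scheme, panel$ploidy)
  dA <- diag(A)
  inv <- ifelse(dA > 1e-12, 1 / sqrt(dA), 0)
  res <- list(A = A, inv = inv)
  ctx$approx_cache[[key]] <- res
  res
}

# Mean, variance, usefulness of one pair under one scheme/tester.
predict_pair <- function(panel, pair, scheme, effects, ctx, tester = NULL) {
  D <- family_locus_dists(panel, pair, scheme, tester = tester)
  st <- locus_stats(D, effects, ctx$cvm)
  mu <- sum(st$mu)
  clipped <- FALSE
  if (ctx$ld_model == "independent") {
    v <- sum(st$var_tot)
  } else if (ctx$ld_model == "approx") {
    am <- approx_matrix(ctx, panel, scheme,
                        ctx$pops[pair[1]], ctx$pops[pair[2]])
    s <- sqrt(st$var_tot)
    w <- s * am$inv
    v <- drop(crossprod(w, am$A %*% w)) + sum(s[am$inv == 0]^2)
    # tester cross-locus LD is not represented at population level
  } else {
    terms <- full_cov_terms(panel, pair, effects, ctx$profiles,
                            ctx$tprofiles, tester)
    dvec <- eval_diag_terms(terms)
    tau <- st$sd_a + st$rho * st$sd_d
    ok <- dvec > 1e-12
    w <- ifelse(ok, tau / sqrt(pmax(dvec, 1e-300)), 0)
    v <- eval_quad_terms(terms, w) + sum(tau[!ok]^2) +
      sum(st$sd_d^2 * (1 - st$rho^2))
  }
  if (v < 0) { v <- 0; clipped <- TRUE }
  list(mean = mu, variance = v, clipped = clipped)
}

#' Predict all crosses of a panel
#'
#' One row per unordered parent pair (optionally restricted by `pairs` or a
#' mask): family mean, within-family variance under the chosen LD model, SD,
#' and usefulness. Multi-tester schemes average over testers. Negative
#' propagated variances are clipped at 0; the number of clips is attached as
#' attribute `"n_clipped"`.
#'
#' @param panel a [parent_panel()].
#' @param scheme a [cross_scheme()].
#' @param effects a [trait_effects()].
#' @param ld_model `"independent"`, `"approx"`, or `"full"` (full requires
#'   phased or fully homozygous parents).
#' @param pairs optional 2-column matrix of parent index pairs; default all
#'   unordered pairs (self-crosses excluded unless `allow_self`).
#' @param cvm a [class_value_map()] (diploid default when NULL).
#' @param selected_prop within-family selected proportion used for the
#'   selection intensity in the usefulness criterion.
#' @param allow_self include self-crosses when enumerating pairs.
#' @param literal_var usefulness uses Var instead of SD (see [usefulness()]).
#' @return tibble with columns `parent1`, `parent2`, `mean`, `variance`, `sd`,
#'   `usefulness`, `ld_model`, `scheme`.
#' @export
predict_all_crosses <- function(panel, scheme, effects,
                                ld_model = c("approx", "independent", "full"),
                                pairs = NULL, cvm = NULL,
                                selected_prop = 0.1, allow_self = FALSE,
                                literal_var = FALSE) {
  ld_model <- match.arg(ld_model)
  if (is.null(cvm)) cvm <- default_cvm(panel$ploidy)
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(panel$n_parents), diag = allow_self),
                 arr.ind = TRUE)
    pairs <- cbind(idx[, 1], idx[, 2])
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  ctx <- predict_context(panel, scheme, effects, ld_model, cvm)
  testers <- scheme$testers %||% NA
  iF <- selection_intensity(selected_prop)
  n_clip <- 0L
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    per_t <- lapply(testers, function(tt) {
      predict_pair(panel, pairs[i, ], scheme, effects, ctx,
                   tester = if (is.na(tt)) NULL else tt)
    })
    mu <- mean(vapply(per_t, `[[`, numeric(1), "mean"))
    vv <- vapply(per_t, `[[`, numeric(1), "variance")
    n_clip <<- n_clip + sum(vapply(per_t, `[[`, logical(1), "clipped"))
    u <- mean(usefulness(vapply(per_t, `[[`, numeric(1), "mean"), vv, iF,
                         effects$accuracy, literal_var))
    tibble::tibble(mean = mu, variance = mean(vv), sd = sqrt(mean(vv)),
                   usefulness = u)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(parent1 = rownames(panel$dosages)[pairs[, 1]],
                   parent2 = rownames(panel$dosages)[pairs[, 2]]),
    dplyr::bind_rows(res))
  out$ld_model <- ld_model
  out$scheme <- scheme_label(scheme)
  attr(out, "n_clipped") <- n_clip
  attr(out, "accuracy") <- effects$accuracy
  class(out) <- c("cross_predictions", class(out))
  out
}
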