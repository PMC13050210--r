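# Synthetic data generation and the validation harness: LD-rich founder
# haplotypes, diploid two-pool DH panels, autotetraploid panels, simulated and
# calibrated marker effects, and the cross-validation / PropSD experiments.

#' Default genetic map for simulated datasets
#'
#' Evenly spaced loci over equal-length chromosomes (defaults: 1,000 loci on
#' 8 chromosomes of 150 cM).
#'
#' @param n_loci,n_chrom,chrom_length_cM map dimensions.
#' @return a [genetic_map()].
#' @export
sim_map <- function(n_loci = 1000, n_chrom = 8, chrom_length_cM = 150) {
  per <- rep(n_loci %/% n_chrom, n_chrom)
  per[seq_len(n_loci %% n_chrom)] <- per[seq_len(n_loci %% n_chrom)] + 1
  genetic_map(data.frame(
    marker = sprintf("m%04d", seq_len(n_loci)),
    chrom = rep(paste0("chr", seq_len(n_chrom)), per),
    pos_cM = unlist(lapply(per, function(k) seq(0, chrom_length_cM,
                                                length.out = k)))))
}

# Maximum feasible correlation between Bernoulli(p1) and Bernoulli(p2)
# (Frechet bounds).
max_bernoulli_corr <- function(p1, p2) {
  q1 <- 1 - p1; q2 <- 1 - p2
  pmin(sqrt(p1 * q2 / (q1 * p2)), sqrt(q1 * p2 / (p1 * q2)))
}

#' Simulate founder haplotypes with target adjacent-locus LD
#'
#' Per chromosome, locus allele frequencies are drawn independently (uniform
#' on `freq_range`) and binary haplotypes are generated as a Markov chain
#' along the map whose adjacent-locus correlation equals the target, capped at
#' the largest value compatible with the two frequencies (Frechet bounds).
#' Chromosomes are independent.
#'
#' @param n_hap number of haplotypes.
#' @param map a [genetic_map()].
#' @param target_autocorr target correlation between adjacent loci, in [0, 1).
#' @param freq_range range of the uniform allele-frequency draw.
#' @return `n_hap x n_loci` 0/1 matrix with the drawn frequencies as
#'   attribute `"freq"`.
#' @export
simulate_founder_haplotypes <- function(n_hap, map, target_autocorr = 0.95,
                                        freq_range = c(0.05, 0.95)) {
  assert_that(target_autocorr >= 0 && target_autocorr < 1,
              "target autocorrelation must be in [0, 1)")
  map <- genetic_map(map)
  nj <- nrow(map)
  p <- runif(nj, freq_range[1], freq_range[2])
  H <- matrix(0, n_hap, nj)
  new_chrom <- c(TRUE, map$chrom[-1] != map$chrom[-nj])
  for (j in seq_len(nj)) {
    if (new_chrom[j]) {
      H[, j] <- runif(n_hap) < p[j]
    } else {
      p1 <- p[j - 1]; p2 <- p[j]
      r <- min(target_autocorr, max_bernoulli_corr(p1, p2))
      covf <- r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
      p11 <- p2 + covf / p1
      p10 <- p2 - covf / (1 - p1)
      pr <- ifelse(H[, j - 1] == 1, p11, p10)
      H[, j] <- runif(n_hap) < pr
    }
  }
  storage.mode(H) <- "double"
  colnames(H) <- map$marker
  attr(H, "freq") <- p
  H
}

#' Simulate the diploid two-pool DH panel
#'
#' Two subpopulations (heterotic-pool analogs) with independent frequency and
#' LD draws; per pool, founder haplotypes are paired into founders, random
#' crosses are made, and each cross yields one doubled-haploid line. Defaults
#' follow the package's reference simulation: 1,000 loci / 8 chromosomes /
#' 150 cM, LD target 0.95, 200 haplotypes and 50 crosses per pool, giving
#' 100 fully homozygous phased lines.
#'
#' @param map a [genetic_map()] (default [sim_map()]).
#' @param n_lines_per_pool DH lines per subpopulation.
#' @param n_hap_per_pool founder haplotypes per subpopulation.
#' @param target_autocorr adjacent-locus LD target.
#' @param seed optional integer seed.
#' @return a phased [parent_panel()] with subpop labels "pool1"/"pool2".
#' @export
make_diploid_dataset <- function(map = sim_map(), n_lines_per_pool = 50,
                                 n_hap_per_pool = 200, target_autocorr = 0.95,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- genetic_map(map)
  cadj <- adjacent_recomb(map)
  nj <- nrow(map)
  pools <- lapply(1:2, function(pp) {
    H <- simulate_founder_haplotypes(n_hap_per_pool, map, target_autocorr)
    founders <- split(sample.int(n_hap_per_pool),
                      rep(seq_len(n_hap_per_pool / 2), each = 2))
    crosses <- matrix(sample(length(founders), 2 * n_lines_per_pool,
                             replace = length(founders) < 2 * n_lines_per_pool),
                      ncol = 2)
    dh <- vapply(seq_len(n_lines_per_pool), function(i) {
      fA <- H[founders[[crosses[i, 1]]], , drop = FALSE]
      fB <- H[founders[[crosses[i, 2]]], , drop = FALSE]
      g1 <- meiosis_gametes(fA[1, ], fA[2, ], cadj, 1)  # gamete from founder A
      g2 <- meiosis_gametes(fB[1, ], fB[2, ], cadj, 1)
      drop(meiosis_gametes(g1, g2, cadj, 1))            # F1 gamete, doubled
    }, numeric(nj))
    t(dh)
  })
  hap1 <- rbind(pools[[1]], pools[[2]])
  dosages <- 2 * hap1
  rownames(dosages) <- sprintf("L%03d", seq_len(nrow(dosages)))
  colnames(dosages) <- map$marker
  haplotypes <- lapply(seq_len(nrow(hap1)), function(i)
    rbind(hap1[i, ], hap1[i, ]))
  parent_panel(dosages, map, ploidy = 2, haplotypes = haplotypes,
               subpop = rep(c("pool1", "pool2"), each = nrow(pools[[1]])))
}

#' Simulate the autotetraploid panel
#'
#' A single subpopulation: founder haplotypes are assembled into tetraploid
#' founders (4 per individual) and random crosses among them produce
#' non-fully-homozygous phased genotypes (defaults: 400 founder haplotypes,
#' 100 crosses, 100 genotypes).
#'
#' @param map a [genetic_map()] (default [sim_map()]).
#' @param n_genotypes panel size (= number of crosses).
#' @param n_founder_hap founder haplotypes.
#' @param target_autocorr adjacent-locus LD target.
#' @param seed optional integer seed.
#' @return a phased [parent_panel()] with ploidy 4.
#' @export
make_tetraploid_dataset <- function(map = sim_map(), n_genotypes = 100,
                                    n_founder_hap = 400,
                                    target_autocorr = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- genetic_map(map)
  cadj <- adjacent_recomb(map)
  H <- simulate_founder_haplotypes(n_founder_hap, map, target_autocorr)
  n_f <- n_founder_hap / 4
  founders <- split(sample.int(n_founder_hap), rep(seq_len(n_f), each = 4))
  crosses <- t(vapply(seq_len(n_genotypes), function(i) sample(n_f, 2),
                      integer(2)))
  haplotypes <- lapply(seq_len(n_genotypes), function(i) {
    gk <- tetra_gametes(lapply(founders[[crosses[i, 1]]],
                               function(r) H[r, ]), cadj, 1)
    gl <- tetra_gametes(lapply(founders[[crosses[i, 2]]],
                               function(r) H[r, ]), cadj, 1)
    rbind(t(gk[[1]]), t(gk[[2]]), t(gl[[1]]), t(gl[[2]]))
  })
  dosages <- t(vapply(haplotypes, colSums, numeric(nrow(map))))
  rownames(dosages) <- sprintf("T%03d", seq_len(n_genotypes))
  colnames(dosages) <- map$marker
  parent_panel(dosages, map, ploidy = 4, haplotypes = haplotypes,
               subpop = rep("pool1", n_genotypes))
}

#' Simulate correlated two-trait marker effects
#'
#' Samples `n_qtl` QTL positions and draws additive (and optionally dominance)
#' effects for each trait from a bivariate normal with the given cross-trait
#' correlation; non-QTL loci get zero effects (genotypic parameterization).
#'
#' @param panel a [parent_panel()] (defines the number of loci).
#' @param n_qtl number of causal loci.
#' @param traits trait names.
#' @param trait_correlation cross-trait effect correlation.
#' @param dominance_ratio SD of dominance effects relative to additive ones
#'   (0 for purely additive traits).
#' @param seed optional integer seed.
#' @return list with one [trait_effects()] per trait and the QTL index set
#'   `qtl`.
#' @export
simulate_effects <- function(panel, n_qtl = 250, traits = c("YLD", "MAT"),
                             trait_correlation = 0.3, dominance_ratio = 0.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nj <- panel$n_loci
  assert_that(n_qtl < nj, "n_qtl must be smaller than the number of loci")
  qtl <- sort(sample.int(nj, n_qtl))
  nt <- length(traits)
  R <- matrix(trait_correlation, nt, nt); diag(R) <- 1
  L <- chol(R)
  draw <- function(scale) {
    z <- matrix(rnorm(n_qtl * nt), n_qtl) %*% L * scale
    z
  }
  A <- draw(1); D <- draw(dominance_ratio)
  out <- lapply(seq_len(nt), function(k) {
    a <- numeric(nj); d <- numeric(nj)
    a[qtl] <- A[, k]
    d[qtl] <- D[, k]
    trait_effects(a, d, parameterization = "genotypic", accuracy = 1)
  })
  names(out) <- traits
  c(out, list(qtl = qtl))
}

# Design matrix of class scores for a locus subset.
score_design <- function(panel, loci, cvm) {
  M <- panel$dosages[, loci, drop = FALSE]
  cbind(matrix(cvm$additive[M + 1], nrow(M)),
        matrix(cvm$dominance[M + 1], nrow(M)))
}

#' Calibrate estimated effects to a target parental accuracy
#'
#' Constructs the estimated-effect settings used in the validation study:
#' \describe{
#' \item{QTL_true}{the true effects, untouched (accuracy 1).}
#' \item{QTL_1}{different per-locus QTL effects that reproduce the parental
#'   genome-wide genotypic values exactly (a random null-space perturbation of
#'   the parental design).}
#' \item{QTL_0.7}{effects re-estimated on the QTL columns from noisy parental
#'   phenotypes (TGV plus Gaussian error) by ridge BLUP, the standard
#'   marker-effect model: the penalty is set from the implied heritability
#'   (lambda = (1 - h2)/h2 times the summed score variance) and the noise is
#'   scaled by bisection until the parental estimated-vs-true correlation
#'   hits `target_r` (within `tol`).}
#' \item{Markers_0.7}{the same ridge-BLUP estimation restricted to the
#'   non-QTL loci (QTL effects are exactly zero).}
#' }
#'
#' @param mode one of "QTL_true", "QTL_1", "QTL_0.7", "Markers_0.7".
#' @param panel a [parent_panel()].
#' @param true_effects a [trait_effects()] with the causal effects.
#' @param qtl integer indices of the causal loci.
#' @param target_r target parental accuracy (default 0.7).
#' @param cvm a [class_value_map()] (diploid default when NULL).
#' @param tol acceptable deviation of the achieved correlation.
#' @param seed optional integer seed.
#' @return a [trait_effects()] with `accuracy` set to the achieved parental
#'   correlation.
#' @export
calibrate_effects <- function(mode = c("QTL_true", "QTL_1", "QTL_0.7",
                                       "Markers_0.7"),
                              panel, true_effects, qtl, target_r = 0.7,
                              cvm = NULL, tol = 0.005, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cvm)) cvm <- default_cvm(panel$ploidy)
  nj <- panel$n_loci
  tgv <- genotypic_value(panel$dosages, true_effects, cvm)
  assert_that(sd(tgv) > 0, "parental true values have zero variance")
  if (mode == "QTL_true") return(true_effects)

  if (mode == "QTL_1") {
    X <- score_design(panel, qtl, cvm)
    beta <- c(true_effects$additive[qtl], true_effects$dominance[qtl])
    sv <- svd(X, nu = 0, nv = ncol(X))
    rank <- sum(sv$d > max(sv$d) * 1e-10)
    assert_that(rank < ncol(X),
                "parental design has no null space; QTL_1 calibration unattainable")
    N <- sv$v[, (rank + 1):ncol(X), drop = FALSE]
    pert <- drop(N %*% rnorm(ncol(N)))
    pert <- pert / max(abs(pert)) * max(abs(beta), 1e-8)
    beta2 <- beta + pert
    a <- true_effects$additive; d <- true_effects$dominance
    a[qtl] <- beta2[seq_along(qtl)]
    d[qtl] <- beta2[-seq_along(qtl)]
    return(trait_effects(a, d, true_effects$parameterization, accuracy = 1))
  }

  # QTL_0.7 / Markers_0.7: ridge-BLUP marker effects from noisy parental
  # phenotypes y = TGV + s*z, with the penalty fixed by the implied
  # heritability h2 = 1/(1 + s^2); the phenotype noise s is bisected until
  # the parental GEGV-TGV correlation hits the target.
  loci <- if (mode == "QTL_0.7") qtl else setdiff(seq_len(nj), qtl)
  X <- score_design(panel, loci, cvm)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sumvar <- sum(colSums(Xc^2)) / (nrow(Xc) - 1)
  sv <- svd(Xc)
  z <- rnorm(length(tgv)) * sd(tgv)
  fit <- function(s) {
    yc <- tgv + s * z
    yc <- yc - mean(yc)
    uy <- drop(crossprod(sv$u, yc))
    h2 <- 1 / (1 + s^2)
    lam <- max((1 - h2) / h2 * sumvar, 1e-8)
    beta <- drop(sv$v %*% (uy * sv$d / (sv$d^2 + lam)))
    gegv <- drop(Xc %*% beta)
    r <- if (sd(gegv) > 1e-12) cor(gegv, tgv) else 0
    list(r = r, beta = beta)
  }
  lo <- 0; hi <- 1
  while (fit(hi)$r > target_r && hi < 1e6) hi <- hi * 2
  assert_that(fit(hi)$r <= target_r + tol,
              "target accuracy unattainable by shrinkage on noisy phenotypes")
  res <- NULL
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    res <- fit(mid)
    if (abs(res$r - target_r) <= tol * 0.5) break
    if (res$r > target_r) lo <- mid else hi <- mid
  }
  a <- numeric(nj); d <- numeric(nj)
  a[loci] <- res$beta[seq_along(loci)]
  d[loci] <- res$beta[-seq_along(loci)]
  trait_effects(a, d, true_effects$parameterization,
                accuracy = max(0, min(1, res$r)))
}

#' Pearson accuracy and normalized RMSE
#'
#' `nrmse` is the root-mean-square error divided by the standard deviation of
#' the true values.
#'
#' @param x,y,pred,true numeric vectors of equal length (>= 2).
#' @return numeric scalar.
#' @export
pearson <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "need equal-length vectors of length >= 2")
  cor(x, y)
}

#' @rdname pearson
#' @export
nrmse <- function(pred, true) {
  assert_that(length(pred) == length(true) && length(true) >= 2,
              "need equal-length vectors of length >= 2")
  s <- sd(true)
  assert_that(s > 0, "true values have zero variance")
  sqrt(mean((pred - true)^2)) / s
}

#' Derive heterozygous clone parents from an inbred panel
#'
#' Pairs the panel's fully homozygous lines within their subpopulations and
#' returns the resulting F1 hybrids as a phased panel of heterozygous clones.
#' Crossing two inbred lines yields a uniform F1, so a clonal breeding
#' scenario is only informative on heterozygous parents such as these.
#'
#' @param panel a fully homozygous diploid [parent_panel()].
#' @param seed optional integer seed for the pairing.
#' @return a phased [parent_panel()] with half as many parents.
#' @export
make_clonal_panel <- function(panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_that(panel$ploidy == 2 && all(panel$dosages %in% c(0, 2)),
              "clone derivation expects a fully homozygous diploid panel")
  pools <- panel$subpop %||% rep("pool1", panel$n_parents)
  idx <- unlist(lapply(unique(pools), function(pp) {
    rows <- which(pools == pp)
    sample(rows, 2 * (length(rows) %/% 2))
  }))
  pairs <- matrix(idx, ncol = 2, byrow = TRUE)
  haplotypes <- lapply(seq_len(nrow(pairs)), function(i)
    rbind(panel$dosages[pairs[i, 1], ] / 2, panel$dosages[pairs[i, 2], ] / 2))
  dosages <- t(vapply(haplotypes, colSums, numeric(panel$n_loci)))
  rownames(dosages) <- sprintf("C%03d", seq_len(nrow(dosages)))
  colnames(dosages) <- colnames(panel$dosages)
  parent_panel(dosages, panel$map, ploidy = 2, haplotypes = haplotypes,
               subpop = pools[pairs[, 1]])
}

#' Standard validation scenarios for a panel
#'
#' Diploid panels get DH, ILs (3 selfing cycles), Hybrid_DH, Hybrid_ILs and
#' Clonal; autotetraploids the non-DH subset. Non-hybrid scenarios draw
#' random pairs panel-wide; hybrid scenarios pair within the first pool and
#' testcross to a tester from the opposite pool (or any other panel member
#' for single-pool panels). For fully homozygous
#' diploid panels the clonal scenario runs on heterozygous clone parents
#' derived with [make_clonal_panel()] (an inbred x inbred F1 does not
#' segregate).
#'
#' @param panel a [parent_panel()].
#' @param seed seed for tester choice and clone derivation.
#' @return named list of scenarios, each `list(scheme, pair_pool)` with an
#'   optional scenario-specific `panel`.
#' @export
standard_scenarios <- function(panel, seed = 1) {
  set.seed(seed)
  pools <- panel$subpop %||% rep("pool1", panel$n_parents)
  pool1 <- which(pools == pools[1])
  pool2 <- setdiff(seq_len(panel$n_parents), pool1)
  if (!length(pool2)) pool2 <- pool1
  tester <- sample(pool2, 1)
  hybrid_pool <- setdiff(pool1, tester)
  all_pool <- setdiff(seq_len(panel$n_parents), tester)
  clonal <- if (panel$ploidy == 2 && all(panel$dosages %in% c(0, 2))) {
    cp <- make_clonal_panel(panel)
    list(scheme = cross_scheme("CLONE"),
         pair_pool = seq_len(cp$n_parents), panel = cp)
  } else {
    list(scheme = cross_scheme("CLONE"), pair_pool = all_pool)
  }
  sc <- list(
    ILs = list(scheme = cross_scheme("SELF", t = 3), pair_pool = all_pool),
    Hybrid_ILs = list(scheme = cross_scheme("SELF", t = 3, testers = tester),
                      pair_pool = hybrid_pool),
    Clonal = clonal
  )
  if (panel$ploidy == 2) {
    sc <- c(list(
      DH = list(scheme = cross_scheme("DH"), pair_pool = all_pool),
      Hybrid_DH = list(scheme = cross_scheme("DH", testers = tester),
                       pair_pool = hybrid_pool)), sc)
  }
  sc
}

#' Cross-validation of predicted family means and SDs
#'
#' For each scenario, draws random parent pairs, simulates progeny under the
#' true effects (the Monte-Carlo truth), predicts the family mean and the
#' within-family SD under each requested LD model and effect setting, and
#' reports Pearson accuracy and NRMSE.
#'
#' @param panel a [parent_panel()].
#' @param scenarios as from [standard_scenarios()].
#' @param true_effects the causal [trait_effects()], or a named list of
#'   value definitions (e.g. genotypic and additive-only versions of the same
#'   trait) scored from the same simulated progeny.
#' @param effect_sets named list of effect settings to evaluate (include
#'   `QTL_true = true_effects` to score the oracle setting). An entry may be
#'   a bare [trait_effects()] (scored against the first truth) or
#'   `list(effects = , truth = "<name>", sd = FALSE)` (`sd = FALSE` scores
#'   the mean only).
#' @param ld_models character subset of independent/approx/full.
#' @param n_crosses random pairs per scenario.
#' @param n_progeny simulated progeny per pair.
#' @param cvm a [class_value_map()] (diploid default when NULL).
#' @param seed master seed.
#' @return tibble of class `cross_validation` with columns `scenario`,
#'   `effect_set`, `quantity` ("mean"/"sd"), `method`, `accuracy`, `nrmse`,
#'   `n_crosses`, `n_progeny`.
#' @export
run_cross_validation_experiment <- function(panel, scenarios, true_effects,
                                            effect_sets,
                                            ld_models = c("independent",
                                                          "approx", "full"),
                                            n_crosses = 200, n_progeny = 2000,
                                            cvm = NULL, seed = 1) {
  if (is.null(cvm)) cvm <- default_cvm(panel$ploidy)
  if (inherits(true_effects, "trait_effects"))
    true_effects <- list(genotypic = true_effects)
  effect_sets <- lapply(effect_sets, function(es) {
    if (inherits(es, "trait_effects"))
      es <- list(effects = es, truth = names(true_effects)[1])
    assert_that(es$truth %in% names(true_effects),
                "effect set refers to an unknown truth definition")
    es
  })
  out <- list()
  for (sn in names(scenarios)) {
    sc <- scenarios[[sn]]
    sc_panel <- sc$panel %||% panel
    set.seed(derive_seed(seed, which(names(scenarios) == sn)))
    pool <- sc$pair_pool
    all_pairs <- t(utils::combn(pool, 2))
    pick <- sample.int(nrow(all_pairs), min(n_crosses, nrow(all_pairs)))
    pairs <- all_pairs[pick, , drop = FALSE]
    truth <- lapply(true_effects, function(x) matrix(0, 2, nrow(pairs)))
    for (i in seq_len(nrow(pairs))) {
      dos <- simulate_progeny(sc_panel, pairs[i, ], sc$scheme, n_progeny)
      for (tn in names(true_effects)) {
        gv <- genotypic_value(dos, true_effects[[tn]], cvm)
        truth[[tn]][, i] <- c(mean(gv), sd(gv))
      }
    }
    for (es in names(effect_sets)) {
      eff <- effect_sets[[es]]$effects
      tr <- truth[[effect_sets[[es]]$truth]]
      want_sd <- effect_sets[[es]]$sd %||% TRUE
      models <- if (want_sd) ld_models else ld_models[1]
      preds <- lapply(models, function(lm_)
        predict_all_crosses(sc_panel, sc$scheme, eff, ld_model = lm_,
                            pairs = pairs, cvm = cvm))
      names(preds) <- models
      out[[length(out) + 1L]] <- tibble::tibble(
        scenario = sn, effect_set = es, quantity = "mean", method = "mean",
        accuracy = pearson(preds[[1]]$mean, tr[1, ]),
        nrmse = nrmse(preds[[1]]$mean, tr[1, ]),
        n_crosses = nrow(pairs), n_progeny = n_progeny)
      if (want_sd) for (lm_ in models) {
        out[[length(out) + 1L]] <- tibble::tibble(
          scenario = sn, effect_set = es, quantity = "sd", method = lm_,
          accuracy = pearson(preds[[lm_]]$sd, tr[2, ]),
          nrmse = nrmse(preds[[lm_]]$sd, tr[2, ]),
          n_crosses = nrow(pairs), n_progeny = n_progeny)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("cross_validation", class(res))
  res
}

# Scaled centered dosage matrix Z with Z Z' = G; used to draw additive values
# u ~ N(0, G) as Z %*% rnorm (iid standard-normal effects on centered
# dosages).
grm_root <- function(panel) {
  M <- panel$dosages; phi <- panel$ploidy
  p <- colMeans(M) / phi
  poly <- p > 0 & p < 1
  sweep(M[, poly, drop = FALSE], 2, phi * p[poly]) /
    sqrt(phi * sum(p[poly] * (1 - p[poly])))
}

#' PropSD validation under random sampling
#'
#' Draws parental samples of the given sizes with replacement, predicts
#' PropSD from the pool GRM, and compares with the Monte-Carlo mean realized
#' loss over random marker-effect draws (u ~ N(0, G)).
#'
#' @param panel a [parent_panel()].
#' @param sizes sample sizes.
#' @param reps samples per size.
#' @param n_effect_draws Monte-Carlo effect draws.
#' @param seed master seed.
#' @return tibble of class `propsd_random` with columns `size`, `rep`,
#'   `predicted`, `realized`, `realized_sem`.
#' @export
run_propsd_random_experiment <- function(panel, sizes = c(5, 20, 100, 200),
                                         reps = 20, n_effect_draws = 1e4,
                                         seed = 1) {
  set.seed(seed)
  G <- grm(panel)
  Z <- grm_root(panel)
  U <- Z %*% matrix(rnorm(ncol(Z) * n_effect_draws), ncol(Z))
  sd_pool <- apply(U, 2, sd)
  out <- list()
  for (sz in sizes) {
    for (rp in seq_len(reps)) {
      sel <- sample.int(panel$n_parents, sz, replace = TRUE)
      predicted <- prop_sd(G, sel)
      loss <- 1 - apply(U[sel, , drop = FALSE], 2, sd) / sd_pool
      out[[length(out) + 1L]] <- tibble::tibble(
        size = sz, rep = rp, predicted = predicted,
        realized = mean(loss),
        realized_sem = sd(loss) / sqrt(length(loss)))
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("propsd_random", class(res))
  res
}

#' PropSD validation under selection
#'
#' For each diversity cutoff and each independent random set of marker
#' effects, optimizes a mating plan subject to that cutoff and compares the
#' plan's predicted PropSD with the realized loss of genetic SD (includes LD)
#' and of genic SD (LD-free) among the selected parents.
#'
#' @param panel a [parent_panel()].
#' @param scheme a [cross_scheme()] used for the predictions.
#' @param cutoffs PropSD cutoffs to scan.
#' @param n_effect_sets independent marker-effect draws per cutoff.
#' @param total_crosses crosses per plan.
#' @param config an [optimizer_config()] (scaled-down default).
#' @param ld_model LD model for the predictions ("independent" keeps the
#'   experiment fast; the diversity comparison does not depend on it).
#' @param seed master seed.
#' @return tibble of class `propsd_selection` with columns `cutoff`,
#'   `effect_set`, `predicted`, `genetic_loss`, `genic_loss`.
#' @export
run_propsd_selection_experiment <- function(panel, scheme = cross_scheme("CLONE"),
                                            cutoffs = c(0.001, 0.01, 0.02,
                                                        0.03, 0.04, 0.05),
                                            n_effect_sets = 100,
                                            total_crosses = 10,
                                            config = optimizer_config(
                                              population_size = 40,
                                              n_elite = 6,
                                              max_iterations = 60,
                                              convergence_patience = 15),
                                            ld_model = "independent",
                                            seed = 1) {
  G <- grm(panel)
  p <- colMeans(panel$dosages) / panel$ploidy
  poly <- p > 0 & p < 1
  # effects scaled like the GRM root so u = Z a has covariance G
  scale_a <- 1 / sqrt(panel$ploidy * sum(p[poly] * (1 - p[poly])))
  out <- list()
  for (ci in seq_along(cutoffs)) {
    for (esi in seq_len(n_effect_sets)) {
      set.seed(derive_seed(seed, ci * 1000 + esi))
      a <- numeric(panel$n_loci)
      a[poly] <- rnorm(sum(poly)) * scale_a
      eff <- trait_effects(a)
      preds <- predict_all_crosses(panel, scheme, eff, ld_model = ld_model)
      cs <- constraint_set(total_crosses = total_crosses,
                           propsd_cutoff = cutoffs[ci])
      cfg <- config; cfg$seed <- derive_seed(seed, 5e5 + ci * 1000 + esi)
      res <- optimize_matings(preds, cs, cfg, G_pool = G)
      sel <- match(plan_parent_multiset(res$plan), rownames(panel$dosages))
      dsel <- panel$dosages[sel, , drop = FALSE]
      out[[length(out) + 1L]] <- tibble::tibble(
        cutoff = cutoffs[ci], effect_set = esi,
        predicted = res$report$propsd,
        genetic_loss = 1 - genetic_sd(dsel, eff) / genetic_sd(panel$dosages, eff),
        genic_loss = 1 - genic_sd(dsel, eff) / genic_sd(panel$dosages, eff))
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("propsd_selection", class(res))
  res
}
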