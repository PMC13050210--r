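# Family means, the three LD variance models, and the usefulness criterion.

test_that("per-locus mean and variance follow the class-value definitions", {
  expect_equal(locus_mean(c(0, 1, 0), a_j = 1, d_j = 0.5), 1.5)
  expect_equal(locus_mean(c(0.25, 0.5, 0.25), a_j = 1, d_j = 1), 1.5)
  expect_equal(locus_variance(c(0, 1, 0), 1, 1), 0)
  expect_equal(locus_variance(c(0.25, 0.5, 0.25), 1, 0), 0.5)
  expect_equal(locus_variance(c(0.25, 0.5, 0.25), 0, 1), 0.25)
  expect_equal(locus_variance(c(0.25, 0.5, 0.25), 1, 1, component = "additive_only"),
               0.5)
})

test_that("additive/dominance decomposition matches enumeration", {
  d <- locus_ad_decomposition(c(0.25, 0.5, 0.25), 1, 1)
  expect_equal(d$total_var, 0.75)
  expect_equal(d$additive_var, 0.5)
  expect_equal(d$dominance_var, 0.25)
  expect_equal(d$ad_correlation, 0)
  # rho equals the brute-force correlation of (m a, w d) under the dist
  set.seed(1)
  for (i in 1:20) {
    p <- runif(3); p <- p / sum(p)
    a <- rnorm(1); dd <- rnorm(1)
    out <- locus_ad_decomposition(p, a, dd)
    m_vals <- (0:2) * a; w_vals <- c(0, 1, 0) * dd
    mm <- sum(p * m_vals); mw <- sum(p * w_vals)
    covb <- sum(p * (m_vals - mm) * (w_vals - mw))
    sa <- sqrt(sum(p * (m_vals - mm)^2)); sdd <- sqrt(sum(p * (w_vals - mw)^2))
    rho_b <- if (sa * sdd > 0) covb / (sa / 1 * sdd) else 0
    expect_equal(out$ad_correlation, rho_b, tolerance = 1e-9)
    expect_equal(out$total_var,
                 out$additive_var + out$dominance_var +
                   2 * out$ad_correlation * sa * sdd, tolerance = 1e-9)
  }
  # d_j = 0: degenerate denominator handled
  expect_equal(locus_ad_decomposition(c(0.25, 0.5, 0.25), 1, 0)$ad_correlation, 0)
})

test_that("family mean reduces to mid-parent value under additivity", {
  pan <- toy_phased_panel()
  a <- c(0.5, -1, 2, 0.3, -0.7, 1.2)
  eff <- trait_effects(a)
  mp <- sum(a * (pan$dosages[3, ] + pan$dosages[4, ]) / 2)
  expect_equal(family_mean(pan, c(3, 4), cross_scheme("F1"), eff), mp)
  # selfing a homozygous parent reproduces its own genotypic value
  effd <- trait_effects(a, rep(0.2, 6))
  expect_equal(family_mean(pan, c(1, 1), cross_scheme("SELF", t = 2), effd),
               unname(genotypic_value(pan$dosages[1, , drop = FALSE], effd)))
})

test_that("family mean matches Monte-Carlo progeny mean across schemes", {
  pan <- ld_panel(n_loci = 40, lines = 10, seed = 21)
  eff <- simulate_effects(pan, n_qtl = 20, seed = 2)$YLD
  for (sch in list(cross_scheme("DH"), cross_scheme("SELF", t = 3),
                   cross_scheme("SELF", t = 1, testers = 15L))) {
    tr <- sim_truth(pan, c(2, 9), sch, eff, 2e4)
    expect_lt(abs(family_mean(pan, c(2, 9), sch, eff) - tr["mean"]),
              3 * tr["se_mean"])
  }
})

test_that("the legacy population-frequency F1 mean is only a comparator", {
  expect_equal(falconer_f1_mean(0.5, 0.5, 0, 2, 0), 0)
  expect_equal(falconer_f1_mean(0.3, 0.8, 0.1, 1.5, 0), 1.5 * (0.3 - 0.8 - 0.1))
  # single-locus Aa x Aa with dominance: the simulator adjudicates
  map <- toy_map(1)
  dos <- rbind(P1 = 1, P2 = 1); colnames(dos) <- map$marker
  h <- list(rbind(1, 0), rbind(0, 1))
  pan <- parent_panel(dos, map, haplotypes = h)
  eff <- trait_effects(1, 1)
  tr <- sim_truth(pan, c(1, 2), cross_scheme("F1"), eff, 4e4)
  mu <- family_mean(pan, c(1, 2), cross_scheme("F1"), eff)
  legacy <- falconer_f1_mean(p = 0.5, q = 0.5, y = 0, a = 1, d = 1)
  expect_lt(abs(mu - tr[["mean"]]), 3 * tr[["se_mean"]])
  expect_gt(abs(legacy - tr[["mean"]]), 10 * tr[["se_mean"]])
})

test_that("covariance utilities behave on edge cases and random inputs", {
  expect_equal(cov_to_corr(diag(c(2, 3, 4))), diag(3))
  S <- rbind(c(2, 0.5, 0), c(0.5, 1, 0), c(0, 0, 0))  # zero-variance locus
  C <- cov_to_corr(S)
  expect_false(anyNA(C))
  expect_equal(C[3, 1], 0); expect_equal(C[3, 3], 1)
  set.seed(4)
  A <- crossprod(matrix(rnorm(25), 5))
  expect_equal(cov_to_corr(A), stats::cov2cor(A))

  # source population covariance equals the brute-force covariance (1/n scale)
  pan <- ld_panel(n_loci = 10, lines = 6, seed = 9)
  eff <- trait_effects(rnorm(10), rnorm(10) / 2)
  S1 <- source_pop_cov(pan, "pool1", eff)
  M <- pan$dosages[pan$subpop == "pool1", ]
  Mstar <- M * rep(eff$additive, each = nrow(M)) +
    (M == 1) * rep(eff$dominance, each = nrow(M))
  n <- nrow(M)
  expect_equal(S1, cov(Mstar) * (n - 1) / n, ignore_attr = TRUE)
  expect_error(source_pop_cov(pan, "nope", eff), "at least 2")
})

test_that("propagation: free recombination kills covariance, complete linkage keeps it", {
  cmat <- matrix(0.5, 3, 3); diag(cmat) <- 0
  Sk <- crossprod(matrix(rnorm(9), 3)); Sl <- crossprod(matrix(rnorm(9), 3))
  Sf <- propagate_family_cov(Sk, Sl, cmat, cross_scheme("F1"))
  expect_equal(Sf[upper.tri(Sf)], rep(0, 3))
  cmat0 <- matrix(0, 3, 3)
  expect_equal(propagate_family_cov(Sk, Sl, cmat0, cross_scheme("F1")),
               (Sk + Sl) / 2)
  expect_error(propagate_family_cov(Sk, Sl[1:2, 1:2], cmat, cross_scheme("F1")),
               "conformable")
})

test_that("phased additive covariance matches the brute-force definition", {
  pan <- toy_phased_panel()
  eff <- trait_effects(c(1, -0.5, 2, 0.7, -1, 0.3))
  pc <- phased_additive_cov(pan$haplotypes[[3]], pan$haplotypes[[4]], eff)
  p <- (colMeans(pan$haplotypes[[3]]) + colMeans(pan$haplotypes[[4]])) / 2
  Hs <- sweep(pan$haplotypes[[3]], 2, p) * rep(eff$additive, each = 2)
  expect_equal(pc$sigma_k, crossprod(Hs) / 2)
  expect_equal(pc$p, p)
  # monomorphic family locus -> zero row/column
  both1 <- which(pan$dosages[3, ] + pan$dosages[4, ] == 4)[1]
  if (!is.na(both1)) expect_equal(unname(pc$sigma_k[both1, ]), rep(0, 6))
  # coupling-phase doubly heterozygous parent -> positive off-diagonal
  Hk <- rbind(c(1, 1), c(0, 0)); Hl <- rbind(c(0, 0), c(0, 0))
  pc2 <- phased_additive_cov(Hk, Hl, trait_effects(c(1, 1)))
  expect_gt(pc2$sigma_k[1, 2], 0)
})

test_that("genome-wide variance models reduce correctly", {
  expect_equal(variance_independent(c(0.5, 0.25)), 0.75)
  expect_equal(variance_approx(sqrt(c(0.5, 0.25)), diag(2)), 0.75)
  expect_equal(variance_approx(c(1, 1), matrix(1, 2, 2)), 4)
  expect_warning(v <- variance_approx(c(1, 1), matrix(c(1, -2, -2, 1), 2)),
                 "clipped")
  expect_equal(v, 0)
  # single locus: full model reduces exactly to the per-locus variance
  d <- locus_ad_decomposition(c(0.2, 0.5, 0.3), 1.3, 0.8)
  expect_equal(variance_full(sqrt(d$additive_var), sqrt(d$dominance_var),
                             d$ad_correlation, matrix(1, 1, 1)),
               d$total_var, tolerance = 1e-9)
  # Ca = I, d = 0: sum of additive variances
  expect_equal(variance_full(c(1, 2), c(0, 0), c(0, 0), diag(2)), 5)
})

test_that("F1 cross-locus covariance of the phased engine matches the simulator", {
  pan <- toy_phased_panel()
  eff <- trait_effects(c(1, -0.5, 2, 0.7, -1, 0.3))
  Sf <- crossplan:::family_cov_full(pan, c(3, 4), cross_scheme("CLONE"), eff)
  n <- 1e5
  dos <- simulate_progeny(pan, c(3, 4), cross_scheme("CLONE"), n, seed = 31)
  vals <- dos * rep(eff$additive, each = n)
  emp <- cov(vals) * (n - 1) / n
  expect_lt(max(abs(Sf - emp)), 0.02)
})

test_that("predicted variances track Monte-Carlo truth for every scheme and ploidy", {
  pan <- ld_panel(n_loci = 50, lines = 10, seed = 13)
  eff <- simulate_effects(pan, n_qtl = 25, seed = 8)$YLD
  pair <- c(3, 8)
  for (sch in list(cross_scheme("DH"), cross_scheme("SELF", t = 3),
                   cross_scheme("DH", testers = 16L))) {
    tr <- sim_truth(pan, pair, sch, eff, 4e4)
    pr <- predict_all_crosses(pan, sch, eff, ld_model = "full",
                              pairs = matrix(pair, 1))
    expect_lt(abs(pr$sd - tr[["sd"]]) / tr[["sd"]], 0.06)
  }
  pan4 <- ld_panel4(n_loci = 50, n_genotypes = 12, seed = 14)
  eff4 <- simulate_effects(pan4, n_qtl = 25, seed = 8)$YLD
  for (sch in list(cross_scheme("CLONE"), cross_scheme("SELF", t = 3))) {
    tr <- sim_truth(pan4, c(2, 7), sch, eff4, 4e4, cvm = cvm4())
    pr <- predict_all_crosses(pan4, sch, eff4, ld_model = "full",
                              pairs = matrix(c(2, 7), 1), cvm = cvm4())
    expect_lt(abs(pr$sd - tr[["sd"]]) / tr[["sd"]], 0.08)
  }
})

test_that("information ordering: full <= approx <= independent in aggregate error", {
  pan <- ld_panel(n_loci = 50, lines = 10, seed = 17)
  eff <- simulate_effects(pan, n_qtl = 25, seed = 5)$YLD
  sch <- cross_scheme("DH")
  pool <- which(pan$subpop == "pool1")
  set.seed(2)
  prs <- t(replicate(25, sample(pool, 2)))
  truth <- vapply(seq_len(nrow(prs)), function(i)
    sim_truth(pan, prs[i, ], sch, eff, 5e3, seed = 100 + i)[["sd"]],
    numeric(1))
  err <- vapply(c("full", "approx", "independent"), function(m) {
    pr <- predict_all_crosses(pan, sch, eff, ld_model = m, pairs = prs)
    median(abs(pr$sd - truth))
  }, numeric(1))
  expect_lte(err[["full"]], err[["approx"]] + 1e-9)
  expect_lte(err[["approx"]], err[["independent"]] + 1e-9)
})

test_that("usefulness follows the SD convention and is monotone in variance", {
  expect_equal(usefulness(3, 4, i = 0), 3)
  expect_equal(usefulness(3, 4, i = 1, r = 1), 5)
  expect_equal(usefulness(3, 4, i = 1, r = 1, literal_var = TRUE), 7)
  u <- usefulness(0, c(1, 2, 4), i = 1.5, r = 0.8)
  expect_true(all(diff(u) > 0))
  expect_error(usefulness(0, -1, 1), "non-negative")
})

test_that("predict_all_crosses enumerates symmetric, consistent predictions", {
  pan <- ld_panel(n_loci = 30, lines = 6, seed = 19)
  eff <- simulate_effects(pan, n_qtl = 15, seed = 4)$YLD
  sch <- cross_scheme("DH")
  all_pr <- predict_all_crosses(pan, sch, eff, ld_model = "approx")
  n <- pan$n_parents
  expect_equal(nrow(all_pr), n * (n - 1) / 2)
  a <- predict_all_crosses(pan, sch, eff, ld_model = "approx",
                           pairs = matrix(c(2, 5), 1))
  b <- predict_all_crosses(pan, sch, eff, ld_model = "approx",
                           pairs = matrix(c(5, 2), 1))
  expect_equal(a[c("mean", "variance", "sd", "usefulness")],
               b[c("mean", "variance", "sd", "usefulness")])
  row <- all_pr[all_pr$parent1 == a$parent1[1] &
                  all_pr$parent2 == a$parent2[1], ]
  expect_equal(row$variance, a$variance)
  # parameterization tag does not change results when d = 0
  effb <- trait_effects(eff$additive, parameterization = "breeding")
  effg <- trait_effects(eff$additive, parameterization = "genotypic")
  expect_equal(
    predict_all_crosses(pan, sch, effb, ld_model = "full")$variance,
    predict_all_crosses(pan, sch, effg, ld_model = "full")$variance)
})
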