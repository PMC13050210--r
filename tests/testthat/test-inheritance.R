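# Gamete / genotype-class engines and the meiosis simulator.

test_that("gamete distributions: Mendelian diploid and hypergeometric tetraploid", {
  expect_equal(gamete_dist(1, 2), c(0.5, 0.5))
  expect_equal(gamete_dist(2, 2), c(0, 1))
  # enumeration oracle: all C(4,2) unordered chromosome pairs of a duplex
  chr <- c(1, 1, 0, 0)
  pairs <- combn(4, 2)
  counts <- table(factor(colSums(matrix(chr[pairs], 2)), levels = 0:2))
  expect_equal(gamete_dist(2, 4), as.vector(counts) / 6)
  expect_error(gamete_dist(5, 4), "0..4")
})

test_that("F1 class distributions are gamete convolutions", {
  expect_equal(f1_locus_dist(gamete_dist(2, 2), gamete_dist(0, 2)),
               c(0, 1, 0))
  expect_equal(f1_locus_dist(gamete_dist(1, 2), gamete_dist(1, 2)),
               c(0.25, 0.5, 0.25))
  # tetraploid duplex x nulliplex: convolution oracle
  gk <- gamete_dist(2, 4); gl <- gamete_dist(0, 4)
  conv <- sapply(0:4, function(s) {
    tot <- 0
    for (i in 0:2) for (j in 0:2) if (i + j == s) tot <- tot + gk[i + 1] * gl[j + 1]
    tot
  })
  expect_equal(f1_locus_dist(gk, gl), conv)
  expect_equal(conv[1:3], c(1 / 6, 4 / 6, 1 / 6))
})

test_that("selfing recursion halves heterozygosity per generation (diploid)", {
  aa <- c(0, 1, 0)
  expect_equal(self_locus_dist(aa, 1), c(0.25, 0.5, 0.25))
  d3 <- self_locus_dist(aa, 3)
  expect_equal(d3[2], 1 / 8)             # 3-step Markov recursion
  expect_equal(d3[c(1, 3)], c(7, 7) / 16)
  # fixation limit: heterozygote mass is monotone decreasing
  hets <- sapply(0:8, function(t) self_locus_dist(aa, t)[2])
  expect_true(all(diff(hets) < 0))
  expect_error(self_locus_dist(aa, -1), "non-negative")
})

test_that("DH pools gametes over classes; testcross convolves with the tester", {
  expect_equal(dh_locus_dist(c(0, 1, 0)), c(0.5, 0, 0.5))
  expect_equal(dh_locus_dist(c(0.25, 0.5, 0.25)), c(0.5, 0, 0.5))
  expect_equal(dh_locus_dist(c(1, 0, 0)), c(1, 0, 0))
  expect_error(dh_locus_dist(rep(0.2, 5)), "ploidy 2")

  # family all dosage 0, tester at ploidy -> all hybrids at phi/2
  expect_equal(testcross_locus_dist(c(1, 0, 0), 2, 2), c(0, 1, 0))
  # (1/2 AA, 1/2 aa) x Aa tester: mixture-then-convolve by hand
  expect_equal(testcross_locus_dist(c(0.5, 0, 0.5), 1, 2),
               c(0.25, 0.5, 0.25))
  # tester homozygous 0: hybrid distribution = family gamete distribution
  fam <- c(0.1, 0.6, 0.3)
  gam <- drop(gamete_dist_matrix(0:2, 2) %*% fam)
  expect_equal(testcross_locus_dist(fam, 0, 2), c(gam, 0))
  expect_error(testcross_locus_dist(fam, 7, 2), "tester dosage")
})

test_that("family_locus_dists composes the pipeline and keeps unit mass", {
  pan <- toy_phased_panel()
  f1 <- family_locus_dists(pan, c(3, 4), cross_scheme("F1"))
  expect_equal(family_locus_dists(pan, c(3, 4), cross_scheme("CLONE")), f1)
  expect_equal(family_locus_dists(pan, c(3, 4), cross_scheme("SELF", t = 0)), f1)
  for (sch in list(cross_scheme("DH"), cross_scheme("SELF", t = 2),
                   cross_scheme("CLONE", testers = 1L))) {
    D <- family_locus_dists(pan, c(3, 4), sch)
    expect_equal(unname(colSums(D)), rep(1, pan$n_loci))
    expect_true(all(D >= 0))
  }
  pan4 <- ld_panel4(n_loci = 12, n_genotypes = 6)
  D4 <- family_locus_dists(pan4, c(1, 2), cross_scheme("SELF", t = 3))
  expect_equal(unname(colSums(D4)), rep(1, 12), tolerance = 1e-12)
})

test_that("SELF and DH conserve the marginal allele frequency", {
  pan <- toy_phased_panel()
  freq_of <- function(D) colSums(D * 0:2) / 2
  f1 <- family_locus_dists(pan, c(3, 4), cross_scheme("F1"))
  expect_equal(freq_of(family_locus_dists(pan, c(3, 4), cross_scheme("SELF", t = 4))),
               freq_of(f1))
  expect_equal(freq_of(family_locus_dists(pan, c(3, 4), cross_scheme("DH"))),
               freq_of(f1))
  # DH heterozygosity is exactly zero
  expect_equal(unname(family_locus_dists(pan, c(3, 4), cross_scheme("DH"))[2, ]),
               rep(0, 6))
})

test_that("simulated recombinant fraction matches the Haldane closed form", {
  map <- genetic_map(data.frame(marker = c("a", "b"), chrom = 1,
                                pos_cM = c(0, 10)))
  dos <- rbind(P1 = c(2, 2), P2 = c(0, 0))
  colnames(dos) <- map$marker
  pan <- parent_panel(dos, map)
  n <- 1e5
  dosim <- simulate_progeny(pan, c(1, 2), cross_scheme("DH"), n, seed = 99)
  # coupling-phase F1; a DH is recombinant when the two loci disagree
  rec <- mean(dosim[, 1] != dosim[, 2])
  c10 <- 0.5 * (1 - exp(-0.2))
  expect_lt(abs(rec - c10), 3 * sqrt(c10 * (1 - c10) / n))
})

test_that("simulator matches per-locus class distributions (chi-square GOF)", {
  pan <- ld_panel(n_loci = 24, lines = 8, seed = 3)
  pan4 <- ld_panel4(n_loci = 24, n_genotypes = 8, seed = 4)
  n <- 2e4
  cases <- list(
    list(pan, cross_scheme("DH")),
    list(pan, cross_scheme("SELF", t = 3)),
    list(pan, cross_scheme("CLONE", testers = 10L)),
    list(pan4, cross_scheme("CLONE")),
    list(pan4, cross_scheme("SELF", t = 2, testers = 5L)))
  for (cs in cases) {
    p <- cs[[1]]; sch <- cs[[2]]
    pair <- c(1, 2)
    D <- family_locus_dists(p, pair, sch)
    dos <- simulate_progeny(p, pair, sch, n, seed = 123)
    pvals <- vapply(seq_len(p$n_loci), function(j) {
      exp_p <- D[, j]
      obs <- tabulate(dos[, j] + 1, nbins = p$ploidy + 1)
      keep <- exp_p > 1e-9
      if (sum(keep) < 2) return(1)
      suppressWarnings(stats::chisq.test(obs[keep], p = exp_p[keep] /
                                           sum(exp_p[keep]))$p.value)
    }, numeric(1))
    # calibration: at alpha = 0.001 allow a small flake budget
    expect_lte(sum(pvals < 0.001), 2)
  }
})

test_that("simulator is reproducible and honors trivial edge cases", {
  pan <- toy_phased_panel()
  a <- simulate_progeny(pan, c(1, 2), cross_scheme("SELF", t = 2), 50, seed = 5)
  b <- simulate_progeny(pan, c(1, 2), cross_scheme("SELF", t = 2), 50, seed = 5)
  expect_identical(a, b)
  # homozygous parents, clonal F1: all progeny identical
  f1 <- simulate_progeny(pan, c(1, 2), cross_scheme("CLONE"), 20, seed = 1)
  expect_true(all(apply(f1, 2, function(x) length(unique(x)) == 1)))
  # progeny allele frequency matches the parental mean within 3 MC SE
  n <- 2e4
  dos <- simulate_progeny(pan, c(3, 4), cross_scheme("CLONE"), n, seed = 2)
  pf <- colMeans(dos) / 2
  pp <- (pan$dosages[3, ] + pan$dosages[4, ]) / 4
  expect_true(all(abs(pf - pp) < 3 * sqrt(pmax(pp * (1 - pp), 0.01) / (2 * n))))
  # unphased heterozygous parent falls back to random phase with a warning
  pan_u <- parent_panel(pan$dosages, pan$map)
  expect_warning(simulate_progeny(pan_u, c(1, 4), cross_scheme("CLONE"), 5),
                 "random consistent phase")
})
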