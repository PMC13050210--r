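# Selection intensity, fitness, feasibility, and the GA+SA search.

test_that("selection intensity matches the normal-tail formula", {
  expect_equal(selection_intensity(1), 0)
  expect_equal(selection_intensity(0.5), dnorm(0) / 0.5, tolerance = 1e-9)
  expect_equal(selection_intensity(0.1), 1.755, tolerance = 1e-3)
  expect_error(selection_intensity(0), "in \\(0, 1\\]")
})

make_toy_predictions <- function() {
  structure(tibble::tibble(
    parent1 = c("A", "A", "A", "B", "B", "C"),
    parent2 = c("B", "C", "D", "C", "D", "D"),
    mean = c(1, 2, 3, 1.5, 0.5, 2.5),
    variance = c(1, 4, 0.25, 1, 2.25, 1),
    sd = sqrt(c(1, 4, 0.25, 1, 2.25, 1)),
    usefulness = NA_real_, ld_model = "independent", scheme = "DH"),
    accuracy = 1)
}

test_that("plan fitness averages usefulness and rewards replication", {
  preds <- make_toy_predictions()
  cs <- constraint_set(total_crosses = 3, selected_per_family = 10,
                       progeny_per_cross = 100)
  plan <- mating_plan(c("A", "A", "B"), c("B", "C", "C"))
  fr <- plan_fitness(plan, preds, cs)
  i1 <- selection_intensity(10 / 100)
  expect_equal(fr$fitness, mean(c(1 + i1 * 1, 2 + i1 * 2, 1.5 + i1 * 1)))
  # doubling a family's crosses raises its usefulness
  cs2 <- constraint_set(total_crosses = 2)
  single <- plan_fitness(mating_plan("A", "C", 1),
                         preds, constraint_set(total_crosses = 1))
  doubled <- plan_fitness(mating_plan("A", "C", 2), preds, cs2)
  expect_gt(doubled$usefulness[1], single$usefulness[1])
  expect_error(plan_fitness(mating_plan("A", "Z"), preds, cs2),
               "without predictions")
})

test_that("feasibility flags every constraint", {
  preds <- make_toy_predictions()
  pan <- ld_panel(n_loci = 30, lines = 2, seed = 41)  # 4 parents
  G <- grm(pan); rownames(G) <- colnames(G) <- c("A", "B", "C", "D")
  plan <- mating_plan(c("A", "A"), c("B", "B"))      # merged: 2 crosses of A-B
  cs <- constraint_set(total_crosses = 2, allow_repeats = FALSE)
  f <- check_feasibility(plan, cs, G)
  expect_false(f$flags[["repeats"]])
  cs2 <- constraint_set(total_crosses = 2, forbidden = data.frame(p1 = "B", p2 = "A"))
  f2 <- check_feasibility(plan, cs2, G)
  expect_false(f2$flags[["forbidden"]])
  cs3 <- constraint_set(total_crosses = 2, parent_max = 1)
  expect_false(check_feasibility(plan, cs3, G)$flags[["parent_max"]])
  cs4 <- constraint_set(total_crosses = 2, propsd_cutoff = 1e-6)
  f4 <- check_feasibility(plan, cs4, G)
  expect_false(f4$flags[["propsd"]])
  expect_gt(f4$propsd, 0)
  ok <- check_feasibility(mating_plan(c("A", "C"), c("B", "D")),
                          constraint_set(total_crosses = 2, propsd_cutoff = 1), G)
  expect_true(ok$feasible)
})

test_that("exhaustive search respects constraints on a crafted toy", {
  preds <- make_toy_predictions()
  cs <- constraint_set(total_crosses = 1)
  ex <- exhaustive_search(preds, cs)
  expect_equal(ex$plan$parent1, "A")   # A-C has the best usefulness
  expect_equal(ex$plan$parent2, "C")
  # forbidding the best pair lowers the optimum
  cs_f <- constraint_set(total_crosses = 1,
                         forbidden = data.frame(p1 = "A", p2 = "C"))
  ex2 <- exhaustive_search(preds, cs_f)
  expect_lt(ex2$fitness, ex$fitness)
  expect_error(exhaustive_search(preds, constraint_set(total_crosses = 20),
                                 max_space = 10), "too large")
})

test_that("GA+SA attains the exhaustive optimum on enumerable instances", {
  pan <- ld_panel(n_loci = 40, lines = 10, seed = 43)
  eff <- simulate_effects(pan, n_qtl = 20, seed = 6)$YLD
  G <- grm(pan)
  preds <- predict_all_crosses(pan, cross_scheme("DH"), eff,
                               ld_model = "independent",
                               pairs = cbind(1:6, 7:12))
  cs <- constraint_set(total_crosses = 3, propsd_cutoff = 1)
  ex <- exhaustive_search(preds, cs, G_pool = G)
  hits <- 0
  for (s in 1:20) {
    o <- optimize_matings(preds, cs,
                          optimizer_config(population_size = 60,
                                           max_iterations = 120,
                                           convergence_patience = 25,
                                           seed = s), G_pool = G)
    hits <- hits + (abs(o$fitness - ex$fitness) < 1e-9)
    if (s == 1) {
      # determinism and agreement between the fast scorer and plan_fitness
      o2 <- optimize_matings(preds, cs,
                             optimizer_config(population_size = 60,
                                              max_iterations = 120,
                                              convergence_patience = 25,
                                              seed = s), G_pool = G)
      expect_identical(o$plan, o2$plan)
      expect_identical(o$trace, o2$trace)
      expect_equal(o$fitness,
                   plan_fitness(o$plan, preds, cs, G_pool = G)$fitness)
    }
  }
  expect_gte(hits, 19)
})

test_that("optimizer never returns an infeasible plan; trace is monotone", {
  pan <- ld_panel(n_loci = 40, lines = 8, seed = 47)
  eff <- simulate_effects(pan, n_qtl = 20, seed = 7)$YLD
  G <- grm(pan)
  preds <- predict_all_crosses(pan, cross_scheme("DH"), eff,
                               ld_model = "independent")
  cs <- constraint_set(total_crosses = 4, propsd_cutoff = 0.15)
  o <- optimize_matings(preds, cs,
                        optimizer_config(population_size = 50,
                                         max_iterations = 80, seed = 3),
                        G_pool = G)
  expect_true(o$report$feasible)
  expect_lt(o$report$propsd, 0.15)
  expect_true(all(diff(o$trace$best_fitness) >= -1e-12))
})

test_that("raising the PropSD cutoff never lowers the attainable optimum", {
  pan <- ld_panel(n_loci = 40, lines = 6, seed = 53)
  eff <- simulate_effects(pan, n_qtl = 20, seed = 9)$YLD
  G <- grm(pan)
  preds <- predict_all_crosses(pan, cross_scheme("DH"), eff,
                               ld_model = "independent",
                               pairs = cbind(c(1, 1, 2, 3), c(2, 3, 4, 5)))
  fits <- vapply(c(0.05, 0.2, 1), function(cut) {
    cs <- constraint_set(total_crosses = 2, propsd_cutoff = cut)
    out <- tryCatch(exhaustive_search(preds, cs, G_pool = G)$fitness,
                    error = function(e) -Inf)
    out
  }, numeric(1))
  expect_true(all(diff(fits) >= -1e-12))
})

test_that("testcross objective is consistent with scheme-level testers", {
  pan <- ld_panel(n_loci = 30, lines = 6, seed = 59)
  eff <- simulate_effects(pan, n_qtl = 15, seed = 10)$YLD
  sch <- cross_scheme("CLONE")
  a <- testcross_objective(pan, sch, eff, testers = 9L, ld_model = "independent",
                           pairs = cbind(1:3, 4:6))
  b <- predict_all_crosses(pan, cross_scheme("CLONE", testers = 9L), eff,
                           ld_model = "independent", pairs = cbind(1:3, 4:6))
  expect_equal(a$usefulness, b$usefulness)
  # homozygous tester, additive effects: hybrid mean = half the family
  # additive mean plus the tester's constant gamete contribution
  effA <- trait_effects(eff$additive)
  hy <- predict_all_crosses(pan, cross_scheme("CLONE", testers = 9L), effA,
                            ld_model = "independent", pairs = cbind(1, 4))
  fam <- predict_all_crosses(pan, cross_scheme("CLONE"), effA,
                             ld_model = "independent", pairs = cbind(1, 4))
  tester_part <- sum(effA$additive * pan$dosages[9, ] / 2)
  expect_equal(hy$mean, fam$mean / 2 + tester_part, tolerance = 1e-9)
  expect_error(testcross_objective(pan, sch, eff, testers = 99L), "invalid")
})
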