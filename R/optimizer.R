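# Constrained mating-plan optimization: usefulness-based fitness with a
# PropSD diversity cutoff, searched by a hybrid genetic algorithm with
# simulated-annealing acceptance.

#' Within-family selection intensity
#'
#' Infinite-population normal approximation: i = phi(z)/p with
#' z = qnorm(1 - p); i = 0 at p = 1 (no selection).
#'
#' @param p selected proportion in (0, 1] (vectorized).
#' @return numeric selection intensity.
#' @export
selection_intensity <- function(p) {
  assert_that(all(p > 0 & p <= 1), "selected proportion must be in (0, 1]")
  ifelse(p >= 1, 0, dnorm(qnorm(1 - p)) / p)
}

#' Constraint set for mating-plan optimization
#'
#' @param total_crosses fixed total number of crosses (budget), >= 1.
#' @param allow_repeats may a family receive more than one cross?
#' @param n_families optional fixed count or `c(min, max)` range of families.
#' @param parent_min,parent_max optional per-parent bounds on the number of
#'   crosses a parent takes part in (scalar or named vector).
#' @param forbidden optional 2-column matrix/data frame of forbidden pairs
#'   (parent names); `allowed` restricts to an explicit whitelist.
#' @param allowed optional 2-column whitelist of pairs.
#' @param propsd_cutoff acceptable PropSD in [0, 1] (1 disables the
#'   diversity constraint).
#' @param selected_per_family individuals selected within each family (drives
#'   the selection intensity).
#' @param progeny_per_cross progeny produced by one cross.
#' @return list of class `constraint_set`.
#' @export
constraint_set <- function(total_crosses, allow_repeats = TRUE,
                           n_families = NULL, parent_min = NULL,
                           parent_max = NULL, forbidden = NULL, allowed = NULL,
                           propsd_cutoff = 1, selected_per_family = 10,
                           progeny_per_cross = 100) {
  assert_that(is_count(total_crosses, 1), "total_crosses must be >= 1")
  assert_that(propsd_cutoff >= 0 && propsd_cutoff <= 1,
              "propsd_cutoff must be in [0, 1]")
  if (!is.null(n_families)) {
    assert_that(length(n_families) <= 2 && all(n_families >= 1),
                "n_families must be a count or a range")
    if (length(n_families) == 1) n_families <- c(n_families, n_families)
  }
  structure(list(total_crosses = as.integer(total_crosses),
                 allow_repeats = isTRUE(allow_repeats),
                 n_families = n_families,
                 parent_min = parent_min, parent_max = parent_max,
                 forbidden = forbidden, allowed = allowed,
                 propsd_cutoff = propsd_cutoff,
                 selected_per_family = selected_per_family,
                 progeny_per_cross = progeny_per_cross),
            class = "constraint_set")
}

#' Optimizer hyperparameters
#'
#' @param population_size,n_elite GA population and elite sizes.
#' @param max_iterations,convergence_patience stopping rules.
#' @param mutation_rate,crossover_rate operator probabilities.
#' @param temp_init,cooling simulated-annealing initial temperature and
#'   geometric cooling factor in (0, 1).
#' @param seed integer seed (reproducibility contract).
#' @param penalty_fitness large negative sentinel assigned to infeasible plans.
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(population_size = 100, n_elite = 10,
                             max_iterations = 200, convergence_patience = 30,
                             mutation_rate = 0.2, crossover_rate = 0.8,
                             temp_init = 1, cooling = 0.98, seed = 1,
                             penalty_fitness = -1e9) {
  assert_that(cooling > 0 && cooling < 1, "cooling factor must be in (0, 1)")
  assert_that(n_elite >= 1 && population_size > n_elite,
              "population must exceed the elite count")
  structure(as.list(environment()), class = "optimizer_config")
}

#' Assemble a mating plan
#'
#' Canonical form: unordered pairs with multiplicities, pair order sorted
#' lexicographically; duplicates are merged into `n_crosses`.
#'
#' @param parent1,parent2 parent names per family.
#' @param n_crosses crosses per family (>= 1).
#' @return tibble of class `mating_plan`.
#' @export
mating_plan <- function(parent1, parent2, n_crosses = 1) {
  swap <- parent2 < parent1
  tmp <- parent1[swap]; parent1[swap] <- parent2[swap]; parent2[swap] <- tmp
  pl <- tibble::tibble(parent1 = parent1, parent2 = parent2,
                       n_crosses = as.integer(n_crosses)) |>
    dplyr::group_by(.data$parent1, .data$parent2) |>
    dplyr::summarise(n_crosses = sum(.data$n_crosses), .groups = "drop") |>
    dplyr::arrange(.data$parent1, .data$parent2)
  assert_that(all(pl$n_crosses >= 1), "n_crosses must be >= 1")
  class(pl) <- c("mating_plan", class(pl))
  pl
}

# Contribution-weighted multiset of selected parents.
plan_parent_multiset <- function(plan) {
  c(rep(plan$parent1, plan$n_crosses), rep(plan$parent2, plan$n_crosses))
}

#' Feasibility of a mating plan
#'
#' Checks the plan against every constraint (total crosses, repeats, family
#' count, parent bounds, forbidden/allowed pairs, PropSD cutoff). Flags, not
#' exceptions.
#'
#' @param plan a [mating_plan()].
#' @param constraints a [constraint_set()].
#' @param G_pool pool relationship matrix (needed for the PropSD flag).
#' @return list with `feasible`, per-constraint logical `flags`, and `propsd`.
#' @export
check_feasibility <- function(plan, constraints, G_pool = NULL) {
  cs <- constraints
  flags <- c(total = sum(plan$n_crosses) == cs$total_crosses,
             repeats = cs$allow_repeats || all(plan$n_crosses == 1))
  if (!is.null(cs$n_families)) {
    flags["n_families"] <- nrow(plan) >= cs$n_families[1] &&
      nrow(plan) <= cs$n_families[2]
  }
  cnt <- table(plan_parent_multiset(plan)) / 1  # crosses per parent
  if (!is.null(cs$parent_max)) {
    pm <- cs$parent_max
    lim <- if (is.null(names(pm))) rep(pm, length(cnt)) else
      pm[names(cnt)]
    flags["parent_max"] <- all(cnt <= lim, na.rm = TRUE)
  }
  if (!is.null(cs$parent_min)) {
    pmn <- cs$parent_min
    lim <- if (is.null(names(pmn))) rep(pmn, length(cnt)) else pmn[names(cnt)]
    flags["parent_min"] <- all(cnt >= lim, na.rm = TRUE)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (!is.null(cs$forbidden)) {
    bad <- key(as.character(cs$forbidden[[1]]), as.character(cs$forbidden[[2]]))
    flags["forbidden"] <- !any(key(plan$parent1, plan$parent2) %in% bad)
  }
  if (!is.null(cs$allowed)) {
    ok <- key(as.character(cs$allowed[[1]]), as.character(cs$allowed[[2]]))
    flags["allowed"] <- all(key(plan$parent1, plan$parent2) %in% ok)
  }
  propsd <- NA_real_
  if (!is.null(G_pool) && cs$propsd_cutoff < 1) {
    sel <- match(plan_parent_multiset(plan), rownames(G_pool))
    propsd <- prop_sd(G_pool, sel)
    flags["propsd"] <- propsd < cs$propsd_cutoff
  } else if (!is.null(G_pool)) {
    sel <- match(plan_parent_multiset(plan), rownames(G_pool))
    propsd <- prop_sd(G_pool, sel)
  }
  list(feasible = all(flags), flags = flags, propsd = propsd)
}

# Lookup environment from a cross-predictions table.
prediction_lookup <- function(predictions) {
  key <- paste(pmin(predictions$parent1, predictions$parent2),
               pmax(predictions$parent1, predictions$parent2), sep = "\r")
  list(key = key,
       mean = setNames(predictions$mean, key),
       sd = setNames(predictions$sd, key))
}

#' Fitness of a mating plan
#'
#' Per family, the selected proportion is selected_per_family /
#' (n_crosses x progeny_per_cross) -- replicating a cross enlarges the family
#' and raises the within-family selection intensity -- and the usefulness is
#' mean + i r sd. The plan fitness is the average usefulness across families
#' (`weight_by_crosses` weights by n_crosses instead). Infeasible plans get
#' the penalty sentinel.
#'
#' @param plan a [mating_plan()].
#' @param predictions a [predict_all_crosses()] table covering the plan's
#'   families.
#' @param constraints a [constraint_set()].
#' @param G_pool pool relationship matrix for the PropSD constraint.
#' @param r prediction accuracy (defaults to the predictions' attribute).
#' @param penalty fitness assigned to infeasible plans.
#' @param weight_by_crosses weight family usefulness by n_crosses.
#' @return list of class `fitness_report`: `fitness`, `usefulness` (per
#'   family), `propsd`, `feasible`, `flags`.
#' @export
plan_fitness <- function(plan, predictions, constraints, G_pool = NULL,
                         r = NULL, penalty = -1e9,
                         weight_by_crosses = FALSE) {
  lk <- prediction_lookup(predictions)
  r <- r %||% attr(predictions, "accuracy") %||% 1
  key <- paste(pmin(plan$parent1, plan$parent2),
               pmax(plan$parent1, plan$parent2), sep = "\r")
  assert_that(all(key %in% lk$key),
              "plan contains families without predictions")
  p_sel <- pmin(1, constraints$selected_per_family /
                  (plan$n_crosses * constraints$progeny_per_cross))
  uf <- usefulness(lk$mean[key], lk$sd[key]^2, selection_intensity(p_sel), r)
  feas <- check_feasibility(plan, constraints, G_pool)
  wt <- if (weight_by_crosses) plan$n_crosses else rep(1, nrow(plan))
  fit <- if (feas$feasible) sum(uf * wt) / sum(wt) else penalty
  structure(list(fitness = fit, usefulness = unname(uf),
                 propsd = feas$propsd, feasible = feas$feasible,
                 flags = feas$flags),
            class = "fitness_report")
}

# ---------------------------------------------------------------------------
# search

# Internal pair universe: predictions rows minus forbidden / outside-whitelist.
allowed_pair_ids <- function(predictions, constraints) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keep <- rep(TRUE, nrow(predictions))
  k <- key(predictions$parent1, predictions$parent2)
  if (!is.null(constraints$forbidden)) {
    bad <- key(as.character(constraints$forbidden[[1]]),
               as.character(constraints$forbidden[[2]]))
    keep <- keep & !(k %in% bad)
  }
  if (!is.null(constraints$allowed)) {
    ok <- key(as.character(constraints$allowed[[1]]),
              as.character(constraints$allowed[[2]]))
    keep <- keep & (k %in% ok)
  }
  which(keep)
}

plan_from_ids <- function(ids, predictions) {
  mating_plan(predictions$parent1[ids], predictions$parent2[ids])
}

#' Optimize a mating plan (genetic algorithm + simulated annealing)
#'
#' Searches multisets of `total_crosses` crosses over the allowed pairs for
#' maximal average usefulness subject to the constraint set. Candidates are
#' scored with [plan_fitness()] (penalty sentinel when infeasible); the best
#' plans are kept as elites, inferior plans may enter the breeding pool with
#' annealed probability, and new candidates arise by crossover (exchanging
#' cross subsets) and mutation (replace a cross, swap one parent, shift a
#' cross between families). Deterministic under `config$seed`.
#'
#' @param predictions a [predict_all_crosses()] table.
#' @param constraints a [constraint_set()].
#' @param config an [optimizer_config()].
#' @param G_pool pool relationship matrix for the PropSD constraint.
#' @param r prediction accuracy (defaults to the predictions' attribute).
#' @return list of class `mating_plan_result`: `plan`, `fitness`, `report`,
#'   `trace` (tibble iteration/best fitness), `n_evaluated`.
#' @export
optimize_matings <- function(predictions, constraints,
                             config = optimizer_config(), G_pool = NULL,
                             r = NULL) {
  set.seed(config$seed)
  cs <- constraints
  ids_all <- allowed_pair_ids(predictions, cs)
  assert_that(length(ids_all) >= 1, "no allowed pairs to optimize over")
  tc <- cs$total_crosses
  if (!cs$allow_repeats)
    assert_that(length(ids_all) >= tc,
                "not enough allowed pairs for total_crosses without repeats")
  parents_by_id <- cbind(predictions$parent1, predictions$parent2)

  # fast scorer on sorted id-multisets (mirrors plan_fitness exactly; the
  # tibble-based path stays the public, audited surface)
  parents <- sort(unique(c(predictions$parent1, predictions$parent2)))
  ip1 <- match(predictions$parent1, parents)
  ip2 <- match(predictions$parent2, parents)
  r_acc <- r %||% attr(predictions, "accuracy") %||% 1
  gidx <- if (!is.null(G_pool)) match(parents, rownames(G_pool)) else NULL
  e_pool <- if (!is.null(G_pool)) expected_sample_sd(G_pool)$expected_sd else NA
  pmax_v <- if (!is.null(cs$parent_max)) {
    if (is.null(names(cs$parent_max))) rep(cs$parent_max, length(parents)) else
      cs$parent_max[parents]
  } else NULL
  pmin_v <- if (!is.null(cs$parent_min)) {
    if (is.null(names(cs$parent_min))) rep(cs$parent_min, length(parents)) else
      cs$parent_min[parents]
  } else NULL
  fast_score <- function(ids) {
    rl <- rle(ids)
    fam <- rl$values; ncr <- rl$lengths
    if (!cs$allow_repeats && any(ncr > 1)) return(config$penalty_fitness)
    if (!is.null(cs$n_families) &&
        (length(fam) < cs$n_families[1] || length(fam) > cs$n_families[2]))
      return(config$penalty_fitness)
    if (!is.null(pmax_v) || !is.null(pmin_v)) {
      cnt <- tabulate(c(rep(ip1[fam], ncr), rep(ip2[fam], ncr)),
                      nbins = length(parents))
      if (!is.null(pmax_v) && any(cnt > pmax_v, na.rm = TRUE))
        return(config$penalty_fitness)
      if (!is.null(pmin_v) && any(cnt < pmin_v, na.rm = TRUE))
        return(config$penalty_fitness)
    }
    if (!is.null(G_pool) && cs$propsd_cutoff < 1) {
      sel <- gidx[c(rep(ip1[fam], ncr), rep(ip2[fam], ncr))]
      psd <- 1 - expected_sample_sd(G_pool[sel, sel, drop = FALSE])$expected_sd /
        e_pool
      if (!(psd < cs$propsd_cutoff)) return(config$penalty_fitness)
    }
    p_sel <- pmin(1, cs$selected_per_family / (ncr * cs$progeny_per_cross))
    uf <- predictions$mean[fam] + selection_intensity(p_sel) * r_acc *
      predictions$sd[fam]
    mean(uf)
  }

  sample_plan <- function() {
    nf <- if (!is.null(cs$n_families))
      sample(cs$n_families[1]:min(cs$n_families[2], tc), 1) else
        if (cs$allow_repeats) sample.int(tc, 1) else tc
    fam <- sample(ids_all, min(nf, length(ids_all)),
                  replace = FALSE)
    sort(c(fam, sample(fam, tc - length(fam), replace = TRUE)))
  }
  score <- fast_score
  mutate_ids <- function(ids) {
    op <- sample.int(3L, 1L)
    slot <- sample.int(tc, 1L)
    if (op == 1L) {            # replace one cross with a random allowed pair
      ids[slot] <- sample(ids_all, 1L)
    } else if (op == 2L) {     # swap one parent of one cross
      pr <- parents_by_id[ids[slot], ]
      keep <- pr[sample.int(2L, 1L)]
      cand <- ids_all[parents_by_id[ids_all, 1] == keep |
                        parents_by_id[ids_all, 2] == keep]
      if (length(cand)) ids[slot] <- cand[sample.int(length(cand), 1L)]
    } else {                   # move a cross onto another existing family
      ids[slot] <- ids[sample.int(tc, 1L)]
    }
    if (!cs$allow_repeats && anyDuplicated(ids)) {
      dup <- which(duplicated(ids))
      pool <- setdiff(ids_all, ids)
      if (length(pool) >= length(dup))
        ids[dup] <- sample(pool, length(dup))
    }
    sort(ids)
  }
  crossover_ids <- function(a, b) {
    pool <- c(a, b)
    if (!cs$allow_repeats) {
      pool <- unique(pool)
      if (length(pool) < tc) pool <- c(pool, setdiff(ids_all, pool))
      sort(sample(pool, tc))
    } else {
      sort(sample(pool, tc, replace = FALSE))
    }
  }

  pop <- replicate(config$population_size, sample_plan(), simplify = FALSE)
  fit <- vapply(pop, score, numeric(1))
  n_eval <- length(pop)
  best_fit <- -Inf; best_ids <- NULL
  trace <- numeric(0)
  stall <- 0L
  temp <- config$temp_init
  for (iter in seq_len(config$max_iterations)) {
    ord <- order(fit, decreasing = TRUE)
    pop <- pop[ord]; fit <- fit[ord]
    if (fit[1] > best_fit + 1e-12) {
      best_fit <- fit[1]; best_ids <- pop[[1]]; stall <- 0L
    } else stall <- stall + 1L
    trace <- c(trace, best_fit)
    if (stall >= config$convergence_patience) break
    elite <- pop[seq_len(config$n_elite)]
    # annealed acceptance of inferior plans into the breeding pool
    rest <- seq(config$n_elite + 1, length(pop))
    accept <- runif(length(rest)) <
      exp(pmin(0, (fit[rest] - fit[config$n_elite]) / max(temp, 1e-8)))
    breeders <- c(elite, pop[rest[accept]])
    if (length(breeders) < 2) breeders <- pop[1:2]
    offspring <- lapply(seq_len(config$population_size - config$n_elite),
                        function(i) {
      if (runif(1) < config$crossover_rate) {
        ab <- sample.int(length(breeders), 2, replace = TRUE)
        ids <- crossover_ids(breeders[[ab[1]]], breeders[[ab[2]]])
      } else {
        ids <- breeders[[sample.int(length(breeders), 1)]]
      }
      if (runif(1) < config$mutation_rate) ids <- mutate_ids(ids)
      ids
    })
    pop <- c(elite, offspring)
    fit <- c(fit[seq_len(config$n_elite)],
             vapply(offspring, score, numeric(1)))
    n_eval <- n_eval + length(offspring)
    temp <- temp * config$cooling
  }
  plan <- plan_from_ids(best_ids, predictions)
  report <- plan_fitness(plan, predictions, cs, G_pool = G_pool, r = r,
                         penalty = config$penalty_fitness)
  structure(list(plan = plan, fitness = best_fit, report = report,
                 trace = tibble::tibble(iteration = seq_along(trace),
                                        best_fitness = trace),
                 n_evaluated = n_eval),
            class = "mating_plan_result")
}

#' @export
print.mating_plan_result <- function(x, ...) {
  cat(sprintf("<mating_plan_result> %d families, %d crosses, fitness %.4f, PropSD %.4f, %s\n",
              nrow(x$plan), sum(x$plan$n_crosses), x$fitness,
              x$report$propsd,
              if (x$report$feasible) "feasible" else "INFEASIBLE"))
  print(tibble::as_tibble(x$plan), n = 10)
  invisible(x)
}

#' Exhaustive mating-plan search (test oracle)
#'
#' Enumerates every multiset of `total_crosses` allowed pairs (combinations
#' without repetition when repeats are disabled), scores the feasible ones,
#' and returns the argmax; ties break toward the lexicographically smallest
#' plan encoding. Guarded to small search spaces.
#'
#' @inheritParams optimize_matings
#' @param max_space refuse to enumerate more plans than this.
#' @return list with `plan`, `fitness`, `report`, `n_plans`.
#' @export
exhaustive_search <- function(predictions, constraints, G_pool = NULL,
                              r = NULL, max_space = 1e6) {
  cs <- constraints
  ids_all <- allowed_pair_ids(predictions, cs)
  m <- length(ids_all); tc <- cs$total_crosses
  n_plans <- if (cs$allow_repeats) choose(m + tc - 1, tc) else choose(m, tc)
  assert_that(n_plans >= 1, "no plans to enumerate")
  assert_that(n_plans <= max_space,
              "search space too large; use optimize_matings()")
  combos <- if (cs$allow_repeats) {
    multiset_combn(m, tc)
  } else {
    utils::combn(m, tc, simplify = FALSE)
  }
  best <- NULL; best_fit <- -Inf
  for (cb in combos) {
    ids <- sort(ids_all[cb])
    plan <- plan_from_ids(ids, predictions)
    rep_ <- plan_fitness(plan, predictions, cs, G_pool = G_pool, r = r)
    if (rep_$feasible && rep_$fitness > best_fit + 1e-12) {
      best_fit <- rep_$fitness; best <- list(plan = plan, report = rep_)
    }
  }
  assert_that(!is.null(best), "no feasible plan exists")
  list(plan = best$plan, fitness = best_fit, report = best$report,
       n_plans = length(combos))
}

# All multisets of size k from 1..m (combinations with repetition).
multiset_combn <- function(m, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, start) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in start:m) rec(c(prefix, v), v)
  }
  rec(integer(0), 1L)
  out
}

#' Testcross predictions aggregated over a tester set
#'
#' Convenience wrapper: attaches the tester set to the scheme and returns the
#' tester-averaged [predict_all_crosses()] table (usefulness is averaged over
#' testers per pair).
#'
#' @inheritParams predict_all_crosses
#' @param testers integer vector of tester parent indices.
#' @return a `cross_predictions` tibble.
#' @export
testcross_objective <- function(panel, scheme, effects, testers,
                                ld_model = "approx", ...) {
  assert_that(length(testers) >= 1 &&
                all(testers >= 1 & testers <= panel$n_parents),
              "invalid tester indices")
  scheme$testers <- testers
  predict_all_crosses(panel, scheme, effects, ld_model = ld_model, ...)
}
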