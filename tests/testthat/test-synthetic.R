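test_that("independence limit: zero loadings give no ground truth and no r", {
  spec <- class_spec("nul", n_taxa = 20, n_guilds = 2, guild_loading = 0,
                     antagonist_fraction = 0, antagonist_loading = 0,
                     noise_sd = 0.5)
  gen <- generate_class(spec, 200, seed = 1)
  expect_equal(nrow(gen$ground_truth), 0L)
  r <- cor(log(gen$community$biomass))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.08)
})

test_that("noiseless limit: shared unit loading gives r = 1", {
  spec <- class_spec("two", n_taxa = 2, n_guilds = 1, guild_loading = 1,
                     antagonist_fraction = 0, noise_sd = 1e-9)
  gen <- generate_class(spec, 50, seed = 2)
  expect_equal(gen$ground_truth$population_r, 1, tolerance = 1e-12)
  expect_equal(cor(log(gen$community$biomass))[1, 2], 1, tolerance = 1e-6)
})

test_that("population r follows the closed form and its sampling spread", {
  # a_i = a_j = 1, noise_sd = 1 -> population r = 1/sqrt(2*2) = 0.5
  spec <- class_spec("pair", n_taxa = 2, n_guilds = 1, guild_loading = 1,
                     antagonist_fraction = 0, noise_sd = 1)
  gen <- generate_class(spec, 84, seed = 3)
  expect_equal(gen$ground_truth$population_r, 0.5, tolerance = 1e-12)
  # Fisher-z oracle: sd(z) = 1/sqrt(81), |r - 0.5| < 0.2 with P ~ 0.97
  hits <- sapply(1:500, function(i) {
    g <- generate_class(spec, 84, seed = 10000 + i)
    abs(cor(log(g$community$biomass))[1, 2] - 0.5) < 0.2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("empirical log-scale correlations converge to the closed form", {
  spec <- default_class_specs()[[1]]
  gen <- generate_class(spec, 1000, seed = 4)
  r <- cor(log(gen$community$biomass))
  gt <- gen$ground_truth
  emp <- r[cbind(gt$taxon_a, gt$taxon_b)]
  expect_lt(max(abs(emp - gt$population_r)), 0.05 + 3 * 1 / sqrt(997))
  expect_lt(mean(abs(emp - gt$population_r)), 0.05)
  # default scenario pins ground-truth pairs at |population r| = 0.5
  expect_equal(unique(abs(round(gt$population_r, 10))), 0.5)
})

test_that("antagonists load negatively and appear as negative pairs", {
  spec <- class_spec("ant", n_taxa = 10, n_guilds = 1, guild_loading = 0.6,
                     antagonist_fraction = 0.5, antagonist_loading = 0.6,
                     noise_sd = 0.4)
  gen <- generate_class(spec, 100, seed = 5)
  gt <- gen$ground_truth
  expect_setequal(unique(gt$sign), c("positive", "negative"))
  expect_true(all((gt$population_r > 0) == (gt$sign == "positive")))
  # member-antagonist pairs are 5*5 = 25 of the 45 pairs
  expect_equal(sum(gt$sign == "negative"), 25L)
})

test_that("biomass is positive and total-biomass scaling is exact", {
  spec <- default_class_specs()[[2]]
  gen <- generate_class(spec, 84, seed = 6)
  b <- gen$community$biomass
  expect_true(all(b > 0))
  expect_equal(mean(rowSums(b)), spec$biomass_scale, tolerance = 1e-12)
})

test_that("degenerate guild configurations are rejected", {
  expect_error(generate_class(class_spec("bad", n_taxa = 5, n_guilds = 3),
                              50, seed = 1),
               "non-degenerate")
  expect_error(class_spec("bad2", n_taxa = 10, guild_loading = 1.5))
  expect_error(class_spec("bad3", n_taxa = 10, noise_sd = 0))
})

test_that("generation is reproducible and seed-sensitive", {
  spec <- default_class_specs()[[1]]
  g1 <- generate_class(spec, 30, seed = 42)
  g2 <- generate_class(spec, 30, seed = 42)
  g3 <- generate_class(spec, 30, seed = 43)
  expect_identical(g1$community$biomass, g2$community$biomass)
  expect_false(identical(g1$community$biomass, g3$community$biomass))
  s1 <- generate_scenario(scenario_config(rng_seed = 9))
  s2 <- generate_scenario(scenario_config(rng_seed = 9))
  expect_identical(s1$community$biomass, s2$community$biomass)
  expect_identical(s1$environment$values, s2$environment$values)
})

test_that("winter temperatures track the configured winter mean", {
  spec <- default_class_specs()[[1]]   # CW: winter 5.63, annual 13.61
  # long monthly calendar so the per-date noise averages out
  calendar <- seq(as.Date("2000-01-15"), by = "month", length.out = 336)
  env <- generate_environment(spec, 1000, seed = 7, dates = calendar)
  winter <- as.integer(format(env$dates, "%m")) %in% c(12, 1, 2)
  expect_lt(abs(mean(env$values[winter, "Temperature"]) - 5.63), 1)
  expect_lt(abs(mean(env$values[, "Temperature"]) -
                  spec$annual_temp_mean), 1)
})

test_that("flat thermal profile with zero noise gives constant temperature", {
  spec <- class_spec("flat", n_taxa = 4, winter_temp_mean = 12,
                     winter_temp_sd = 1e-12, annual_temp_mean = 12,
                     env_profile = list(DO = c(9, 1)))
  env <- generate_environment(spec, 50, seed = 8)
  expect_lt(diff(range(env$values[, "Temperature"])), 1e-9)
})

test_that("temperature and dissolved oxygen are negatively rank-correlated", {
  spec <- default_class_specs()[[1]]
  rhos <- sapply(1:200, function(s) {
    e <- generate_environment(spec, 84, seed = s)
    rank_correlation(e$values[, "Temperature"], e$values[, "DO"])$rho
  })
  expect_gte(mean(rhos < 0), 0.95)
  expect_lt(abs(mean(rhos) - (-0.5)), 0.15)
})

test_that("station replicates of one date share one environmental row", {
  spec <- default_class_specs()[[3]]
  env <- generate_environment(spec, 84, seed = 11)
  split_rows <- split(seq_len(84), as.character(env$dates))
  for (rows in split_rows)
    expect_equal(max(apply(env$values[rows, , drop = FALSE], 2,
                           function(v) diff(range(v)))), 0)
})

test_that("default scenario matches the emulated study design", {
  sc <- generate_scenario(scenario_config(rng_seed = 13))
  cm <- sc$community
  expect_equal(n_samples(cm), 252L)
  expect_equal(as.integer(table(cm$class_label)), c(84L, 84L, 84L))
  # ~26% of the taxon union is common to all three classes
  sets <- lapply(split_by_class(cm), function(p)
    taxa_names(p)[colSums(p$biomass > 0) > 0])
  common <- Reduce(intersect, sets)
  union_n <- length(unique(unlist(sets)))
  expect_gt(length(common) / union_n, 0.20)
  expect_lt(length(common) / union_n, 0.32)
  expect_named(sc$ground_truth, c("CW", "MW", "WW"))
})

test_that("shared-fraction extremes force Jaccard similarity to 100 and 0", {
  eq_specs <- lapply(c("A", "B", "C"), function(nm)
    class_spec(nm, n_taxa = 20, n_guilds = 2, guild_coverage = 1,
               biomass_scale = 1, env_profile = list(DO = c(9, 1))))
  full <- generate_scenario(scenario_config(eq_specs, n_samples_per_class = 12,
                                            shared_fraction = 1,
                                            rng_seed = 2))
  jm <- jaccard_matrix(full$community)
  expect_true(all(jm == 100))
  none <- generate_scenario(scenario_config(eq_specs, n_samples_per_class = 12,
                                            shared_fraction = 0,
                                            rng_seed = 2))
  jm0 <- jaccard_matrix(none$community)
  expect_true(all(jm0[upper.tri(jm0)] == 0))
})

test_that("class seeds are order-independent", {
  specs <- default_class_specs()
  s1 <- generate_scenario(scenario_config(specs, rng_seed = 21))
  s2 <- generate_scenario(scenario_config(rev(specs), rng_seed = 21))
  cw1 <- split_by_class(s1$community)$CW
  cw2 <- split_by_class(s2$community)$CW
  # restrict to taxa present in CW (the union ordering differs by run)
  present <- sort(taxa_names(cw1)[colSums(cw1$biomass > 0) > 0])
  expect_identical(cw1$biomass[, present], cw2$biomass[, present])
})
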