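test_that("source pools are valid, deterministic, and SAD-shaped", {
  p <- make_source_pool(2, "dirichlet_uniform", seed = 1)
  expect_length(p$q, 2)
  expect_true(all(p$q > 0))
  expect_equal(sum(p$q), 1, tolerance = 1e-12)
  expect_identical(make_source_pool(40, seed = 9), make_source_pool(40, seed = 9))
  expect_error(make_source_pool(1), "S must be >= 2")

  # a long-tailed lognormal pool is more uneven than a tight one
  wide <- make_source_pool(300, "lognormal", list(sigma = 2), seed = 5)
  narrow <- make_source_pool(300, "lognormal", list(sigma = 0.5), seed = 5)
  expect_gt(oracle_gini(wide$q), oracle_gini(narrow$q))
  expect_gt(oracle_gini(wide$q), 0.8)
})

test_that("neutral simulation conserves depth and is a pure function of seed", {
  pool <- make_source_pool(60, seed = 2)
  cfg <- sim_config(60, 25, N_local = 500, m = 0.4, depth = 700, seed = 11)
  tab <- simulate_neutral_community(pool, cfg)
  expect_true(all(rowSums(unclass(tab)) == 700))
  expect_identical(unclass(simulate_neutral_community(pool, cfg)), unclass(tab))

  cfgd <- sim_config(60, 6, N_local = 200, m = 0.4, depth = 700,
                     mode = "dynamic", seed = 11)
  tabd <- simulate_neutral_community(pool, cfgd)
  expect_true(all(rowSums(unclass(tabd)) == 700))
  expect_identical(unclass(simulate_neutral_community(pool, cfgd)),
                   unclass(tabd))
})

test_that("m = 1 stationary communities track the source pool", {
  pool <- make_source_pool(40, seed = 6)
  cfg <- sim_config(40, 150, N_local = 1000, m = 1, depth = 3000, seed = 3)
  tab <- simulate_neutral_community(pool, cfg)
  mad_big <- mean(abs(colMeans(relative_abundance(tab)) - pool$q))
  cfg$n_samples <- 15L
  mad_small <- mean(abs(colMeans(relative_abundance(
    simulate_neutral_community(pool, cfg))) - pool$q))
  expect_lt(mad_big, 0.002)
  expect_lt(mad_big, mad_small + 1e-6)
})

test_that("simulated occurrence matches the Sloan prediction", {
  pool <- make_source_pool(150, "lognormal", list(sigma = 2), seed = 11)
  cfg <- sim_config(150, 200, N_local = 1000, m = 0.3, depth = 2000, seed = 4)
  tab <- simulate_neutral_community(pool, cfg)
  f_obs <- occurrence_frequency(tab)
  f_pred <- predict_frequency(mean_relative_abundance(tab), 0.3, 2000, 1)
  expect_lt(mean(abs(f_obs - f_pred)), 0.05)
})

test_that("selection injection behaves as documented", {
  pool <- make_source_pool(50, seed = 8)
  cfg <- sim_config(50, 10, N_local = 300, m = 0.3, depth = 500,
                    mode = "dynamic", seed = 2)
  expect_identical(inject_selection(cfg, "OTU5", 1), cfg)
  expect_error(simulate_neutral_community(
    pool, inject_selection(cfg, "OTUX", 2)), "unknown taxon")
  expect_error(simulate_neutral_community(
    pool, sim_config(50, 5, selection = c(OTU1 = 2), mode = "stationary")),
    "stationary")

  # a w = 5 taxon ends up over-represented relative to its source share
  tax <- pool$taxon_ids[which.min(abs(pool$q - stats::median(pool$q)))]
  wins <- 0
  for (r in 1:20) {
    cfgs <- inject_selection(sim_config(50, 8, N_local = 300, m = 0.3,
                                        depth = 1000, mode = "dynamic",
                                        seed = 100 + r), tax, 5)
    tb <- simulate_neutral_community(pool, cfgs)
    wins <- wins +
      (mean_relative_abundance(tb)[tax] > pool$q[match(tax, pool$taxon_ids)])
  }
  expect_gte(wins, 19)
})

test_that("the factorial experiment has the configured shape and ground truth", {
  preset <- perch_recovery_preset(S = 60, tanks = 2, replicates = 2,
                                  habitats = c("water", "gut"),
                                  timepoints = c("T0", "T3", "T5"),
                                  n_selected = 4, n_host_selected = 2,
                                  N_local = 300, depth = 500)
  sim <- simulate_experiment(preset, seed = 21)
  expect_equal(nrow(sim$metadata), 3 * 2 * 2 * 3 * 2)
  expect_equal(nrow(sim$counts), nrow(sim$metadata))
  expect_equal(ape::Ntip(sim$tree), 60)
  expect_setequal(unique(sim$truth$selected$type), c("cadmium", "host"))
  # habitats draw from distinct source pools
  expect_gt(mean(abs(sim$truth$pools$water$q - sim$truth$pools$gut$q)), 0)
  # determinism
  sim2 <- simulate_experiment(preset, seed = 21)
  expect_identical(unclass(sim2$counts), unclass(sim$counts))

  # control communities carry no cadmium selection at any time
  expect_true(all(preset$severity["Ctrl", ] == 0))
  # exposure peaks at T3 and relaxes afterwards for both regimes
  expect_true(all(preset$severity[c("CC", "CV"), "T3"] == 1))
  expect_true(all(preset$severity[c("CC", "CV"), "T5"] <
                    preset$severity[c("CC", "CV"), "TR1"]))
})

test_that("treatment separation is detectable at peak exposure but not under null", {
  # null: no selected taxa anywhere, so treatments are exchangeable
  null_sig <- 0
  for (s in 1:10) {
    preset <- perch_recovery_preset(S = 80, tanks = 3, replicates = 2,
                                    habitats = "water", timepoints = "T3",
                                    n_selected = 0, n_host_selected = 0,
                                    N_local = 300, depth = 800)
    sim <- simulate_experiment(preset, seed = 400 + s)
    dm <- gunifrac(sim$counts, sim$tree, 0.5)
    pa <- permanova(dm, sim$metadata$treatment, n_perm = 199, seed = s)
    null_sig <- null_sig + (pa$p_value <= 0.05)
  }
  expect_lte(null_sig, 1)

  # suppression of resident taxa at T3: CC vs Ctrl separates
  hits <- 0
  for (s in 1:5) {
    # (tanks x replicates gives 9 samples per treatment group)
    preset <- perch_recovery_preset(S = 80, tanks = 3, replicates = 3,
                                    habitats = "water", timepoints = "T3",
                                    n_selected = 16, cd_w = 0.05,
                                    n_host_selected = 0,
                                    N_local = 300, depth = 800)
    sim <- simulate_experiment(preset, seed = 500 + s)
    keep <- sim$metadata$treatment %in% c("Ctrl", "CC")
    dm <- gunifrac(count_table(unclass(sim$counts)[keep, , drop = FALSE]),
                   sim$tree, 0.5)
    pa <- permanova(dm, droplevels(sim$metadata$treatment[keep]),
                    n_perm = 199, seed = s)
    hits <- hits + (pa$p_value <= 0.05)
  }
  expect_gte(hits, 5 * 0.9 - 1)
})
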