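test_that("delta/atom% conversion matches the standard-ratio formula and is monotone", {
  expect_equal(delta_to_atom_percent(0), 0.36630, tolerance = 1e-4)
  expect_equal(delta_to_atom_percent(6), 0.36849, tolerance = 1e-4)
  expect_equal(delta_to_atom_percent(2.5), 0.36721, tolerance = 1e-4)
  d <- seq(-900, 900, by = 37)
  expect_true(all(diff(delta_to_atom_percent(d)) > 0))
  expect_error(delta_to_atom_percent(-1000), "-1000")
  expect_error(isotope_constants(natural_abundance_atom_pct = 0.40),
               "inconsistent")
})

test_that("source-pool delta follows the ambient-nitrate rule", {
  expect_equal(assign_source_delta("NO3", 0.2), 6)
  expect_equal(assign_source_delta("NO3", 1.0), 2.5)
  # the boundary concentration is treated as the high-nitrate case
  expect_equal(assign_source_delta("NO3", 0.5), 2.5)
  for (s in setdiff(SUBSTRATES, "NO3")) expect_equal(assign_source_delta(s), 0)
  expect_error(assign_source_delta("NO3"), "ambient_NO3")
})

test_that("source-pool enrichment mixes ambient and spike by concentration", {
  e <- source_pool_enrichment(1.0, 0.3663, 0.1, 98)
  expect_equal(e$atom_pct, 9.2421, tolerance = 1e-4)
  expect_length(e$flags, 0)
  # spike-dominated pool when the ambient is unmeasurable
  e2 <- source_pool_enrichment(0.4, 0.3663, 0.05, 98, ambient_below_dl = TRUE)
  expect_equal(e2$atom_pct, 98)
  expect_setequal(e2$flags, c("AMBIENT_BELOW_DL", "OVER_ENRICHED"))
  # vanishing spike recovers the ambient enrichment
  e3 <- source_pool_enrichment(1.0, 0.3663, 1e-12, 98)
  expect_equal(e3$atom_pct, 0.3663, tolerance = 1e-8)
})

test_that("mixing-model rates reproduce hand-computed values and identities", {
  expect_equal(absolute_uptake_rate(0.3663, 0.3663, 9.2421, 1, 1, 2), 0)
  expect_equal(absolute_uptake_rate(0.3663, 0.5663, 9.2421, 1, 1, 2),
               0.011267, tolerance = 1e-4)
  expect_equal(specific_uptake_rate(0.3663, 0.5663, 9.2421, 2),
               0.011267, tolerance = 1e-4)
  # rho = v x PN_avg for arbitrary inputs
  set.seed(11)
  for (i in 1:20) {
    a0 <- runif(1, 0.3, 0.5); af <- a0 + runif(1, -0.1, 2)
    a_src <- runif(1, 5, 50); pni <- runif(1, 0.2, 3); pnf <- runif(1, 0.2, 3)
    t <- runif(1, 1, 5)
    expect_equal(absolute_uptake_rate(a0, af, a_src, pni, pnf, t),
                 specific_uptake_rate(a0, af, a_src, t) * (pni + pnf) / 2,
                 tolerance = 1e-12)
  }
  # strictly increasing in the final enrichment
  af <- seq(0.4, 3, length.out = 25)
  expect_true(all(diff(absolute_uptake_rate(0.3663, af, 9.2, 1, 1.1, 3)) > 0))
  # negative excess enrichment gives a negative rate, not an error
  expect_lt(absolute_uptake_rate(0.3663, 0.36, 9.2, 1, 1, 2), 0)
  expect_error(absolute_uptake_rate(0.3663, 0.5, 0.3, 1, 1, 2), "contrast")
})

test_that("per-experiment detection limit scales with contrast, PN and time", {
  expect_equal(experiment_detection_limit(9.2421, 0.3663, 1.0, 2),
               1.014e-4, tolerance = 1e-3)
  dl <- experiment_detection_limit(9.2421, 0.3663, 1.0, 2)
  expect_equal(experiment_detection_limit(9.2421, 0.3663, 1.0, 4), dl / 2)
  expect_equal(experiment_detection_limit(2 * 9.2421 - 0.3663, 0.3663, 1.0, 2),
               dl / 2)
  expect_equal(experiment_detection_limit(9.2421, 0.3663, 2.0, 2), dl * 2)
})

test_that("consumption filter excludes at half the added substrate", {
  expect_equal(qc_consumption_filter(0.55), "EXCLUDED_CONSUMPTION")
  expect_equal(qc_consumption_filter(0.50), "EXCLUDED_CONSUMPTION")
  expect_length(qc_consumption_filter(0.10), 0)
  expect_equal(qc_consumption_filter(NA), "CONSUMPTION_UNKNOWN")
  expect_error(qc_consumption_filter(1.2), "\\[0, 1\\]")
})

test_that("replicate aggregation gives mean, sample SD and flag union", {
  agg <- aggregate_replicates(c(0.010, 0.012, 0.011))
  expect_equal(agg$rate, 0.011)
  expect_equal(agg$rate_sd, 0.001)
  single <- aggregate_replicates(0.02)
  expect_equal(single$rate, 0.02)
  expect_equal(single$rate_sd, 0)
  expect_true("SINGLE_REPLICATE" %in% single$flags)
  excl <- aggregate_replicates(c(0.01, 0.02), flags = "EXCLUDED_CONSUMPTION")
  expect_true(is.na(excl$rate))
  expect_error(aggregate_replicates(numeric(0)), "replicate")
})

test_that("noise-free simulated experiments recover the forward-model identity", {
  # rho_hat / rho_true = (PN0 + rho t / 2) / (PN0 + rho t) exactly
  grid <- expand.grid(rho = c(0.001, 0.01, 0.05, 0.2, 0.5),
                      pn0 = c(0.5, 1, 2), t = c(2, 3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a_src <- 25
    reps <- simulate_incubation(g$rho, g$pn0, NAT_ABUND, a_src, g$t,
                                n_replicates = 1L, noise_cv = 0)
    rho_hat <- absolute_uptake_rate(reps$atom_pn_initial_pct,
                                    reps$atom_pn_final_pct, a_src,
                                    reps$pn_initial_umolN_L,
                                    reps$pn_final_umolN_L, g$t)
    expected <- g$rho * (g$pn0 + g$rho * g$t / 2) / (g$pn0 + g$rho * g$t)
    expect_equal(rho_hat, expected, tolerance = 1e-12)
  }
})

test_that("the rates driver flags, aggregates and excludes correctly", {
  cruise <- noise_free_cruise()
  rates <- compute_uptake_rates(cruise$incubations)
  expect_equal(nrow(rates), 4 * 3 * 6)  # regimes x depths x substrates
  expect_true(all(rates$n_replicates == 3))
  expect_true(all(rates$detection_limit_umolN_L_h > 0))
  # urea ambient is below its detection limit everywhere: spike-dominated
  urea <- rates[rates$substrate == "urea", ]
  expect_true(all(grepl("AMBIENT_BELOW_DL", urea$flags)))
  # noise-free replicates agree, so SDs vanish
  expect_true(all(rates$rate_sd < 1e-12))
  # forcing high consumption excludes the experiment
  inc <- cruise$incubations
  key <- inc$station_id == inc$station_id[1] & inc$depth_id == inc$depth_id[1] &
    inc$substrate == "NO3"
  inc$consumed_fraction[key] <- 0.6
  rates2 <- compute_uptake_rates(inc)
  hit <- rates2$station_id == inc$station_id[1] &
    rates2$depth_id == inc$depth_id[1] & rates2$substrate == "NO3"
  expect_true(all(is_excluded(rates2$flags[hit])))
  expect_true(all(is.na(rates2$rate_umolN_L_h[hit])))
  expect_error(compute_uptake_rates(inc[, setdiff(names(inc), "duration_h")]), "missing column")
})
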