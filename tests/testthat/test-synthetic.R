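test_that("fixed seed reproduces the simulated screen exactly", {
  p <- screen_sim_params(n_strains = 10L, seed = 42L)
  a <- simulate_screen(p)
  b <- simulate_screen(p)
  expect_identical(a$tidy, b$tidy)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_screen(screen_sim_params(n_strains = 10L, seed = 43L))
  expect_false(identical(a$tidy$od600, c2$tidy$od600))
})

test_that("noise-free null model reads the inoculum at 48 h in every assay well", {
  p <- screen_sim_params(n_strains = 6L, leakiness = rep(0, 6), noise_sd = 0,
                         additive_sd = 0, contamination_prob = 0, seed = 1L)
  sim <- simulate_screen(p)
  t48 <- sim$tidy[sim$tidy$time == 48, ]
  expect_true(all(t48$od600[t48$kind != "blank"] == 0.1))
  expect_true(all(t48$od600[t48$kind == "blank"] == 0))
  # monoculture growth follows leakiness; planted pair overrides the max-leak null
  p2 <- screen_sim_params(n_strains = 3L, leakiness = c(0, 0.3, 0), noise_sd = 0,
                          additive_sd = 0, contamination_prob = 0,
                          planted_pairs = data.frame(strain_a = "S001",
                                                     strain_b = "S003",
                                                     effect = 0.5),
                          seed = 1L)
  sim2 <- simulate_screen(p2)
  t48b <- sim2$tidy[sim2$tidy$time == 48, ]
  od_of <- function(cond) unique(t48b$od600[t48b$condition_id == cond])
  expect_equal(od_of("mono_S002"), 0.1 + 0.3)
  expect_equal(od_of("co_S001_S002"), 0.1 + 0.3)  # max-leak null
  expect_equal(od_of("co_S001_S003"), 0.1 + 0.5)  # planted effect
  expect_error(simulate_screen(screen_sim_params(
    n_strains = 3L,
    planted_pairs = data.frame(strain_a = "S001", strain_b = "S099", effect = 0.5))),
    "unknown strain")
})

test_that("simulated screens flow through the pipeline and planted truth scores cleanly", {
  planted <- data.frame(strain_a = c("S001", "S004"), strain_b = c("S002", "S007"),
                        effect = 0.5)
  p <- screen_sim_params(n_strains = 12L, leakiness = rep(0, 12),
                         planted_pairs = planted, contamination_prob = 0,
                         seed = 7L)
  sim <- simulate_screen(p)
  res <- run_screen(sim$tidy, sim$conditions, strains = sim$strains)
  ev <- evaluate_calls(res$assays, sim$truth)
  expect_equal(ev$n_planted, 2L)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # perfect / empty call edge cases
  none <- res$assays; none$call <- "no_growth_advantage"
  ev0 <- evaluate_calls(none, sim$truth)
  expect_equal(ev0$recall, 0)
  expect_true(is.na(ev0$precision))
  bad_truth <- sim$truth
  bad_truth$planted_pairs$coculture_id[1] <- "co_not_there"
  expect_error(evaluate_calls(res$assays, bad_truth), "absent")
})

test_that("planted contamination is flagged with zero misses and no extras", {
  p <- screen_sim_params(n_strains = 12L, leakiness = rep(0, 12),
                         contamination_prob = 0.01,
                         contamination_targets = "nongrowing",
                         noise_sd = 0.01, seed = 11L)
  sim <- simulate_screen(p)
  qc <- screen_qc(sim$tidy, sim$conditions)
  hard <- qc$flags[qc$flags$severity == "flag" &
                     qc$flags$flag_kind == "contamination", ]
  truth_key <- paste(sim$truth$contaminated$plate_id, sim$truth$contaminated$well)
  flag_key <- paste(hard$plate_id, hard$well)
  expect_gt(length(truth_key), 0L)
  expect_true(all(truth_key %in% flag_key))
  expect_true(all(flag_key %in% truth_key))
})

test_that("planted edge bias flags the biased plate's edge assays", {
  p <- screen_sim_params(n_strains = 12L, bias_plates = 1L, edge_offset = 0.5,
                         contamination_prob = 0, seed = 5L)
  sim <- simulate_screen(p)
  qc <- screen_qc(sim$tidy, sim$conditions)
  ev <- evaluate_flags(qc$flags, sim$truth, qc$growth)
  expect_equal(ev$bias_missed, 0L)
  g1 <- qc$growth[qc$growth$plate_id == "plate01" & qc$growth$kind != "blank", ]
  edge_wells <- g1$well[is_edge(g1$row, g1$col, 384)]
  flagged <- qc$flags$well[qc$flags$flag_kind == "positional_bias" &
                             qc$flags$plate_id == "plate01"]
  expect_true(all(edge_wells %in% flagged))
})

test_that("artifact-free screens keep the well false-flag rate within the MAD-rule budget", {
  p <- screen_sim_params(n_strains = 16L, contamination_prob = 0, seed = 23L)
  sim <- simulate_screen(p)
  qc <- screen_qc(sim$tidy, sim$conditions)
  hard <- qc$flags[qc$flags$severity == "flag", ]
  n_assay_wells <- sum(qc$growth$kind != "blank")
  # budget: ~5.6% per-replicate false flags are inherent to the k=3 MAD rule
  # at n = 4, plus a few percent from median polish on a randomized layout
  expect_lt(nrow(hard) / n_assay_wells, 0.10)
  # and nearly all pair assays remain testable (>= 2 replicates each side)
  res <- screen_hits(qc$growth, sim$conditions, flags = qc$flags,
                     apply_activity_filter = FALSE)
  testable <- !res$assays$dropped
  expect_gt(mean(testable), 0.95)
})

test_that("activity-range drops increase monotonically with constituent leakiness", {
  # syntrophic pairs (effect 0.5) whose constituents leak progressively more:
  # a fit monoculture erodes the assay window until the Z-factor gate drops it
  drop_rate <- function(leak) {
    strains <- sprintf("S%03d", 1:10)
    pairs <- t(utils::combn(strains, 2))
    p <- screen_sim_params(n_strains = 10L, leakiness = rep(leak, 10),
                           planted_pairs = data.frame(strain_a = pairs[, 1],
                                                      strain_b = pairs[, 2],
                                                      effect = 0.5),
                           contamination_prob = 0, seed = 17L)
    sim <- simulate_screen(p)
    growth <- blank_correct(sim$tidy)
    assays <- pair_assays(growth, sim$conditions)
    mean(assays$drop_reason == "activity_range")
  }
  rates <- vapply(c(0, 0.25, 0.45), drop_rate, 1)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("obligate cross-feeding: no export means no growth; symmetry holds 0.5", {
  still <- simulate_coculture_dynamics(rho1 = 0, rho2 = 0, n0 = c(0.05, 0.05),
                                       duration = 48, step = 0.2)
  expect_lt(max(abs(still$N1 - 0.05)), 1e-6)
  expect_lt(max(abs(still$N2 - 0.05)), 1e-6)

  sym <- simulate_coculture_dynamics(r1 = 0.4, r2 = 0.4, rho1 = 0.05,
                                     rho2 = 0.05, n0 = c(0.05, 0.05),
                                     duration = 72, step = 0.2)
  expect_lt(max(abs(sym$proportion_true - 0.5)), 1e-9)
  expect_gt(sym$N1[length(sym$N1)], 0.1)  # community actually grows
  expect_error(simulate_coculture_dynamics(step = -1), "positive")
  expect_error(simulate_coculture_dynamics(r1 = -0.1), "nonnegative")
})

test_that("halving the integration step changes trajectories by < 1e-4 relative", {
  a <- simulate_coculture_dynamics(r1 = 0.45, r2 = 0.35, rho1 = 0.06,
                                   rho2 = 0.04, n0 = c(0.04, 0.06),
                                   duration = 72, step = 0.2)
  b <- simulate_coculture_dynamics(r1 = 0.45, r2 = 0.35, rho1 = 0.06,
                                   rho2 = 0.04, n0 = c(0.04, 0.06),
                                   duration = 72, step = 0.1)
  common <- match(a$times, b$times)
  rel <- abs(a$N1 - b$N1[common]) / pmax(abs(b$N1[common]), 1e-12)
  expect_lt(max(rel), 1e-4)
})

test_that("serial passages re-establish the community composition", {
  passes <- simulate_serial_passages(n_passages = 2L, passage_od = 0.1,
                                     duration = 48, r1 = 0.45, r2 = 0.35,
                                     rho1 = 0.06, rho2 = 0.04,
                                     n0 = c(0.04, 0.06), step = 0.2,
                                     channel_noise_sd = 0.02, seed = 9L)
  tr <- lapply(passes, function(s) {
    proportion_trajectory(s$times, s$F_blue, s$F_red, s$curves)
  })
  res <- stability_compare(tr[[1]], tr[[2]])
  expect_true(res$re_established)
  expect_lte(res$final_delta, 0.15)
})
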