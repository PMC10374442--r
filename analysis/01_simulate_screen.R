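#!/usr/bin/env Rscript
# Generates the synthetic growth-complementation screen used by the
# downstream analysis scripts: a 24-strain strict-auxotroph library with 40
# planted syntrophic pairs (effect 0.5 of carrying OD), plus a 64-strain
# null library for type-I assessment. Writes the tidy observation tables
# and the ground truth under results/.

library(syntroscreen)

dir.create("results", showWarnings = FALSE)
cfg <- screen_config(seed = 20260929L)

# --- planted screen: every downstream claim about power refers to this ---
strains <- sprintf("S%03d", 1:24)
pairs <- t(utils::combn(strains, 2))
set.seed(cfg$seed)
sel <- sample(nrow(pairs), 40L)
planted <- data.frame(strain_a = pairs[sel, 1], strain_b = pairs[sel, 2],
                      effect = 0.5)
sim <- simulate_screen(screen_sim_params(n_strains = 24L,
                                         leakiness = rep(0, 24),
                                         planted_pairs = planted,
                                         seed = cfg$seed))
write_results(sim$tidy, "results/screen_tidy.csv", cfg)
write_results(sim$conditions, "results/screen_conditions.csv", cfg)
write_results(sim$truth$planted_pairs, "results/screen_truth_planted.csv", cfg)

# --- null screen: 64 strains, 2,016 pairs, ~27% leaky, nothing planted ---
sim0 <- simulate_screen(screen_sim_params(n_strains = 64L, seed = cfg$seed + 1L))
write_results(sim0$tidy, "results/null_tidy.csv", cfg)
write_results(sim0$conditions, "results/null_conditions.csv", cfg)

cat("planted screen:", length(unique(sim$tidy$plate_id)), "plates,",
    nrow(sim$tidy) / 2, "wells, 40 planted pairs\n")
cat("null screen:   ", length(unique(sim0$tidy$plate_id)), "plates,",
    nrow(sim0$tidy) / 2, "wells\n")
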