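#!/usr/bin/env Rscript
# Step 1: simulate the study population.
#
# Generates the default synthetic NHANES-like population — 2,000 adult
# person-days across 14 strata with two PSUs each, log-normal day-1
# weights, ~10 background items per day and Poisson(0.78) typical-sandwich
# occurrences — and writes it in the canonical item-level recall CSV.
# The full item table goes to scratch/ (it is bulky and regenerable);
# a small structural summary goes to results/.

library(dietshift)

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- population_config(seed = 2025L)
pop <- gen_population(cfg)
write_recall_table(pop, "scratch/synthetic_recall.csv")

pol <- substitution_policy()
counts <- vapply(pop, function(d) length(identify_sandwiches(d, pol)), 0L)
w <- vapply(pop, `[[`, 0, "weight")
energy <- vapply(pop, function(d) daily_totals(d)$nutrients[["energy"]], 0)

summary_df <- data.frame(
  n_person_days = length(pop),
  n_strata = length(unique(vapply(pop, `[[`, "", "stratum"))),
  n_items = sum(vapply(pop, function(d) length(d$items), 0L)),
  pct_sandwich_consumers = round(100 * mean(counts > 0), 1),
  weighted_mean_sandwiches_per_day = round(weighted_mean(counts, w), 3),
  weighted_mean_energy_kcal = round(weighted_mean(energy, w), 1))
write.csv(summary_df, "results/01_population_summary.csv", row.names = FALSE)

cat("Simulated", summary_df$n_person_days, "person-days (",
    summary_df$n_items, "items ) across", summary_df$n_strata, "strata.\n")
cat(sprintf("%.1f%% of person-days contain a sandwich;",
            summary_df$pct_sandwich_consumers),
    sprintf("weighted mean %.3f sandwiches/day (configured rate %.2f).\n",
            summary_df$weighted_mean_sandwiches_per_day, cfg$sandwich_rate))
cat(sprintf("Weighted mean daily energy: %.0f kcal.\n",
            summary_df$weighted_mean_energy_kcal))
cat("Item table: scratch/synthetic_recall.csv;",
    "summary: results/01_population_summary.csv\n")
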