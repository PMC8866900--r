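#!/usr/bin/env Rscript
# Generate the synthetic study: a WT-like strain and a fast-growing mutant
# with reduced adaptation capacity (higher glucose-phase growth rate, lower
# acetate-phase rate, longer shift lag), plus reporter, budget-table and
# dual-reporter isocost datasets. Everything downstream reads from
# results/sim/.

library(riboalloc)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scenarios <- list(
  WT     = list(mu1 = 0.90, mu2 = 0.35, lag_duration = 1.0, seed = 101),
  rrnDel = list(mu1 = 0.97, mu2 = 0.25, lag_duration = 1.6, seed = 202))

for (nm in names(scenarios)) {
  p <- scenarios[[nm]]
  sim <- simulate_diauxic_growth(mu1 = p$mu1, mu2 = p$mu2,
                                 lag_duration = p$lag_duration,
                                 n_wells = 9, strain = nm, seed = p$seed)
  write_plate(sim$series, file.path(out, paste0("growth_", nm, ".csv")),
              time_unit = "minutes")
  write.csv(sim$series$wells, file.path(out, paste0("growth_", nm, "_meta.csv")),
            row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  write.csv(data.frame(strain = nm, mu1_real = truth$mu1_real,
                       mu2_real = truth$mu2_real,
                       shift_time = truth$shift_time, lag = truth$lag),
            file.path(out, paste0("growth_", nm, "_truth.csv")),
            row.names = FALSE, quote = FALSE)
  cat(sprintf("%s: true mu1 %.3f, mu2 %.3f, shift at %.2f h -> %s\n",
              nm, truth$mu1_real, truth$mu2_real, truth$shift_time,
              file.path(out, paste0("growth_", nm, ".csv"))))
}

# ribosome-reporter allocation: same slope for every strain (the shared
# growth-law regime), WT intercept
strains <- data.frame(strain = c("WT", "rrnDel"),
                      intercept = c(2, 2), slope = c(3, 3))
alloc <- simulate_reporter_allocation(strains, seed = 303)
write_plate(alloc$series, file.path(out, "allocation.csv"),
            time_unit = "minutes")
write.csv(alloc$series$wells, file.path(out, "allocation_meta.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(alloc$truth, file.path(out, "allocation_truth.csv"),
          row.names = FALSE, quote = FALSE)
cat(sprintf("allocation: %d wells across %d media, shared slope %.1f\n",
            nrow(alloc$truth), length(unique(alloc$truth$medium)), 3))

# aceB-like promoter reporter, mutant rise rate at 85% of WT
for (nm in c("WT", "rrnDel")) {
  rise <- if (nm == "WT") 2 else 0.85 * 2
  ps <- simulate_promoter_reporter(rise_rate = rise, seed = 404 +
                                     (nm == "rrnDel"))
  write_plate(ps$series, file.path(out, paste0("promoter_", nm, ".csv")),
              time_unit = "minutes")
  write.csv(ps$series$wells,
            file.path(out, paste0("promoter_", nm, "_meta.csv")),
            row.names = FALSE, quote = FALSE)
}
cat("promoter: WT rise 2.0, mutant rise 1.7 (85% of WT)\n")

# gene budget table with planted direction totals (fg per cell)
budget <- simulate_budget_tables(up_total_fg = 6.27, down_total_fg = 2.09,
                                 seed = 505)
write.table(budget$table, file.path(out, "genes.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("budget table: %d genes, planted up/down totals 6.27/2.09 fg\n",
            nrow(budget$table)))

# isocost: mutant budget at 70% of WT
for (nm in c("WT", "rrnDel")) {
  b <- if (nm == "WT") 1000 else 700
  iso <- simulate_isocost(budget = b, strain = nm,
                          seed = 606 + (nm == "rrnDel"))
  write_plate(iso$series, file.path(out, paste0("isocost_", nm, ".csv")),
              time_unit = "minutes")
  write.csv(iso$series$wells,
            file.path(out, paste0("isocost_", nm, "_meta.csv")),
            row.names = FALSE, quote = FALSE)
}
cat("isocost: WT budget 1000, mutant 700 (four AHL levels: 0/2.5/5/20 nM)\n")
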