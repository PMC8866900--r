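#!/usr/bin/env Rscript
# Ribosome-reporter allocation: normalized fluorescence vs growth rate per
# strain, per-strain regression slopes, and mutant-vs-WT slope comparison.

library(riboalloc)

out <- "results"
pl <- read_plate(file.path(out, "sim", "allocation.csv"),
                 file.path(out, "sim", "allocation_meta.csv"),
                 layout = "long")

pts <- do.call(rbind, lapply(colnames(pl$od), function(w) {
  fit <- fit_growth_curve(pl, w)
  p <- compute_normalized_fluorescence(pl, w, fit)
  data.frame(well = w, strain = p$strain, medium = p$medium,
             mu = p$mu, f_norm = p$f_norm, f_norm_sd = p$f_norm_sd)
}))
write.table(pts, file.path(out, "allocation_points.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

fits <- lapply(split(pts, pts$strain), function(d)
  fit_allocation_regression(d, strain = d$strain[1]))
pooled <- fit_allocation_regression(pts, strain = "pooled")
reg_tab <- do.call(rbind, lapply(c(fits, list(pooled = pooled)), function(f)
  data.frame(strain = f$strain, slope = f$slope,
             slope_lo = f$slope_ci[1], slope_hi = f$slope_ci[2],
             intercept = f$intercept, n = f$n, r_squared = f$r_squared)))
write.table(reg_tab, file.path(out, "allocation_regressions.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cmp <- compare_slopes(fits$rrnDel, fits$WT)
cat(sprintf("WT slope %.2f [%.2f, %.2f]; mutant slope %.2f [%.2f, %.2f]\n",
            fits$WT$slope, fits$WT$slope_ci[1], fits$WT$slope_ci[2],
            fits$rrnDel$slope, fits$rrnDel$slope_ci[1],
            fits$rrnDel$slope_ci[2]))
cat(sprintf("slope difference %.3f (p = %.2f): %s\n", cmp$estimate, cmp$p,
            if (cmp$significant) "strains differ" else
              "no significant difference between mutant and WT (95%)"))
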