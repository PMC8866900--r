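#!/usr/bin/env Rscript
# Isocost lines from the dual-reporter assay: (RFP/OD, GFP/OD) matched at
# OD 0.2 across the four inducer levels, per-strain line fits and budget
# ratios against WT.

library(riboalloc)

out <- "results"
levels <- list(L1 = 0, L2 = 2.5, L3 = 5, L4 = 20)
fits <- list()
for (nm in c("WT", "rrnDel")) {
  pl <- read_plate(file.path(out, "sim", paste0("isocost_", nm, ".csv")),
                   file.path(out, "sim", paste0("isocost_", nm, "_meta.csv")),
                   layout = "long")
  pts <- match_expression(pl, levels)
  fits[[nm]] <- fit_isocost_line(pts, nm)
  cat(sprintf("%s: slope %.2f, budget (GFP intercept) %.0f [%.0f, %.0f]\n",
              nm, fits[[nm]]$slope, fits[[nm]]$budget,
              fits[[nm]]$gfp_intercept_ci[1], fits[[nm]]$gfp_intercept_ci[2]))
}
cmp <- compare_budgets(fits, "WT")
write.table(cmp, file.path(out, "isocost_budgets.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
mut <- cmp[cmp$strain == "rrnDel", ]
cat(sprintf(
  "mutant budget is %.0f%% of WT [%.0f%%, %.0f%%]%s\n",
  100 * mut$ratio, 100 * mut$ratio_ci_lo, 100 * mut$ratio_ci_hi,
  if (mut$significant) " - significantly reduced" else ""))
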