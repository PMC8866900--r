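#!/usr/bin/env Rscript
# Transcript-to-proteome mass budget: translation efficiencies from the WT
# reference, per-gene mass deltas, direction/category totals and the Pareto
# concentration of the change.

library(riboalloc)

out <- "results"
genes <- read_gene_table(file.path(out, "sim", "genes.tsv"))
te <- compute_translation_efficiency(genes)
mc <- mass_contribution_deltas(te)
ps <- pareto_summary(mc, top_n = 20)

write.table(mc$genes, file.path(out, "budget_genes.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(mc$by_direction, file.path(out, "budget_by_direction.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(mc$by_category, file.path(out, "budget_by_category.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(ps$top, file.path(out, "budget_pareto_top20.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("genes analysed: %d (excluded, no WT transcript: %d)\n",
            nrow(mc$genes), length(mc$excluded)))
cat(sprintf("upregulated mass %.2f fg vs downregulated %.2f fg (ratio %.2f)\n",
            mc$up_total, mc$down_total, mc$ratio_up_down))
cat(sprintf("top 20 genes carry %.1f%% of the total mass change\n",
            ps$top_n_share_pct))
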