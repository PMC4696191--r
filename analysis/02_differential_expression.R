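#!/usr/bin/env Rscript
# Stage 2: FPKM normalization and NB differential expression (Wald test with
# pooled method-of-moments dispersion, BH-FDR at alpha = 0.05) on the
# simulated counts, then the up/down split and the COG breakdown.

library(rosregulon)

fix <- "results/simulated"
genome <- read_genome(file.path(fix, "genome.fasta"), file.path(fix, "genes.tsv"))
counts <- read_counts(file.path(fix, "counts.tsv"), file.path(fix, "design.tsv"))
truth <- read.delim(file.path(fix, "truth.tsv"))

de <- classify_de(de_test(counts), alpha = 0.05)
write_table(de, "results/de_results.tsv")

dir <- summarize_direction(de)
cat(dir$n_significant, "genes significant at FDR 0.05:",
    dir$pct_up, "% up,", dir$pct_down, "% down in the mutant\n")

called <- de$status[match(truth$gene_id, de$gene_id)]
cat("recovery of planted DE genes:",
    round(100 * mean(called[truth$is_de] != "ns"), 1), "%;",
    "false positives among null genes:",
    sum(called[!truth$is_de] != "ns"), "/", sum(!truth$is_de), "\n")

cog <- breakdown_by_cog(de, genome)
write_table(cog$table, "results/cog_summary.tsv")
cat("COG classification rate:", cog$classification_rate_pct, "%\n")

fpkm <- compute_fpkm(counts)
top <- top_n_by_abs_lfc(de, fpkm, n = 100)
write_table(data.frame(gene_id = rownames(top), top, check.names = FALSE),
            "results/top100_fpkm.tsv")
cat("top-100 |log2fc| FPKM matrix written\n")
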