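#!/usr/bin/env Rscript
# Stage 4: join differential expression with the promoter scan into
# regulon records, split direct vs indirect targets, and score the
# regulator's dominant mode of action.

library(rosregulon)

fix <- "results/simulated"
genome <- read_genome(file.path(fix, "genome.fasta"), file.path(fix, "genes.tsv"))
counts <- read_counts(file.path(fix, "counts.tsv"), file.path(fix, "design.tsv"))

de <- classify_de(de_test(counts), alpha = 0.05)
hits <- scan_genome(genome, min_identity_pct = 85)
rec <- integrate_regulon(de, hits, genome)
write_table(rec, "results/regulon.tsv")

n_direct <- sum(rec$regulation_class == "direct")
cat(nrow(rec), "regulon records:", n_direct, "direct,",
    nrow(rec) - n_direct, "indirect\n")

s <- repressor_score(rec)
cat(sprintf("%.0f %% of direct targets up-regulated in the mutant -> %s\n",
            100 * s$fraction_up, s$label))
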