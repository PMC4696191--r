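#!/usr/bin/env Rscript
# Stage 1: build the synthetic study that stands in for the unavailable
# wild-type vs rosR-mutant sequencing data: a two-contig genome with genes on
# both strands, COG labels, ~15% DE genes (63.2% of them up-regulated in the
# mutant), RosR-box copies planted in the promoters of the designated direct
# targets, and 3+3 replicate NB counts (dispersion 0.05, median depth ~1000
# reads per CDS).

library(rosregulon)

outdir <- "results/simulated"
cfg <- scenario_config(genes_per_contig = 100, seed = 20240901)
sc <- make_scenario(cfg, outdir = outdir)

cat("genome:", length(sc$genome$contigs), "contigs,",
    sum(nchar(sc$genome$contigs)), "bp, GC",
    round(100 * mean(strsplit(paste(sc$genome$contigs, collapse = ""),
                              "")[[1]] %in% c("G", "C")), 1), "%\n")
cat("genes:", nrow(sc$truth), "| DE:", sum(sc$truth$is_de),
    "| up among DE:",
    round(100 * mean(sc$truth$true_log2fc[sc$truth$is_de] > 0), 1), "%\n")
cat("direct targets with planted motifs:", sum(sc$truth$planted), "\n")
cat("fixtures written under", outdir, "\n")
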