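#!/usr/bin/env Rscript
# Stage 5: phenotype statistics. Doubling times of the wild-type-like
# (4.5 h) and mutant-like (6.0 h) strains estimated from simulated 9-h CFU
# courses (30-min sampling, 5% noise), and autoaggregation percentages at
# the two strains' reported aggregation levels.

library(rosregulon)

rows <- list()
for (strain in list(list(name = "wild-type", td = 4.5, agg = 0.0974),
                    list(name = "rosR mutant", td = 6.0, agg = 0.3669))) {
  curve <- simulate_growth_curve(n0 = 1e7, doubling_time_h = strain$td,
                                 duration_h = 9, step_h = 0.5,
                                 noise_cv = 0.05, seed = 7)
  fit <- generation_time_h(curve$times_h, curve$cfu_per_ml)
  m <- simulate_aggregation(strain$agg, a1 = 1.0, noise_sd = 0)
  agg <- autoaggregation_pct(m$A1, m$A2)
  cat(sprintf("%-12s doubling time %.2f h (r2 %.3f), autoaggregation %.2f %%\n",
              strain$name, fit$doubling_time_h, fit$r2, agg))
  rows[[strain$name]] <- data.frame(strain = strain$name,
                                    doubling_time_h = fit$doubling_time_h,
                                    r2 = fit$r2, autoaggregation_pct = agg)
}
write_table(do.call(rbind, rows), "results/phenotypes.tsv")
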