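#!/usr/bin/env Rscript
# Biodistribution: group mean +/- SD per organ, tumor-to-brain and
# tumor-to-blood ratios, and the Student's t comparison of cellular uptake.

suppressPackageStartupMessages(library(bnctquant))

meas <- read.csv("results/inputs/biodistribution.csv")
tab <- biodistribution_table(meas)
write.csv(tab, "results/biodistribution_table.csv", row.names = FALSE)
disp <- tab
disp[c("tumor", "brain", "blood", "t_br", "t_bl")] <-
  lapply(disp[c("tumor", "brain", "blood", "t_br", "t_bl")], round, 1)
cat("Tumor / brain / blood summary with ratios:\n")
print(disp, row.names = FALSE)

upt <- read.csv("results/inputs/uptake.csv")
upt$uptake <- normalize_uptake(upt$boron_ug, upt$n_cells)
cat("\nCellular uptake comparisons (ug B / 1e9 cells):\n")
for (cl in unique(upt$cell_line)) {
  g <- upt[upt$cell_line == cl, ]
  dpa <- g$uptake[g$compound == "dpa_bstpg"]
  for (other in c("bpa", "bsh")) {
    t_ <- compare_uptake(dpa, g$uptake[g$compound == other])
    cat(sprintf("  %-4s dpa_bstpg (mean %5.1f) vs %-3s (mean %5.1f): t = %6.2f, p = %.2g\n",
                cl, mean(dpa), other, mean(g$uptake[g$compound == other]),
                t_$t, t_$p))
  }
}
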