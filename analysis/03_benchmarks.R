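#!/usr/bin/env Rscript
# Objective benchmarks: IFR and prevalence per incidence tier from the
# simulated count table, odds ratios against the lowest-risk tier, and the
# quarantined cruise-ship worked example (7 deaths among 705 diagnosed of
# 3711 aboard) as a calibration reference point.

suppressMessages(library(riskbeliefs))

counts <- readr::read_csv("results/stratum_counts.csv",
                          show_col_types = FALSE)
bench <- compute_rates(counts)
ors <- odds_ratio_table(bench, reference = "lowest")
readr::write_csv(bench, "results/benchmarks.csv")
readr::write_csv(ors, "results/odds_ratios.csv")

cat("benchmarks by incidence tier:\n")
print(as.data.frame(bench[c("stratum", "ifr_pct", "prevalence_per100")]),
      row.names = FALSE, digits = 3)
cat("\nprevalence odds ratios vs lowest tier:\n")
print(as.data.frame(ors[c("stratum", "odds_ratio")]), row.names = FALSE,
      digits = 4)

ship <- compute_rates(tibble::tibble(stratum = "ship", deaths = 7,
                                     diagnosed = 705, population = 3711))
cat(sprintf("\ncruise-ship reference: IFR %.2f%%, prevalence %.0f%% -- an IFR
more than ten times below prevalence, the benchmark for well-ordered beliefs\n",
            ship$ifr_pct, ship$prevalence_per100))
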