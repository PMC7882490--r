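#!/usr/bin/env Rscript
# Comparative optimism: per-wave mean difference between own risk (q2) and
# expected prevalence (q4), the rescaled [0,1] index, and the wave contrast
# from a weighted quasibinomial GLM on the index. The generated wave shifts
# (+11.5 on q2, -11.1 on q4) reverse the sign of the gap between waves.

suppressMessages(library(riskbeliefs))

survey <- read_survey("results/survey.csv")
opt <- optimism_dynamics(survey)
print(opt)

pw <- opt$per_wave
pw$wave_contrast_p <- opt$wave_contrast$p_value
readr::write_csv(pw, "results/optimism.csv")

change <- pw$mean_q2_minus_q4[pw$wave == 2] - pw$mean_q2_minus_q4[pw$wave == 1]
cat(sprintf("\nwave-2 minus wave-1 change in mean (q2 - q4): %+.2f points
(configured: +22.6 before heaping distortion); index falls below 0.5 in wave 2:
comparative optimism turned into comparative pessimism.\n", change))
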