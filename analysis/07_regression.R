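#!/usr/bin/env Rscript
# Determinants of beliefs: survey-weighted quasibinomial logit GLM of each
# 0-100 item on demographics and wave, reported as average marginal effects
# with delta-method standard errors (the scale on which the published
# regression tables are reported).

suppressMessages(library(riskbeliefs))

survey <- read_survey("results/survey.csv")
survey$wave <- factor(survey$wave)
terms <- c("gender", "age_category", "region_tier", "wave")

all_ames <- purrr::map_dfr(
  c("q1_ifr", "q2_own_risk", "q3_others_risk", "q4_prevalence"),
  function(outcome) {
    fit <- fit_quasibinomial(survey, outcome, terms, use_weights = TRUE)
    ame <- average_marginal_effects(fit)
    dplyr::mutate(ame, outcome = outcome, dispersion = fit$dispersion,
                  n = fit$n_used, .before = 1)
  })
readr::write_csv(all_ames, "results/marginal_effects.csv")

cat("average marginal effects (probability scale), q2 own risk:\n")
q2 <- all_ames[all_ames$outcome == "q2_own_risk", ]
print(as.data.frame(q2[c("term", "level", "ame", "se", "p_value")]),
      row.names = FALSE, digits = 3)
cat(sprintf("\ndispersion: %s
the wave AME sits near the generated +11.5-point shift, attenuated by the
12%% heap at 50 (heaped answers do not move with the wave); gender/age/tier
AMEs reflect the small generated logit effects.\n",
            paste(sprintf("%s %.2f", unique(all_ames$outcome),
                          all_ames$dispersion[!duplicated(all_ames$outcome)]),
                  collapse = ", ")))
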