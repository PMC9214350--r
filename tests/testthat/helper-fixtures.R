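# Shared test fixtures, built in code.

# A three-effect arm mirroring the structure of the cheapest bundled arm
# (home-visit psychosocial stimulation: cognitive + two language domains).
three_effect_arm <- function(arm_id = "demo_hv",
                             per_child_local = 1,
                             per_child_standardized = 24) {
  intervention_arm(
    arm_id = arm_id, study_label = "Demo home visits",
    country = "Demoland", study_year = "2011",
    per_child_local = per_child_local,
    per_child_standardized = per_child_standardized,
    effects = rbind(
      effect_estimate("cognitive", 0.67, 0.48, 0.86, TRUE),
      effect_estimate("expressive_language", 0.97, 0.82, 1.21, TRUE),
      effect_estimate("receptive_language", 0.85, 0.64, 1.03, TRUE)
    )
  )
}

single_effect_arm <- function(arm_id = "demo_single", estimate = 0.33,
                              lower = 0.04, upper = 0.61,
                              per_child_standardized = 1357,
                              per_child_local = 183) {
  intervention_arm(
    arm_id = arm_id, study_label = "Demo single domain",
    country = "Demoland", study_year = "2001",
    per_child_local = per_child_local,
    per_child_standardized = per_child_standardized,
    effects = effect_estimate("cognitive", estimate, lower, upper, TRUE)
  )
}

# Flat-CPI parameters with a controllable wage ratio:
# reference_wage / local_wage = wage_ratio.
flat_params <- function(wage_ratio = 1, reference_wage = 3549,
                        country = "Demoland", years = c(2005, 2010),
                        cpi = c(100, 100)) {
  standardization_params(
    cpi_table = data.frame(country = country, year = years, cpi = cpi),
    local_wage_table = data.frame(country = country, year = 2010,
                                  wage = reference_wage / wage_ratio),
    reference_year = 2010, reference_wage = reference_wage
  )
}

random_effects <- function(d, rng_round = FALSE) {
  est <- stats::runif(d, -0.5, 1.8)
  half <- stats::runif(d, 0, 0.6)
  eff <- effect_estimate(sample(ecd_domains, d), est, est - half, est + half,
                         significant = est - half > 0)
  if (rng_round) {
    eff$estimate <- round(eff$estimate, 2)
    eff$lower <- round(eff$lower, 2)
    eff$upper <- pmax(eff$estimate, round(eff$upper, 2))
    eff$lower <- pmin(eff$lower, eff$estimate)
  }
  eff
}
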