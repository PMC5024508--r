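# Independent oracles and shared fixtures for the suite.

# Inclusion-exclusion expansion of the union probability of independent
# events: an independent route to the complement-product pooling rule,
# feasible by brute force for small numbers of policies.
inclusion_exclusion <- function(e) {
  n <- length(e)
  total <- 0
  for (k in seq_len(n)) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      total <- total + (-1)^(k + 1) * prod(e[idx])
    }
  }
  total
}

israel <- israel_profile()

israel_report <- build_report(
  israel$profile, israel$status,
  price_increase_override = israel$price_increase_override
)

report_row <- function(report, policy) {
  report[report$policy == policy, , drop = FALSE]
}

# gender-symmetric profile: both genders identical in every respect
symmetric_profile <- country_profile(
  "Symmetria", 2020,
  population = c(male = 1e6, female = 1e6),
  prevalence = c(male = 0.2, female = 0.2),
  pct_agriculture = 0.1,
  labor_participation = c(male = 0.65, female = 0.65)
)
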