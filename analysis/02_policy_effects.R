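#!/usr/bin/env Rscript
# Per-policy incremental effects of moving each MPOWER domain from its
# current Israeli level to the full MPOWER target: short-term (5-year) and
# long-term (40-year) relative reductions in smoking prevalence.
# Writes results/policy_effects.csv.

suppressPackageStartupMessages(library(mpowersim))
dir.create("results", showWarnings = FALSE)

cfg <- read_config(system.file("extdata", "israel.yaml", package = "mpowersim"))
eff <- all_policy_effects(cfg$profile, cfg$status,
                          price_increase_override = cfg$price_increase_override)
eff$combined <- combine_effects(eff)

tab <- data.frame(
  policy = names(eff),
  short_term_pct = sapply(eff, function(e) 100 * e$short_term),
  long_term_pct = sapply(eff, function(e) 100 * e$long_term)
)
write.csv(tab, "results/policy_effects.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 4)

cat("\nTaxation is the single strongest lever long-term (its effect doubles\n")
cat("over 40 years); cessation treatment and warnings start small but grow\n")
cat("the fastest (multipliers 2.5 and 2). Combined, full MPOWER implementation\n")
cat(sprintf("reduces prevalence among current smokers by %.1f%% in 5 years and %.1f%% in 40.\n",
            100 * eff$combined$short_term, 100 * eff$combined$long_term))
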