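params <- default_effect_params()

test_that("price increase follows the net-price-fixed convention", {
  mk_status <- function(excise, vat) {
    s <- unclass(israel$status)
    s$excise_share <- excise
    s$vat_rate <- vat
    do.call(policy_status, s)
  }
  # no VAT: ratio of net shares, hand algebra (1-0.50)/(1-0.60) - 1
  p <- default_effect_params(list(tax_target_share = 0.60))
  expect_equal(compute_price_increase(mk_status(0.50, 0), p)$relative_price_increase,
               0.25)
  # no change in share -> no price change, any VAT
  p2 <- default_effect_params(list(tax_target_share = 0.50))
  expect_equal(compute_price_increase(mk_status(0.50, 0.2), p2)$relative_price_increase, 0)
  # target share and VAT jointly consuming the whole price is undefined
  p3 <- default_effect_params(list(tax_target_share = 0.85))
  expect_error(compute_price_increase(mk_status(0.50, 0.2), p3), "whole price")
})

test_that("tax effect is elasticity magnitude times price increase, doubled long-term", {
  e <- tax_effect(israel$profile, israel$status, params,
                  price_increase_override = 0.39)
  expect_equal(e$short_term, 0.15 * 0.39)
  expect_equal(e$long_term, 0.15 * 0.39 * 2)
  # already at target: zero effect with a warning, not an error
  s <- unclass(israel$status)
  s$excise_share <- 0.75
  s$vat_rate <- 0
  at_target <- do.call(policy_status, s)
  expect_warning(e0 <- tax_effect(israel$profile, at_target, params), "target")
  expect_equal(e0$short_term, 0)
})

test_that("smoke-free effect reproduces the adjustor arithmetic and pools by smokers", {
  # independent hand computation from the stated composition
  urban <- 1 - israel$profile$pct_agriculture
  full <- 0.06 * urban * israel$profile$labor_participation + 0.02 + 0.01
  cur <- 0.5 * full * (0.75 + 0.25 * 3 / 10) * (0.75 + 0.25 * 0.25)
  smokers <- israel$profile$population * israel$profile$prevalence
  expected <- sum((full - cur) * smokers) / sum(smokers)

  e <- smokefree_effect(israel$profile, israel$status, params)
  expect_equal(e$short_term, expected)
  expect_equal(e$long_term, expected * 1.25)
  expect_equal(unname(e$short_by_gender), unname(full - cur))

  # zeroed labor force and no restaurant/bar gap: only worksite term, annihilated
  prof0 <- country_profile("x", 2020, c(male = 1e6, female = 1e6),
                           c(male = 0.2, female = 0.2), 0,
                           c(male = 0, female = 0))
  s <- unclass(target_policy_status())
  s$smokefree_coverage <- 1 # restaurants/bars already covered
  e0 <- smokefree_effect(prof0, do.call(policy_status, s), params)
  expect_equal(e0$short_term, 0)
})

test_that("gender-symmetric profiles yield gender-identical smoke-free effects", {
  e <- smokefree_effect(symmetric_profile, israel$status, params)
  expect_equal(e$short_by_gender[["male"]], e$short_by_gender[["female"]])
})

test_that("cessation effect is the gap between the full package and the additive sum", {
  e <- cessation_effect(israel$profile, israel$status, params)
  expect_equal(e$short_term, 0.0475 - (0.00667 + 0.00334 + 0.01125))
  expect_equal(e$long_term, e$short_term * 2.5)
  # all sub-policies present: credited at the full package, zero increment
  e0 <- cessation_effect(israel$profile, target_policy_status(), params)
  expect_equal(e0$short_term, 0)
  # publicity factor applies symmetrically at the scenario's publicity level
  e_low <- cessation_effect(israel$profile, israel$status, params,
                            target_publicity = 0)
  expect_equal(e_low$short_term, 0.75 * e$short_term)
})

test_that("media, marketing and warnings effects follow their tier rules", {
  m <- media_effect(israel$status, params)
  expect_equal(m$short_term, 0.065 - 0.01)
  expect_equal(m$long_term, (0.065 - 0.01) * 1.2)

  k <- marketing_effect(israel$status, params)
  expect_equal(k$short_term, 0.05 - 0.01 * (0.5 + 0.5 * 2 / 10))
  expect_equal(k$long_term, k$short_term * 1.3)

  w <- warnings_effect(israel$status, params)
  expect_equal(w$short_term, 0.02)
  expect_equal(w$long_term, 0.04)
  # with baseline credit, the current tier is subtracted
  w2 <- warnings_effect(israel$status, params, baseline_credit = TRUE)
  expect_equal(w2$short_term, 0.02 - 0.01)

  tgt <- target_policy_status()
  expect_equal(media_effect(tgt, params)$short_term, 0)
  expect_equal(marketing_effect(tgt, params)$short_term, 0)
  expect_equal(warnings_effect(tgt, params, baseline_credit = TRUE)$short_term, 0)
})

test_that("long-term effect multiplies by the domain multiplier and caps below one", {
  expect_equal(long_term_effect(0.026, "cessation", params), 0.065)
  expect_equal(long_term_effect(0.02, "warnings", params), 0.04)
  expect_equal(long_term_effect(0, "tax", params), 0)
  expect_equal(long_term_effect(0.9, "cessation", params), params$long_term_cap)
})

test_that("a status already at the MPOWER target yields zero effect in every domain", {
  tgt <- target_policy_status(params)
  eff <- suppressWarnings(
    all_policy_effects(israel$profile, tgt, params, baseline_credit = TRUE)
  )
  for (e in eff) expect_equal(e$short_term, 0, info = e$domain)
  expect_equal(combine_effects(eff)$short_term, 0)
})

test_that("weakening any baseline policy field never shrinks the incremental effect", {
  weaker <- list(
    list(field = "smokefree_coverage", strong = 0.8, weak = 0.2),
    list(field = "smokefree_enforcement", strong = 8L, weak = 1L),
    list(field = "media_tier", strong = "moderate", weak = "none"),
    list(field = "marketing_tier", strong = "direct_ban", weak = "none"),
    list(field = "marketing_enforcement", strong = 9L, weak = 0L),
    list(field = "cessation_provision", strong = "most", weak = "none"),
    list(field = "excise_share", strong = 0.70, weak = 0.40)
  )
  for (seed in 1:20) {
    gen <- generate_profile(seed)
    for (w in weaker) {
      s_strong <- unclass(gen$status); s_strong[[w$field]] <- w$strong
      s_weak <- unclass(gen$status); s_weak[[w$field]] <- w$weak
      e_strong <- suppressWarnings(all_policy_effects(
        gen$profile, do.call(policy_status, s_strong), params))
      e_weak <- suppressWarnings(all_policy_effects(
        gen$profile, do.call(policy_status, s_weak), params))
      expect_gte(combine_effects(e_weak)$short_term,
                 combine_effects(e_strong)$short_term)
    }
  }
})
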