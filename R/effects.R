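# Per-domain incremental policy effects: the relative reduction in smoking
# prevalence from moving the current MPOWER policy level to the full MPOWER
# target. Incremental effect = target effect - current effect (absolute
# difference): this is the convention that reproduces the published
# single-policy effects exactly, whereas the relative-complement form
# (target - current)/(1 - current) does not.

new_policy_effect <- function(domain, short, params, adjustors = list(),
                              short_by_gender = NULL) {
  # negative increments (current stronger than target) clamp to zero; the
  # sub-unity cap keeps extreme inputs (e.g. huge implied price changes)
  # from implying more than the whole smoking population quitting
  short <- min(max(0, short), params$long_term_cap)
  long <- long_term_effect(short, domain, params)
  long_by_gender <- NULL
  if (!is.null(short_by_gender)) {
    short_by_gender <- pmin(pmax(short_by_gender, 0), params$long_term_cap)
    long_by_gender <- vapply(short_by_gender, long_term_effect,
                             numeric(1), domain = domain, params = params)
  }
  structure(
    list(domain = domain, short_term = short, long_term = long,
         short_by_gender = short_by_gender, long_by_gender = long_by_gender,
         adjustors = adjustors),
    class = "policy_effect"
  )
}

#' @export
print.policy_effect <- function(x, ...) {
  cat(sprintf("<policy_effect> %-10s short %5.2f%%  long %5.2f%%\n",
              x$domain, 100 * x$short_term, 100 * x$long_term))
  invisible(x)
}

#' Long-term (40-year) effect from a short-term (5-year) effect
#'
#' Each policy domain carries a long-term multiplier: the ratio of the
#' 40-year relative prevalence change to the 5-year change. The long-term
#' effect is the short-term effect times that multiplier, capped just below
#' one so extreme inputs cannot imply eliminating more than the whole
#' smoking population.
#'
#' @param short short-term fractional prevalence reduction, in `[0, 1)`.
#' @param domain one of [policy_domains()], or `"combined"` (multiplier 1:
#'   combined effects are pooled after per-domain multiplication).
#' @param params an [default_effect_params()] table.
#' @return the long-term fractional reduction.
#' @examples
#' p <- default_effect_params()
#' long_term_effect(0.026, "cessation", p)  # 0.065
#' @export
long_term_effect <- function(short, domain, params = default_effect_params()) {
  stopifnot(short >= 0, short < 1)
  mult <- if (domain == "combined") 1 else params[[domain]]$long_term_multiplier
  min(short * mult, params$long_term_cap)
}

# share-contingent scaling: the (1 - share) part of an effect survives zero
# enforcement/publicity; the remaining share scales linearly with the level.
contingent_factor <- function(share, level) (1 - share) + share * level

#' Relative cigarette price increase implied by an excise-share change
#'
#' Translates a change in the excise-tax share of the retail cigarette price
#' into a relative retail price change, holding the net-of-tax price
#' component fixed and applying the VAT rate multiplicatively to the
#' excise-inclusive price: with excise share `e` of retail and VAT rate `v`,
#' retail = net * (1 + v) / (1 - e * (1 + v)), so the price ratio is
#' (1 - e_current * (1+v)) / (1 - e_target * (1+v)).
#'
#' This net-price-fixed convention is one of several used in the tax
#' literature, and published country figures are not always derivable from
#' it (pass-through, industry pricing and rounding intervene); effect
#' computations therefore accept a `price_increase_override` so a published
#' country-specific price response can be pinned, as the packaged Israel
#' fixture does with its published 39%.
#'
#' @param status a [policy_status()] (uses `excise_share` and `vat_rate`).
#' @param params an [default_effect_params()] table (uses `tax_target_share`).
#' @return an object of class `price_change`: list with
#'   `current_excise_share`, `target_excise_share`, `vat_rate`,
#'   `relative_price_increase`.
#' @examples
#' s <- israel_profile()$status
#' compute_price_increase(s)$relative_price_increase
#' @export
compute_price_increase <- function(status, params = default_effect_params()) {
  e0 <- status$excise_share
  e1 <- params$tax_target_share
  v <- status$vat_rate
  if (e1 * (1 + v) >= 1) {
    stop_field("tax_target_share", "target excise share and VAT jointly consume the whole price")
  }
  rel <- (1 - e0 * (1 + v)) / (1 - e1 * (1 + v)) - 1
  structure(
    list(current_excise_share = e0, target_excise_share = e1, vat_rate = v,
         relative_price_increase = rel),
    class = "price_change"
  )
}

#' Tax policy effect
#'
#' Short-term effect of raising the excise tax to the MPOWER target share of
#' retail price: the magnitude of the prevalence elasticity times the
#' relative price increase. A country already at or above the target gets a
#' zero effect with a warning, not an error.
#'
#' @param profile a [country_profile()] (unused by the arithmetic; kept for a
#'   uniform effect signature).
#' @param status a [policy_status()].
#' @param params an [default_effect_params()] table.
#' @param price_increase_override optional fraction replacing the internally
#'   computed relative price increase (see [compute_price_increase()]).
#' @return a `policy_effect`.
#' @examples
#' isr <- israel_profile()
#' tax_effect(isr$profile, isr$status, price_increase_override = 0.39)
#' @export
tax_effect <- function(profile, status, params = default_effect_params(),
                       price_increase_override = NULL) {
  if (status$excise_share >= params$tax_target_share) {
    warning("excise share already at or above the MPOWER target; tax effect is zero")
    return(new_policy_effect("tax", 0, params,
                             adjustors = list(price_increase = 0)))
  }
  rel <- price_increase_override %||%
    compute_price_increase(status, params)$relative_price_increase
  short <- abs(params$elasticity) * rel
  new_policy_effect("tax", short, params,
                    adjustors = list(price_increase = rel,
                                     elasticity = params$elasticity))
}

#' Smoke-free air law effect
#'
#' The full-target effect per gender is the work-site ban effect scaled by
#' the urban adjustor `(1 - pct_agriculture)` and by labor-force
#' participation (work-site laws only reach people who work indoors), plus
#' the restaurant and pub/bar ban effects, all scaled by the enforcement and
#' publicity factors (25% of the effect is contingent on each). The current
#' effect is the current coverage fraction of the unscaled full effect,
#' scaled by the current enforcement and publicity factors. The incremental
#' effect is their difference; per-gender effects are pooled weighting by
#' smoker counts.
#'
#' @inheritParams tax_effect
#' @return a `policy_effect` carrying per-gender components.
#' @export
smokefree_effect <- function(profile, status, params = default_effect_params()) {
  sf <- params$smokefree
  urban <- 1 - profile$pct_agriculture
  # per-gender maximal effect, before enforcement/publicity scaling
  raw_full <- sf$effects[["workplace_full"]] * urban * profile$labor_participation +
    sf$effects[["restaurants"]] + sf$effects[["pubs_bars"]]

  enf_cur <- contingent_factor(sf$enforcement_share, status$smokefree_enforcement / 10)
  pub_cur <- contingent_factor(sf$publicity_share, status$publicity_level)
  # MPOWER target: full coverage, complete enforcement, full publicity
  full_g <- raw_full
  cur_g <- status$smokefree_coverage * raw_full * enf_cur * pub_cur
  short_g <- pmax(full_g - cur_g, 0)

  smokers <- profile$population * profile$prevalence
  pooled <- sum(short_g * smokers) / sum(smokers)
  new_policy_effect(
    "smokefree", pooled, params,
    adjustors = list(urban = urban,
                     labor = profile$labor_participation,
                     enforcement_factor = enf_cur,
                     publicity_factor = pub_cur),
    short_by_gender = short_g
  )
}

#' Cessation-treatment policy effect
#'
#' Cessation sub-policy effects are additive: NRT availability (0.667%
#' over-the-counter, 0.334% by prescription), prescription medications
#' (0.334%), treatment provision (2.25% in most facility types, 1.125% in
#' some), and a national quitline (0.5%). The full package is worth 4.75%;
#' a country with every sub-policy at its maximum level is credited the
#' full-package value, so its incremental effect is zero. Otherwise the
#' incremental effect is the full-package effect minus the sum already
#' in place, with the publicity factor (25% of the effect is
#' publicity-contingent) applied symmetrically to both terms at the
#' scenario's publicity level — full publicity under the MPOWER target, so
#' the factor is one there. An optional urban adjustment
#' (`params$cessation$urban_adjust`) scales both terms by
#' `1 - pct_agriculture`; it defaults off (see [default_effect_params()]).
#'
#' @inheritParams tax_effect
#' @param target_publicity publicity level of the target scenario (default 1,
#'   full publicity under complete MPOWER implementation).
#' @return a `policy_effect`.
#' @export
cessation_effect <- function(profile, status, params = default_effect_params(),
                             target_publicity = 1) {
  ce <- params$cessation
  eff <- ce$effects
  at_max <- status$cessation_nrt == "otc" &&
    status$cessation_rx_meds == "with_prescription" &&
    status$cessation_provision == "most" &&
    isTRUE(status$cessation_quitline)
  # with the complete package in place the overall published effect (4.75%)
  # is credited, not the (smaller) additive sum of sub-effects, so a country
  # already at the target sees a zero incremental effect
  current <- if (at_max) ce$full else sum(
    switch(status$cessation_nrt, otc = eff[["nrt_otc"]],
           with_prescription = eff[["nrt_rx"]], none = 0),
    switch(status$cessation_rx_meds, with_prescription = eff[["rx_meds"]], none = 0),
    switch(status$cessation_provision, most = eff[["provision_most"]],
           some = eff[["provision_some"]], none = 0),
    if (status$cessation_quitline) eff[["quitline"]] else 0
  )
  pub <- contingent_factor(ce$publicity_share, target_publicity)
  scale <- pub * if (isTRUE(ce$urban_adjust)) 1 - profile$pct_agriculture else 1
  short <- scale * max(0, ce$full - current)
  new_policy_effect("cessation", short, params,
                    adjustors = list(current_sum = current,
                                     publicity_factor = pub))
}

#' Mass-media campaign effect
#'
#' Campaign tiers are mutually exclusive (none / low / moderate / high,
#' worth 0% / 1% / 3.5% / 6.5%); the incremental effect of moving to a
#' highly publicized national campaign is the high-tier effect minus the
#' current tier's.
#'
#' @inheritParams tax_effect
#' @return a `policy_effect`.
#' @export
media_effect <- function(status, params = default_effect_params()) {
  eff <- params$media$effects
  short <- eff[["high"]] - eff[[status$media_tier]]
  new_policy_effect("media", short, params,
                    adjustors = list(current_tier = status$media_tier))
}

#' Marketing-restriction effect
#'
#' Half of a marketing ban's effect is contingent on enforcement. The
#' current effect is the current tier's effect (partial 1%, direct-only 3%,
#' comprehensive 5%) scaled by `0.5 + 0.5 * enforcement/10`; the target is a
#' fully enforced comprehensive ban on direct and indirect advertising.
#'
#' @inheritParams tax_effect
#' @return a `policy_effect`.
#' @export
marketing_effect <- function(status, params = default_effect_params()) {
  mk <- params$marketing
  enf <- contingent_factor(mk$enforcement_share, status$marketing_enforcement / 10)
  current <- mk$effects[[status$marketing_tier]] * enf
  short <- mk$effects[["comprehensive"]] - current
  new_policy_effect("marketing", short, params,
                    adjustors = list(current_tier = status$marketing_tier,
                                     enforcement_factor = enf))
}

#' Health-warning effect
#'
#' Moving to complete warnings (bold, graphic, covering half the pack) is
#' worth 2%. By default the existing warning tier is credited at zero — the
#' step to graphic warnings is treated as a qualitatively new stimulus for
#' smokers habituated to the current text warning — so the full 2% applies;
#' set `baseline_credit = TRUE` to subtract the current tier's effect
#' instead.
#'
#' @inheritParams tax_effect
#' @param baseline_credit subtract the current tier's effect from the
#'   complete-tier effect (default `FALSE`).
#' @return a `policy_effect`.
#' @export
warnings_effect <- function(status, params = default_effect_params(),
                            baseline_credit = FALSE) {
  eff <- params$warnings$effects
  base <- if (isTRUE(baseline_credit)) eff[[status$warning_tier]] else 0
  new_policy_effect("warnings", eff[["complete"]] - base, params,
                    adjustors = list(current_tier = status$warning_tier,
                                     baseline_credit = baseline_credit))
}

#' Compute all six per-domain policy effects
#'
#' @inheritParams tax_effect
#' @param price_increase_override optional pinned relative price increase for
#'   the tax domain.
#' @param baseline_credit passed to [warnings_effect()].
#' @return named list of `policy_effect` objects, in [policy_domains()] order.
#' @examples
#' isr <- israel_profile()
#' eff <- all_policy_effects(isr$profile, isr$status,
#'                           price_increase_override = isr$price_increase_override)
#' sapply(eff, `[[`, "short_term")
#' @export
all_policy_effects <- function(profile, status, params = default_effect_params(),
                               price_increase_override = NULL,
                               baseline_credit = FALSE) {
  list(
    smokefree = smokefree_effect(profile, status, params),
    cessation = cessation_effect(profile, status, params),
    media     = media_effect(status, params),
    warnings  = warnings_effect(status, params, baseline_credit = baseline_credit),
    marketing = marketing_effect(status, params),
    tax       = tax_effect(profile, status, params, price_increase_override)
  )
}
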