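#' Default MPOWER effect-size parameter table
#'
#' Returns the constants that drive the simulation: for each of the six
#' MPOWER policy domains, the maximal short-term (5-year) relative reduction
#' in smoking prevalence by policy tier, the long-term (40-year) multiplier,
#' the share of the effect contingent on enforcement and on publicity, the
#' urban-adjustment flag, and the plus/minus sensitivity range. Also carries
#' the prevalence elasticity of cigarette price (-0.15) and the MPOWER
#' excise-tax target (75% of retail price).
#'
#' Effects are fractions throughout (0.06 means a 6% relative prevalence
#' reduction); percent appears only at I/O boundaries. Tier effects are
#' asserted to increase strictly with tier strength at load time.
#'
#' The cessation `urban_adjust` flag defaults to `FALSE`: the additive
#' cessation sub-policy effects are national pharmaceutical/benefit policies
#' whose published overall effect (4.75%) is not labor-force limited, unlike
#' the work-site component of smoke-free laws.
#'
#' @param overrides optional named nested list merged over the defaults
#'   (e.g. `list(tax = list(long_term_multiplier = 2.5))`).
#' @return an object of class `effect_params`: a named list with elements
#'   `tax`, `smokefree`, `media`, `marketing`, `warnings`, `cessation`,
#'   `elasticity`, `tax_target_share`, `long_term_cap`, `publicity_presets`.
#' @examples
#' p <- default_effect_params()
#' p$smokefree$effects[["workplace_full"]]  # 0.06
#' p$cessation$long_term_multiplier         # 2.5
#' @export
default_effect_params <- function(overrides = NULL) {
  p <- list(
    elasticity = -0.15,
    tax_target_share = 0.75,
    long_term_cap = 0.999,
    # named presets for the continuous publicity level (campaign funding proxy)
    publicity_presets = c(none = 0, low = 0.25, moderate = 0.5, high = 1.0),
    tax = list(
      long_term_multiplier = 2,
      range = 0.25,
      urban_adjust = FALSE
    ),
    smokefree = list(
      effects = c(
        partial_facilities = 0.02, # ban in 2 of 3: health/university/government
        offices_only       = 0.04,
        workplace_full     = 0.06,
        restaurants        = 0.02,
        pubs_bars          = 0.01
      ),
      long_term_multiplier = 1.25,
      enforcement_share = 0.25,
      publicity_share = 0.25,
      range = 0.50,
      urban_adjust = TRUE
    ),
    media = list(
      effects = c(none = 0, low = 0.01, moderate = 0.035, high = 0.065),
      long_term_multiplier = 1.2,
      range = 0.50,
      urban_adjust = FALSE
    ),
    marketing = list(
      effects = c(none = 0, partial = 0.01, direct_ban = 0.03, comprehensive = 0.05),
      long_term_multiplier = 1.3,
      enforcement_share = 0.50,
      range = 0.50,
      urban_adjust = FALSE
    ),
    warnings = list(
      effects = c(none = 0, weak = 0.005, moderate = 0.01, complete = 0.02),
      long_term_multiplier = 2,
      range = 0.50,
      urban_adjust = FALSE
    ),
    cessation = list(
      effects = c(
        nrt_otc = 0.00667, nrt_rx = 0.00334, rx_meds = 0.00334,
        provision_most = 0.0225, provision_some = 0.01125, quitline = 0.005
      ),
      full = 0.0475, # all sub-policies combined, fully publicized
      long_term_multiplier = 2.5,
      publicity_share = 0.25,
      range = 0.75,
      urban_adjust = FALSE
    )
  )
  if (!is.null(overrides)) p <- utils::modifyList(p, overrides)
  validate_effect_params(p)
}

validate_effect_params <- function(p) {
  for (dom in policy_domains()) {
    d <- p[[dom]]
    if (d$long_term_multiplier < 1) stop_field(paste0(dom, "$long_term_multiplier"), "must be >= 1")
    if (!is_fraction(d$range)) stop_field(paste0(dom, "$range"), "must be a fraction in [0, 1]")
    eff <- d$effects
    if (!is.null(eff)) {
      if (any(eff < 0) || any(eff >= 1)) stop_field(paste0(dom, "$effects"), "must lie in [0, 1)")
    }
  }
  # tier monotonicity: stronger tiers must have strictly larger effects
  tiers <- list(
    smokefree = p$smokefree$effects[c("partial_facilities", "offices_only", "workplace_full")],
    media     = p$media$effects[c("none", "low", "moderate", "high")],
    marketing = p$marketing$effects[c("none", "partial", "direct_ban", "comprehensive")],
    warnings  = p$warnings$effects[c("none", "weak", "moderate", "complete")]
  )
  for (dom in names(tiers)) {
    if (any(diff(tiers[[dom]]) <= 0)) {
      stop_field(paste0(dom, "$effects"), "tier effects must increase strictly with tier strength")
    }
  }
  if (p$elasticity >= 0) stop_field("elasticity", "prevalence elasticity must be negative")
  if (!is_fraction(p$tax_target_share)) stop_field("tax_target_share", "must be a fraction")
  structure(p, class = "effect_params")
}

#' The six MPOWER policy domains, in report (scenario-table) order
#' @return character vector of domain identifiers
#' @export
policy_domains <- function() {
  c("smokefree", "cessation", "media", "warnings", "marketing", "tax")
}
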