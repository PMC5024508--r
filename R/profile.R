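#' Construct a country profile
#'
#' A country profile holds the demographic side of the model for one baseline
#' year: adult (ages 20+) population and current-smoking prevalence by
#' gender, the labor statistics that drive the work-site urban adjustment,
#' and the bounds on the fraction of current smokers expected to die
#' prematurely from smoking.
#'
#' @param name country name.
#' @param year baseline calendar year.
#' @param population named numeric vector of adult population counts, one
#'   element per gender (conventionally `male`, `female`); strictly positive
#'   whole numbers.
#' @param prevalence named numeric vector of current-smoking prevalence
#'   fractions, same names as `population`.
#' @param pct_agriculture fraction of workers employed in agriculture; the
#'   work-site smoke-free effect is scaled by `1 - pct_agriculture`.
#' @param labor_participation named vector of labor-force participation
#'   fractions per gender.
#' @param death_fraction_lower,death_fraction_upper lower and upper bounds on
#'   the proportion of current smokers who will die prematurely from smoking
#'   (defaults 0.50 and 0.65).
#' @return an object of class `country_profile`.
#' @examples
#' country_profile("Demo", 2020,
#'   population = c(male = 1e6, female = 1e6),
#'   prevalence = c(male = 0.25, female = 0.15),
#'   pct_agriculture = 0.05,
#'   labor_participation = c(male = 0.7, female = 0.6))
#' @export
country_profile <- function(name, year, population, prevalence,
                            pct_agriculture, labor_participation,
                            death_fraction_lower = 0.50,
                            death_fraction_upper = 0.65) {
  obj <- structure(
    list(
      name = as.character(name), year = as.integer(year),
      population = population, prevalence = prevalence,
      pct_agriculture = pct_agriculture,
      labor_participation = labor_participation,
      death_fraction_lower = death_fraction_lower,
      death_fraction_upper = death_fraction_upper
    ),
    class = "country_profile"
  )
  validate_country_profile(obj)
}

validate_country_profile <- function(p) {
  g <- names(p$population)
  if (is.null(g) || any(!nzchar(g))) stop_field("population", "must be a named per-gender vector")
  p$population <- stats::setNames(as.numeric(p$population), g)
  if (any(p$population <= 0) || any(p$population != round(p$population))) {
    stop_field("population", "counts must be strictly positive whole numbers")
  }
  for (f in c("prevalence", "labor_participation")) {
    if (!identical(sort(names(p[[f]])), sort(g))) {
      stop_field(f, "gender names must match those of population")
    }
    check_fraction(p[[f]], f)
    p[[f]] <- p[[f]][g] # align order
  }
  check_fraction(p$pct_agriculture, "pct_agriculture")
  check_fraction(p$death_fraction_lower, "death_fraction_lower")
  check_fraction(p$death_fraction_upper, "death_fraction_upper")
  if (p$death_fraction_lower > p$death_fraction_upper) {
    stop_field("death_fraction_lower", "must not exceed death_fraction_upper")
  }
  p
}

#' Construct an MPOWER policy status
#'
#' Records the current level of each of the six MPOWER policy domains for a
#' country, in the units the model consumes: coverage fractions, 0-10
#' enforcement scores, named policy tiers, tax shares, and a continuous
#' publicity level in `[0, 1]` (named presets `none`/`low`/`moderate`/`high`
#' map to 0/0.25/0.5/1).
#'
#' @param smokefree_coverage fraction of the full smoke-free regime currently
#'   in force.
#' @param smokefree_enforcement integer compliance score 0-10.
#' @param cessation_nrt availability of nicotine replacement therapy:
#'   `"none"`, `"with_prescription"`, or `"otc"`.
#' @param cessation_rx_meds availability of prescription cessation
#'   medications (bupropion/varenicline): `"none"` or `"with_prescription"`.
#' @param cessation_provision coverage of cessation treatment provision:
#'   `"none"`, `"some"`, or `"most"`.
#' @param cessation_quitline logical; is a national quitline operating?
#' @param media_tier media-campaign tier: `"none"`, `"low"`, `"moderate"`,
#'   `"high"`.
#' @param marketing_tier marketing-restriction tier: `"none"`, `"partial"`,
#'   `"direct_ban"`, `"comprehensive"`.
#' @param marketing_enforcement integer compliance score 0-10.
#' @param warning_tier health-warning tier: `"none"`, `"weak"`, `"moderate"`,
#'   `"complete"`.
#' @param excise_share excise tax as a fraction of the retail cigarette price.
#' @param vat_rate value-added tax rate (fraction of pre-VAT price).
#' @param publicity_level tobacco-control campaign funding/publicity level,
#'   a fraction in `[0, 1]` or one of the preset names.
#' @return an object of class `policy_status`.
#' @export
policy_status <- function(smokefree_coverage,
                          smokefree_enforcement,
                          cessation_nrt,
                          cessation_rx_meds,
                          cessation_provision,
                          cessation_quitline,
                          media_tier,
                          marketing_tier,
                          marketing_enforcement,
                          warning_tier,
                          excise_share,
                          vat_rate,
                          publicity_level) {
  obj <- structure(
    list(
      smokefree_coverage = smokefree_coverage,
      smokefree_enforcement = smokefree_enforcement,
      cessation_nrt = cessation_nrt,
      cessation_rx_meds = cessation_rx_meds,
      cessation_provision = cessation_provision,
      cessation_quitline = cessation_quitline,
      media_tier = media_tier,
      marketing_tier = marketing_tier,
      marketing_enforcement = marketing_enforcement,
      warning_tier = warning_tier,
      excise_share = excise_share,
      vat_rate = vat_rate,
      publicity_level = publicity_level
    ),
    class = "policy_status"
  )
  validate_policy_status(obj)
}

validate_policy_status <- function(s) {
  check_fraction(s$smokefree_coverage, "smokefree_coverage")
  s$smokefree_enforcement <- check_enforcement(s$smokefree_enforcement, "smokefree_enforcement")
  check_enum(s$cessation_nrt, c("none", "with_prescription", "otc"), "cessation_nrt")
  check_enum(s$cessation_rx_meds, c("none", "with_prescription"), "cessation_rx_meds")
  check_enum(s$cessation_provision, c("none", "some", "most"), "cessation_provision")
  if (!is.logical(s$cessation_quitline) || length(s$cessation_quitline) != 1L ||
      is.na(s$cessation_quitline)) {
    stop_field("cessation_quitline", "must be TRUE or FALSE")
  }
  check_enum(s$media_tier, c("none", "low", "moderate", "high"), "media_tier")
  check_enum(s$marketing_tier, c("none", "partial", "direct_ban", "comprehensive"), "marketing_tier")
  s$marketing_enforcement <- check_enforcement(s$marketing_enforcement, "marketing_enforcement")
  check_enum(s$warning_tier, c("none", "weak", "moderate", "complete"), "warning_tier")
  check_fraction(s$excise_share, "excise_share")
  if (!is.numeric(s$vat_rate) || s$vat_rate < 0 || s$vat_rate >= 1) {
    stop_field("vat_rate", "must be a fraction in [0, 1)")
  }
  # excise + the VAT share of retail price must leave a positive net price
  vat_share <- s$vat_rate / (1 + s$vat_rate)
  if (s$excise_share + vat_share >= 1) {
    stop_field("excise_share", "excise share plus implied VAT share must be < 1")
  }
  if (is.character(s$publicity_level)) {
    presets <- c(none = 0, low = 0.25, moderate = 0.5, high = 1.0)
    check_enum(s$publicity_level, names(presets), "publicity_level")
    s$publicity_level <- unname(presets[s$publicity_level])
  }
  check_fraction(s$publicity_level, "publicity_level")
  s
}

#' The packaged Israel 2014 profile and policy status
#'
#' Returns the Israel configuration used throughout the package examples:
#' 2014 adult smoking prevalence of 24.5% (men) and 13.2% (women), 2% of
#' workers in agriculture, labor participation 70%/60% (men/women),
#' smoke-free coverage at 50% with enforcement 3/10, cessation treatment
#' available (over-the-counter NRT, prescription medications, provision in
#' some facility types, no national quitline), a low-level media presence,
#' a partial marketing ban with enforcement 2/10, moderate pack warnings, an
#' excise share of 69.03% of retail price with 17% VAT, and low publicity.
#'
#' Adult population counts are synthetic in the narrow sense that no census
#' figure is stored: they are back-derived from the published smoker counts
#' and prevalences (698,936 / 0.245 = 2,852,800 men; 394,152 / 0.132 =
#' 2,986,000 women), which the published table itself implies.
#'
#' The element `price_increase_override = 0.39` pins the relative cigarette
#' price increase implied by raising the excise share from 69% to 75%, the
#' published figure for Israel; see [compute_price_increase()] for why the
#' model does not derive it.
#'
#' @return a list with elements `profile` (a [country_profile()]), `status`
#'   (a [policy_status()]), and `price_increase_override`.
#' @examples
#' isr <- israel_profile()
#' isr$profile$prevalence[["male"]]  # 0.245
#' @export
israel_profile <- function() {
  list(
    profile = country_profile(
      name = "Israel", year = 2014,
      population = c(male = 2852800, female = 2986000),
      prevalence = c(male = 0.245, female = 0.132),
      pct_agriculture = 0.02,
      labor_participation = c(male = 0.70, female = 0.60),
      death_fraction_lower = 0.50,
      death_fraction_upper = 0.65
    ),
    status = policy_status(
      smokefree_coverage = 0.5,
      smokefree_enforcement = 3L,
      cessation_nrt = "otc",
      cessation_rx_meds = "with_prescription",
      cessation_provision = "some",
      cessation_quitline = FALSE,
      media_tier = "low",
      marketing_tier = "partial",
      marketing_enforcement = 2L,
      warning_tier = "moderate",
      excise_share = 0.6903,
      vat_rate = 0.17,
      publicity_level = "low"
    ),
    price_increase_override = 0.39
  )
}

#' @export
print.country_profile <- function(x, ...) {
  cat(sprintf("<country_profile> %s (%d)\n", x$name, x$year))
  for (g in names(x$population)) {
    cat(sprintf("  %-7s population %10s  prevalence %5.1f%%\n",
                g, format(x$population[[g]], big.mark = ","),
                100 * x$prevalence[[g]]))
  }
  cat(sprintf("  agriculture %.1f%%; death fractions %.0f-%.0f%%\n",
              100 * x$pct_agriculture, 100 * x$death_fraction_lower,
              100 * x$death_fraction_upper))
  invisible(x)
}
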