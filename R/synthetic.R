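# Synthetic country-profile generator. Sampling ranges bracket plausible
# national values (including the packaged Israel profile): they exist to
# exercise the model over its admissible input space for property testing,
# not to emulate any particular country's statistics.

#' Generate a random admissible country profile and policy status
#'
#' Draws every field of a [country_profile()] / [policy_status()] pair from
#' independent uniform distributions over admissible ranges: population per
#' gender in 1e5-1e7, prevalence in 0.05-0.50, agriculture share in 0-0.4,
#' labor participation in 0.4-0.9, enforcement scores uniform over 0-10,
#' policy tiers uniform over their enumerations, excise share in 0.30-0.74,
#' VAT in 0-0.25, publicity over the named presets. Deterministic for a
#' given seed; the generator uses its own RNG stream and leaves the global
#' random state untouched.
#'
#' @param seed integer seed governing all draws.
#' @param overrides optional list with `profile` and/or `status` sublists
#'   whose named elements replace the generated values before validation
#'   (so invalid overrides fail with an error naming the field). A
#'   `price_increase_override` element is passed through.
#' @return list with `profile`, `status` and (possibly `NULL`)
#'   `price_increase_override`, the same shape [israel_profile()] returns.
#' @examples
#' a <- generate_profile(1)
#' b <- generate_profile(1)
#' identical(a, b)  # TRUE
#' @export
generate_profile <- function(seed, overrides = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  pick <- function(x) x[[sample.int(length(x), 1L)]]
  prof_fields <- list(
    name = sprintf("synthetic-%d", as.integer(seed)),
    year = sample(2000:2025, 1L),
    population = round(stats::runif(2, 1e5, 1e7)),
    prevalence = stats::runif(2, 0.05, 0.50),
    pct_agriculture = stats::runif(1, 0, 0.4),
    labor_participation = stats::runif(2, 0.4, 0.9),
    death_fraction_lower = 0.50,
    death_fraction_upper = 0.65
  )
  for (f in c("population", "prevalence", "labor_participation")) {
    names(prof_fields[[f]]) <- c("male", "female")
  }
  stat_fields <- list(
    smokefree_coverage = stats::runif(1),
    smokefree_enforcement = sample(0:10, 1L),
    cessation_nrt = pick(c("none", "with_prescription", "otc")),
    cessation_rx_meds = pick(c("none", "with_prescription")),
    cessation_provision = pick(c("none", "some", "most")),
    cessation_quitline = pick(c(TRUE, FALSE)),
    media_tier = pick(c("none", "low", "moderate", "high")),
    marketing_tier = pick(c("none", "partial", "direct_ban", "comprehensive")),
    marketing_enforcement = sample(0:10, 1L),
    warning_tier = pick(c("none", "weak", "moderate", "complete")),
    excise_share = stats::runif(1, 0.30, 0.74),
    vat_rate = stats::runif(1, 0, 0.25),
    publicity_level = pick(c("none", "low", "moderate", "high"))
  )
  if (!is.null(overrides$profile)) {
    bad <- setdiff(names(overrides$profile), names(prof_fields))
    if (length(bad)) stop_field(bad[[1]], "unknown profile field")
    prof_fields[names(overrides$profile)] <- overrides$profile
  }
  if (!is.null(overrides$status)) {
    bad <- setdiff(names(overrides$status), names(stat_fields))
    if (length(bad)) stop_field(bad[[1]], "unknown status field")
    stat_fields[names(overrides$status)] <- overrides$status
  }
  list(
    profile = do.call(country_profile, prof_fields),
    status = do.call(policy_status, stat_fields),
    price_increase_override = overrides$price_increase_override %||% NULL
  )
}

#' The policy status of a country at the full MPOWER target
#'
#' Full smoke-free coverage with complete enforcement, every cessation
#' sub-policy in place, a highly publicized media campaign, a fully enforced
#' comprehensive marketing ban, complete warnings, the excise tax at the
#' target share, and full publicity. With this status the incremental effect
#' of every domain is zero (warnings require `baseline_credit = TRUE`, which
#' credits the existing complete warning).
#'
#' @param params an [default_effect_params()] table (for the target tax share).
#' @param vat_rate VAT rate to carry (default 0).
#' @return a [policy_status()].
#' @export
target_policy_status <- function(params = default_effect_params(), vat_rate = 0) {
  policy_status(
    smokefree_coverage = 1,
    smokefree_enforcement = 10L,
    cessation_nrt = "otc",
    cessation_rx_meds = "with_prescription",
    cessation_provision = "most",
    cessation_quitline = TRUE,
    media_tier = "high",
    marketing_tier = "comprehensive",
    marketing_enforcement = 10L,
    warning_tier = "complete",
    excise_share = params$tax_target_share,
    vat_rate = vat_rate,
    publicity_level = 1
  )
}
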