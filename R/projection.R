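# Turning effects into counts: smokers, reductions in smokers, and
# smoking-attributable deaths averted; pooling policies into a combined
# scenario.

#' Number of current smokers implied by a country profile
#'
#' Smokers per gender are prevalence times adult population; the total is
#' their sum. Counts are rounded half-away-from-zero at presentation.
#'
#' @param profile a [country_profile()].
#' @return list with `by_gender` (named counts) and `total`.
#' @examples
#' smokers_from_profile(israel_profile()$profile)$total  # 1,093,088
#' @export
smokers_from_profile <- function(profile) {
  by_gender <- round_count(profile$population * profile$prevalence)
  list(by_gender = by_gender, total = sum(by_gender))
}

#' Projected smoking-attributable deaths among current smokers
#'
#' Between 50% and 65% of current smokers are expected to die prematurely
#' from smoking; the bounds are the profile's death fractions applied to the
#' smoker count.
#'
#' @param smokers a smoker count (scalar or per-gender vector).
#' @param profile a [country_profile()] supplying the death fractions.
#' @return list with `lower` and `upper` death counts, rounded.
#' @examples
#' attributable_deaths(1093088, israel_profile()$profile)
#' @export
attributable_deaths <- function(smokers, profile) {
  stopifnot(all(smokers >= 0))
  list(lower = round_count(profile$death_fraction_lower * smokers),
       upper = round_count(profile$death_fraction_upper * smokers))
}

#' Combine policy effects multiplicatively
#'
#' Policies reaching their MPOWER targets together are pooled as
#' `1 - prod(1 - e_i)`, separately for the short- and long-term components:
#' each additional policy acts on the prevalence remaining after the others,
#' which proportionally shrinks its contribution and bounds the overall
#' effect in `[0, 1)`. The combination is order-invariant and dominates each
#' single effect.
#'
#' @param effects list of `policy_effect` objects.
#' @return a `policy_effect` with domain `"combined"`; per-gender components
#'   are combined gender-wise when any input carries them.
#' @examples
#' isr <- israel_profile()
#' eff <- all_policy_effects(isr$profile, isr$status,
#'                           price_increase_override = isr$price_increase_override)
#' combine_effects(eff)$short_term  # ~0.226
#' @export
combine_effects <- function(effects) {
  stopifnot(length(effects) >= 1)
  shorts <- vapply(effects, `[[`, numeric(1), "short_term")
  longs <- vapply(effects, `[[`, numeric(1), "long_term")
  stopifnot(all(shorts >= 0), all(shorts < 1), all(longs < 1))

  genders <- unique(unlist(lapply(effects, function(e) names(e$short_by_gender))))
  short_bg <- long_bg <- NULL
  if (length(genders)) {
    pick <- function(e, comp, scal, g) (e[[comp]] %||% stats::setNames(rep(e[[scal]], length(genders)), genders))[[g]]
    short_bg <- vapply(genders, function(g) {
      complement_product(vapply(effects, pick, numeric(1), "short_by_gender", "short_term", g))
    }, numeric(1))
    long_bg <- vapply(genders, function(g) {
      complement_product(vapply(effects, pick, numeric(1), "long_by_gender", "long_term", g))
    }, numeric(1))
  }
  structure(
    list(domain = "combined",
         short_term = complement_product(shorts),
         long_term = complement_product(longs),
         short_by_gender = short_bg, long_by_gender = long_bg,
         adjustors = list(n_policies = length(effects))),
    class = "policy_effect"
  )
}

#' Reduction in the number of smokers for a given effect
#'
#' @param effect fractional prevalence reduction in `[0, 1)` (scalar or
#'   per-gender vector).
#' @param smokers matching smoker count(s).
#' @return rounded count(s) of smokers no longer smoking.
#' @export
reduction_in_smokers <- function(effect, smokers) {
  stopifnot(all(effect >= 0), all(effect < 1))
  round_count(effect * smokers)
}

#' Build the full projection report
#'
#' One row per policy domain plus a combined row, each carrying the short-
#' and long-term effect, the long-term reduction in the number of smokers
#' (per gender and total), and the implied lower/upper smoking-attributable
#' deaths averted. The baseline block (smokers and projected deaths) is
#' attached as `attr(report, "baseline")`.
#'
#' Per-gender reductions use gender-specific effects where a policy has them
#' (only smoke-free air laws do, via labor-force participation); the
#' combined row is pooled gender-wise so its count columns are consistent
#' with its effect columns. All arithmetic is carried in full precision and
#' rounded only in the returned counts.
#'
#' @inheritParams all_policy_effects
#' @param direction `"central"` (default), `"lower"` or `"upper"`: evaluate
#'   the report with every domain's sensitivity range applied at that limit
#'   (see [apply_range()]).
#' @return a `projection_report`: a data.frame with one row per scenario.
#' @examples
#' isr <- israel_profile()
#' rep <- build_report(isr$profile, isr$status,
#'                     price_increase_override = isr$price_increase_override)
#' rep[rep$policy == "combined", ]
#' @export
build_report <- function(profile, status, params = default_effect_params(),
                         price_increase_override = NULL,
                         baseline_credit = FALSE,
                         direction = c("central", "lower", "upper")) {
  direction <- match.arg(direction)
  effects <- all_policy_effects(profile, status, params,
                                price_increase_override = price_increase_override,
                                baseline_credit = baseline_credit)
  if (direction != "central") {
    effects <- lapply(effects, apply_range, params = params, direction = direction)
  }
  effects$combined <- combine_effects(effects)

  smokers <- smokers_from_profile(profile)
  genders <- names(smokers$by_gender)
  deaths <- attributable_deaths(smokers$by_gender, profile)

  rows <- lapply(names(effects), function(dom) {
    e <- effects[[dom]]
    long_g <- e$long_by_gender %||% stats::setNames(rep(e$long_term, length(genders)), genders)
    red_g <- long_g[genders] * (profile$population * profile$prevalence)[genders]
    red_total <- sum(red_g)
    out <- data.frame(policy = dom,
                      short_term = e$short_term,
                      long_term = if (is.null(e$long_by_gender)) e$long_term else
                        red_total / sum(profile$population * profile$prevalence))
    for (g in genders) out[[paste0("reduction_", g)]] <- round_count(red_g[[g]])
    out$reduction_total <- round_count(red_total)
    for (g in genders) {
      out[[paste0("deaths_lower_", g)]] <- round_count(profile$death_fraction_lower * red_g[[g]])
    }
    out$deaths_lower_total <- round_count(profile$death_fraction_lower * red_total)
    for (g in genders) {
      out[[paste0("deaths_upper_", g)]] <- round_count(profile$death_fraction_upper * red_g[[g]])
    }
    out$deaths_upper_total <- round_count(profile$death_fraction_upper * red_total)
    out
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "baseline") <- list(
    name = profile$name, year = profile$year,
    prevalence = profile$prevalence,
    smokers_by_gender = smokers$by_gender,
    smokers_total = smokers$total,
    deaths_lower_by_gender = deaths$lower,
    deaths_lower_total = sum(deaths$lower),
    deaths_upper_by_gender = deaths$upper,
    deaths_upper_total = sum(deaths$upper)
  )
  class(report) <- c("projection_report", "data.frame")
  report
}

#' @export
print.projection_report <- function(x, ...) {
  b <- attr(x, "baseline")
  cat(sprintf("<projection_report> %s (%d)\n", b$name, b$year))
  cat(sprintf("  baseline smokers %s; projected deaths %s - %s\n",
              format(b$smokers_total, big.mark = ","),
              format(b$deaths_lower_total, big.mark = ","),
              format(b$deaths_upper_total, big.mark = ",")))
  df <- as.data.frame(x)
  # half-away-from-zero at one decimal; the epsilon keeps decimal halves
  # (e.g. 5.85%) from rounding down through binary representation error
  pct <- function(v) sprintf("-%.1f%%", floor(1000 * v + 0.5 + 1e-9) / 10)
  df$short_term <- pct(df$short_term)
  df$long_term <- pct(df$long_term)
  print(df, row.names = FALSE)
  invisible(x)
}
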