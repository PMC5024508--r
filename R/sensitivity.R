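# Interval sensitivity analysis: each domain's published effect size carries
# a plus/minus range (tax 25%, smoke-free/media/marketing/warnings 50%,
# cessation 75%). Ranges scale the computed incremental effect of the
# scenario — the quantity the uncertainty statement attaches to — not the
# per-tier maximal constants. The alternative reading — scaling the maximal
# constants — is arithmetically identical here, because every incremental
# effect is linear in its domain's constants (current and target levels use
# the same ones), so no separate switch is needed.

#' Scale a policy effect to a sensitivity limit
#'
#' Multiplies the effect (short- and long-term, and per-gender components)
#' by `1 - range` or `1 + range` for its domain, clamping to `[0, 1)`.
#' Applying the lower limit and then rescaling by `(1 + r) / (1 - r)`
#' recovers the upper limit exactly (pre-clamp): the scaling is linear.
#'
#' @param effect a `policy_effect`.
#' @param params an [default_effect_params()] table.
#' @param direction `"lower"` or `"upper"`.
#' @return the scaled `policy_effect`.
#' @examples
#' isr <- israel_profile()
#' e <- tax_effect(isr$profile, isr$status, price_increase_override = 0.39)
#' apply_range(e, direction = "upper")$short_term  # 0.0585 * 1.25
#' @export
apply_range <- function(effect, params = default_effect_params(),
                        direction = c("lower", "upper")) {
  direction <- match.arg(direction)
  r <- if (effect$domain == "combined") 0 else params[[effect$domain]]$range
  f <- if (direction == "lower") 1 - r else 1 + r
  clamp <- function(x) pmin(pmax(x, 0), params$long_term_cap)
  effect$short_term <- clamp(effect$short_term * f)
  effect$long_term <- clamp(effect$long_term * f)
  if (!is.null(effect$short_by_gender)) {
    effect$short_by_gender <- clamp(effect$short_by_gender * f)
    effect$long_by_gender <- clamp(effect$long_by_gender * f)
  }
  effect$adjustors$sensitivity <- c(direction = direction, factor = f)
  effect
}

#' Lower/central/upper projection reports
#'
#' Evaluates the full report with every domain's sensitivity range at its
#' lower limit, centrally, and at its upper limit simultaneously. The
#' central report lies cell-wise between the bounds.
#'
#' @inheritParams build_report
#' @return list with elements `lower`, `central`, `upper`, each a
#'   `projection_report`.
#' @examples
#' isr <- israel_profile()
#' b <- bounds_report(isr$profile, isr$status,
#'                    price_increase_override = isr$price_increase_override)
#' b$upper[b$upper$policy == "combined", "reduction_total"]
#' @export
bounds_report <- function(profile, status, params = default_effect_params(),
                          price_increase_override = NULL,
                          baseline_credit = FALSE) {
  one <- function(dir) build_report(profile, status, params,
                                    price_increase_override = price_increase_override,
                                    baseline_credit = baseline_credit,
                                    direction = dir)
  list(lower = one("lower"), central = one("central"), upper = one("upper"))
}
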