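---
title: "An abridged MPOWER tobacco-control policy model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An abridged MPOWER tobacco-control policy model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpowersim)
```

## The model

`mpowersim` implements an *abridged* tobacco-control policy simulation in
the SimSmoke family. The full models in that family evolve a population
through birth, death, smoking initiation and cessation year by year; the
abridged variant deliberately does not. It takes a **single baseline year**
— adult population and current-smoking prevalence by gender, plus the
current status of the six WHO MPOWER policy domains — and asks one
question: *if this country fully implemented the MPOWER package, by how
much would smoking prevalence among the people who smoke today fall, and
how many of their premature deaths would be averted?*

Two horizons are modelled, and only two: a short-term effect at 5 years and
a long-term effect at 40 years. Each policy domain has a short-term effect
size (a relative reduction in smoking prevalence, a fraction in $[0,1)$)
and a long-term multiplier (the ratio of the 40-year to the 5-year relative
change). Internally everything is a fraction; percent notation appears only
at I/O boundaries, which removes the most common class of bug in this kind
of model.

The projection side is deliberately simple. Smokers per gender are
prevalence times adult population. Between 50% and 65% of current smokers
are expected to die prematurely of smoking-related causes — the bounds that
generate the lower/upper death columns throughout. A policy effect $e$
translates into $e \times \text{smokers}$ fewer smokers, and averted deaths
are the death fractions applied to that reduction.

## Per-domain effect rules

Each domain's incremental effect is **target effect minus current effect**
(an absolute difference, see Design decisions below). The constants live in
`default_effect_params()` and can be overridden there or from the `params:`
block of a configuration file.

**Taxation.** Raising the excise tax to the MPOWER target of 75% of retail
price changes the retail price; the prevalence elasticity of price
($-0.15$) converts the relative price change into a relative prevalence
reduction: $e_\text{tax} = |\eta| \cdot \Delta p / p$. The long-term
multiplier is 2. The translation of an excise-share change into a price
change depends on pass-through behaviour that is country-specific;
`compute_price_increase()` implements a documented net-price-fixed
convention (VAT applied multiplicatively to the excise-inclusive price),
and every effect function accepts a `price_increase_override` so a
published country-specific price response can be pinned. The packaged
Israel profile pins 0.39, the published figure for its 69%→75% move.

**Smoke-free air laws.** The full-target effect per gender is the work-site
ban effect (6%) scaled by the urban adjustor $(1 - \text{agriculture
share})$ and by gender-specific labor-force participation — work-site laws
only reach people who work indoors — plus the restaurant (2%) and pub/bar
(1%) ban effects. 25% of the effect is contingent on enforcement (a 0–10
score) and 25% of it on publicity, via the factor $(1-s) + s\,\ell$: the
non-contingent share of the effect survives zero enforcement. The current
effect is the current coverage fraction of the unscaled full effect times
the current enforcement and publicity factors. Per-gender effects are
pooled weighting by smoker counts, which keeps the per-gender and total
count columns of the report mutually consistent.

**Cessation treatment.** Sub-policy effects are additive: NRT (0.667%
over-the-counter, 0.334% prescription-only), prescription medications
(0.334%), provision of treatment (2.25% in most facility types, 1.125% in
some), quitline (0.5%). The complete, fully publicized package is worth
4.75%; the incremental effect is 4.75% minus what is already in place. 25%
of the effect is publicity-contingent and the factor is applied
symmetrically to both the current and the target term at the scenario's
publicity level — full publicity under the MPOWER target, where the factor
is 1. Because the published sub-effects sum to 3.751%, not 4.75%, a country
with every sub-policy in place is credited the overall 4.75% directly, so
its incremental effect is zero rather than a spurious 1%. The long-term
multiplier is 2.5 — cessation support starts small but compounds the
fastest of all domains except warnings and tax.

**Media campaigns.** Tiers are mutually exclusive (none/low/moderate/high:
0%, 1%, 3.5%, 6.5%); the increment is the high tier minus the current tier.
Multiplier 1.2.

**Marketing restrictions.** Tier effects (partial 1%, direct-only 3%,
comprehensive 5%) with half the effect contingent on enforcement:
current $= e_\text{tier}\,(0.5 + 0.5\,\text{enf}/10)$; target is a fully
enforced comprehensive ban. Multiplier 1.3.

**Health warnings.** Complete (bold, graphic, half the pack) warnings are
worth 2%. By default the existing tier is credited at zero — the step to
graphic warnings is treated as a qualitatively new stimulus for smokers
habituated to the current text warning — so the full 2% applies;
`baseline_credit = TRUE` restores the subtraction. Multiplier 2.

## Combining policies and projecting counts

Policies implemented together are pooled with the complement product
$$e_\text{combined} = 1 - \prod_i (1 - e_i),$$
separately for the short- and long-term components. Each additional policy
acts on the prevalence the others leave behind, which proportionally
shrinks its contribution and bounds the overall effect in $[0,1)$ — a
deliberately conservative treatment of overlapping effects. The rule is
order-invariant, dominates each single effect, and equals the
inclusion–exclusion expansion of the union of independent events (the test
suite checks this against a brute-force oracle on up to four policies).

`build_report()` assembles the scenario table: one row per domain plus a
combined row, each with the short/long effects, the long-term reduction in
smokers (per gender and total) and the implied lower/upper deaths averted.
Only smoke-free effects differ by gender (via labor participation); the
other domains apply identically to both. All arithmetic is carried in full
precision; counts are rounded half-away-from-zero once, at presentation.
The combined row's displayed effect is the smoker-weighted pooled effect
(total reduction over total smokers), so its effect and count columns agree.

## Sensitivity analysis

Each domain's effect size carries a published plus/minus range: ±25% for
tax, ±50% for smoke-free, media, marketing and warnings, ±75% for
cessation. `bounds_report()` re-evaluates the whole table with every range
at its lower and at its upper limit simultaneously; the central report lies
cell-wise between the bounds. The ranges scale the computed incremental
effect of the scenario, the quantity the uncertainty statement attaches to.
Scaling the per-tier maximal constants instead would be arithmetically
identical here, because every incremental effect is linear in its domain's
constants; no separate switch is therefore provided. Ranges compound
multiplicatively with the enforcement and publicity factors. Uncertainty
propagation is interval-only by design — the published ranges are interval
statements, and a Monte Carlo treatment would manufacture distributional
assumptions the inputs do not support.

## Numerical choices and degenerate inputs

* Incremental effects clamp at zero when the current policy already exceeds
  the target (e.g. an excise share at or above 75% yields a zero tax effect
  with a warning, not an error).
* Short- and long-term effects cap at 0.999: extreme synthetic inputs (a
  small excise share with a high VAT implies a very large price change) may
  otherwise imply more than the whole smoking population quitting.
* The publicity level is a continuous fraction in $[0,1]$ with named
  presets none = 0, low = 0.25, moderate = 0.5, high = 1, because policy
  reports grade publicity qualitatively; the presets are overridable in any
  configuration file.
* Counts round half-away-from-zero at presentation only; golden tests on
  count columns therefore use relative tolerances (≤0.5%) while
  ratio-derived identities (deaths-lower / deaths-upper) hold exactly
  pre-rounding.

## The Israel profile

The packaged configuration (`inst/extdata/israel.yaml`,
`israel_profile()`) describes Israel in 2014: prevalence 24.5% (men) and
13.2% (women), 2% of workers in agriculture, labor participation 70%/60%,
smoke-free coverage at 50% with enforcement 3/10, over-the-counter NRT plus
prescription medications and provision in some facility types, no national
quitline, a low media tier, a partial marketing ban with enforcement 2/10,
moderate warnings, an excise share of 69.03% with 17% VAT, and low
publicity. The adult population counts carry a caveat: no census figure is
stored; they are back-derived from the published smoker counts and
prevalences (698,936/0.245 = 2,852,800 men; 394,152/0.132 = 2,986,000
women) and are labelled as derived in the file.

```{r israel}
isr <- israel_profile()
report <- build_report(isr$profile, isr$status,
                       price_increase_override = isr$price_increase_override)
report
```

## The synthetic generator, and what passing tests show

`generate_profile()` draws a complete admissible profile/status pair from
independent uniforms: population per gender in $10^5$–$10^7$, prevalence in
0.05–0.50, agriculture share in 0–0.4, labor participation in 0.4–0.9,
enforcement scores uniform on 0–10, tiers uniform over their enumerations,
excise share in 0.30–0.74, VAT in 0–0.25. The ranges bracket plausible
national values (including the packaged Israel profile) so the pipeline is
exercised over its whole admissible input space; a single integer seed
governs all draws through a private RNG stream, and overrides pin any
field (subject to validation).

What the generator emulates is the *structure* of a national profile, not
real-world covariation: prevalence is drawn independently of tax levels,
enforcement independently of income, and no survey sampling error is
modelled (the model consumes point prevalences by design). Passing the
property suite therefore demonstrates that the model's structural
invariants — effects in $[0,1)$, zero increment at the MPOWER target,
monotonicity in the policy gap, combined-row dominance, sensitivity
bracketing — hold over the admissible input space; it says nothing about
the empirical accuracy of the effect sizes themselves, which come from the
published literature. The test suite sweeps 1,000 seeded profiles through
the full pipeline (bounds included); the `analysis/05` driver reports the
same invariants over 500.

## Known limitations

The abridged design inherits real restrictions: no cohort dynamics, so no
effects on future initiation, youth, or the unborn; no time path between
the 5- and 40-year horizons; current smokers only, with no spontaneous
cessation trend; a single national profile with no subpopulation
stratification; cigarettes only, with no substitution toward other tobacco
products; and mortality only — morbidity, secondhand-smoke exposure and
economic costs are out of scope. The tax price-change algebra is
convention-dependent, which is why the engine prefers a pinned published
price response where one exists.
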