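# Israel, baseline year 2014.
# Adult (20+) population counts are synthetic/back-derived: published smoker
# counts divided by the published prevalences (698,936 / 24.5% men;
# 394,152 / 13.2% women) — no census figure is stored here.
name: Israel
year: 2014
population:
  male: 2852800
  female: 2986000
prevalence:
  male: 24.5%
  female: 13.2%
pct_agriculture: 2%
labor_participation:
  male: 70%
  female: 60%
death_fraction:
  lower: 50%
  upper: 65%
policy:
  smokefree_coverage: 50%
  smokefree_enforcement: 3
  cessation_nrt: otc
  cessation_rx_meds: with_prescription
  cessation_provision: some
  cessation_quitline: no
  media_tier: low
  marketing_tier: partial
  marketing_enforcement: 2
  warning_tier: moderate
  excise_share: 69.03%
  vat_rate: 17%
  publicity_level: low
# Published relative cigarette price increase for the 69% -> 75% excise move;
# pinned because the price pass-through is country-specific (see
# ?compute_price_increase).
price_increase_override: 39%
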