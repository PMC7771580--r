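# Fortified-rice introduction in Brazil: worked case configuration.
# Supply is the miller's dispatch to retailers over the 27-month window;
# consumption parameters come from secondary consumption data and in-store
# consumer surveys.
product_name: Fortified rice (Brazil)
product_type: fast_moving
area: Brazil, regions served by the partner miller
period:
  start: "2013-02"
  end: "2015-04"
  label: February 2013 to April 2015
supply:
  mode: sales_distribution
  sales_volume: 11174.56
  unit: metric_tons
  quality_factor: 1       # independent testing found product within spec
  losses_factor: 1        # dispatch assumed fully sold; negligible losses
  leakage_fraction: 0
use:
  type: fast_moving
  base_daily_amount: 160.3   # g cooked rice per capita per day
  amount_basis: measured
  multipliers:
    - {name: share_of_rice_consumed_at_home, value: 0.85}
    - {name: fortified_share_of_home_rice, value: 0.60}
  conversion_divisor: 2.5    # cooked-to-dry mass ratio
  use_days: period           # staple food, consumed daily
  frequency_basis: measured
segments:
  - {name: repeat_consumers, supply_share: 0.82, use_days: period}
  - {name: trial_consumers, supply_share: 0.18, use_days: 30.4}
subgroups:
  - {name: women_15_49, population_fraction: 0.2814}
  - {name: children_6m_5y, population_fraction: 0.0654}
  - {name: lower_socioeconomic_classes, population_fraction: 0.741}
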