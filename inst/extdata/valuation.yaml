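# Monetary valuation context, Swedish 2018 price level.
# Wages are calibrated to the published unit-cost table (the underlying
# unrounded source data are not public); they sit at the Statistics Sweden
# 2018 mean gross hourly wage scale for physiotherapists and the general
# population respectively.
provider_gross_hourly_wage: 187.2
population_gross_hourly_wage: 196.58
social_fee_rate: 0.3142        # legally mandated minimum employer social fees
leisure_fraction: 0.30         # reference value of leisure time
facility_surcharge: 0.10       # facility rent surcharge on on-site staff time
user_fee_ceiling: 1100         # SEK per year; all patients assumed to reach it
training_wage_multiplier: 1.5
fx_usd_per_100_sek: 10.2
fx_eur_per_100_sek: 9.43
reference_year: 2018
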