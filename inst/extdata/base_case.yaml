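# Base-case parameter set: 4-state Markov cohort model of chronic idiopathic
# constipation under three treatment strategies (Japanese societal perspective,
# 2024 NHI prices, JPY). All monetary values are per 28-day cycle.
settings:
  cycle_length_days: 28
  n_cycles: 26
  annual_discount_rate: 0.02
  days_per_year: 365
  discount_timing: cycle-end        # or cycle-start
  cycle_convention: mortality-first # or accrue-first
  use_rounded_cycle_probs: false
reference_arm: elobixibat_10mg
arms:
- name: elobixibat_10mg
  drug_cost_per_cycle: 4715.2
  responder_proportion: 0.6012458
  risk_ratio_vs_reference: 1.0
- name: linaclotide_0.5mg
  drug_cost_per_cycle: 3869.6
  responder_proportion: 0.4302036
  risk_ratio_vs_reference: 0.7155
- name: lubiprostone_48ug
  drug_cost_per_cycle: 5600.0
  responder_proportion: 0.5308396
  risk_ratio_vs_reference: 0.8829
transitions:
  annual_relapse_prob: 0.15         # improved -> unimproved, expert opinion
  annual_mortality_prob: 0.0129     # all-cause, 12.9 per 1000 (2022)
  unimproved_mortality_multiplier: 1.0
qol:
  improved_score: 1.64              # PAC-QoL, >=3 complete evacuations
  unimproved_score: 1.88            # PAC-QoL, 0-1 complete evacuations
costs:
  disimpaction_per_cycle: 333.3     # NHI J022-2, once per 12 weeks
  enema_per_cycle: 1300.0           # NHI J022, once per 2 weeks
  addon_stimulant_per_cycle: 186.4  # senna extract / sennoside
  addon_osmotic_per_cycle: 365.4    # magnesium oxide
cost_components:
  prop_age_ge65: 0.4174669          # from age distribution 62.9 +/- 10.1
  care_time_frac_improved: 0.040238095   # 16.9 min of a 7-h caregiver workday
  care_time_frac_unimproved: 0.058095238 # 24.4 min of a 7-h caregiver workday
  prop_needing_care: 0.062952       # 18.3% using care services x 34.4% needing defecation management
  avg_wage_per_cycle: 286839.6      # 311,800 JPY/month converted to 28 days
  impairment_improved: 0.2057       # overall work productivity impairment, no CIC
  impairment_unimproved: 0.3518     # overall work productivity impairment, CIC
addon:
  enabled: false
  cycles_before_addon: 3            # tunnel length: add-on from the 3rd unimproved cycle
  improvement_prob: 0.04            # unimproved -> improved once on add-on therapy
  improvement_time_unit: cycle      # or year (converted to a per-cycle probability)
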