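# Registry of named synthetic-cohort scenarios.
#
# Risks r are per person-year.  p_impaired is the fraction of the born
# cohort carrying a congenital risk; the remainder has r = 0, which keeps the
# living denominators nearly constant through childhood.  n_individuals is the
# cohort size per (population, year) cell; the default cells form a
# single population-year so that expected-count mode yields one table.

inverse_proportion:
  family: reciprocal
  r_min: 0.0001     # negligible depletion of the mildest risks by age 10
  r_max: 1000.0     # severest risks act within hours (mean survival ~9 h)
  p_impaired: 0.02
  n_individuals: 10000000
  populations: [S1]
  years: [2000]
  cause_label: ALL

perinatal_uniform:
  family: uniform
  r_max: 50.0       # worst perinatal risks act within days
  p_impaired: 0.02
  n_individuals: 10000000
  populations: [S1]
  years: [2000]
  cause_label: XVI

bending:
  family: reciprocal
  r_min: 0.0001
  r_max: 1.5        # risk ceiling bends the trajectory at ~8 months
  p_impaired: 0.02
  n_individuals: 10000000
  populations: [S1]
  years: [2000]
  cause_label: OTHER

neoplasm_flat:
  family: point_mass
  r: 0.005          # constant low risk, negligible depletion before age 20
  p_impaired: 0.008 # susceptible subpopulation of 800 per 100,000
  n_individuals: 10000000
  populations: [S1]
  years: [2000]
  cause_label: II

homogeneous:
  family: point_mass
  r: 0.1
  p_impaired: 1.0
  n_individuals: 1000000
  populations: [S1]
  years: [2000]
  cause_label: ALL
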