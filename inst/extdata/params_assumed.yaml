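frequencies:
  BRCA2: 0.00102
  BRCA1: 0.00064
  HOXB13: 0.0017
  REC: 0.1
rr_brca2:
- age_lo: 0.0
  rr: 7.0
- age_lo: 55.0
  rr: 5.5
- age_lo: 65.0
  rr: 4.2
- age_lo: 75.0
  rr: 3.0
rr_brca1:
- age_lo: 0.0
  rr: 2.35
- age_lo: 65.0
  rr: 1.0
rr_hoxb13:
  pre1930: 2.0
  post1930: 3.6
hoxb13_cohort_split: 1930
rec_model: recessive
rr_rec: 10.0
sigma70: 2.13
sigma_rate: 0.989
alpha: 0.523
sensitivity:
  BRCA2: 0.83
  BRCA1: 0.65
  HOXB13: 1.0
pgs_nugget_sd: 0.2
grid:
  obs: 7
  res: 7
max_age: 90
default_birth_year: 1960
female_penetrance:
  breast:
    rates:
    - age_lo: 0.0
      rate: 0.0
    - age_lo: 25.0
      rate: 8.0e-05
    - age_lo: 30.0
      rate: 0.00025
    - age_lo: 35.0
      rate: 0.0006
    - age_lo: 40.0
      rate: 0.0012
    - age_lo: 45.0
      rate: 0.0018
    - age_lo: 50.0
      rate: 0.0023
    - age_lo: 60.0
      rate: 0.0028
    - age_lo: 70.0
      rate: 0.003
    rr_brca1: 8.0
    rr_brca2: 5.0
  ovarian:
    rates:
    - age_lo: 0.0
      rate: 0.0
    - age_lo: 35.0
      rate: 0.0001
    - age_lo: 45.0
      rate: 0.00025
    - age_lo: 55.0
      rate: 0.0004
    - age_lo: 65.0
      rate: 0.0005
    rr_brca1: 25.0
    rr_brca2: 8.0
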