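# Age-specific SIRS criterion limits, transcribed from the 2005 International
# Pediatric Sepsis Consensus Conference definitions. The rule engine treats
# this file as data: edit a copy and pass its path to load_thresholds() to
# run with different limits.
#
# Units: temperature degC (core), heart_rate and respiratory_rate per minute,
# leukocytes 10^3/uL, immature_neutrophil_limit a fraction in [0, 1].
# Limits are exclusive by default: a value must be strictly beyond a limit to
# fire (set limits_exclusive: false for weak inequalities).
# Bradycardia (low heart rate) is a criterion only in the bands that flag it.
version: ipscc-2005-v1
limits_exclusive: true
mandatory_criteria: [temperature, leukocytes]
immature_neutrophil_limit: 0.10
age_bands:
  - name: newborn            # 0 days to 1 week
    min_days: 0
    max_days: 7
    temperature: {lower: 36.0, upper: 38.5}
    heart_rate: {lower: 100, upper: 180, bradycardia: true}
    respiratory_rate: {upper: 50}
    leukocytes: {upper: 34.0}
  - name: neonate            # 1 week to 1 month
    min_days: 7
    max_days: 30
    temperature: {lower: 36.0, upper: 38.5}
    heart_rate: {lower: 100, upper: 180, bradycardia: true}
    respiratory_rate: {upper: 40}
    leukocytes: {lower: 5.0, upper: 19.5}
  - name: infant             # 1 month to 1 year
    min_days: 30
    max_days: 365
    temperature: {lower: 36.0, upper: 38.5}
    heart_rate: {lower: 90, upper: 180, bradycardia: true}
    respiratory_rate: {upper: 34}
    leukocytes: {lower: 5.0, upper: 17.5}
  - name: toddler_preschool  # over 1 year to 5 years
    min_days: 365
    max_days: 2190
    temperature: {lower: 36.0, upper: 38.5}
    heart_rate: {upper: 140}
    respiratory_rate: {upper: 22}
    leukocytes: {lower: 6.0, upper: 15.5}
  - name: school_age         # 6 to 12 years
    min_days: 2190
    max_days: 4745
    temperature: {lower: 36.0, upper: 38.5}
    heart_rate: {upper: 130}
    respiratory_rate: {upper: 18}
    leukocytes: {lower: 4.5, upper: 13.5}
  - name: adolescent         # 13 to under 18 years
    min_days: 4745
    max_days: 6570
    temperature: {lower: 36.0, upper: 38.5}
    heart_rate: {upper: 110}
    respiratory_rate: {upper: 14}
    leukocytes: {lower: 4.5, upper: 11.0}
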