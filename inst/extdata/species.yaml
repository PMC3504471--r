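rat:
  gestation_days: 21.5
  t_init: 22.0
  tau: 5.0
  fa_max: 1.0
  fa_min: 0.0
ferret:
  gestation_days: 41.0
  t_init: 49.0
  tau: 10.7
  fa_max: 1.0
  fa_min: 0.0
human:
  gestation_days: 270.0
  t_init: 173.0
  tau: 39.8
  fa_max: 1.0
  fa_min: 0.0
cat:
  gestation_days: 65.0
  t_init: .na.real
  tau: .na.real
  fa_max: 1.0
  fa_min: 0.0
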