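# Expected-median models for converting raw marker levels to MoMs,
# as printed with the source marker tables. RNA expression in relative
# (fold-change) units; CL in cm; MAP in mmHg. ga_days is gestational age at
# sampling in days; weight enters as log10(kg) where weight_transform says so.
PSME2:
  form: constant
  intercept: 0.85
NAMPT:
  form: constant
  intercept: 2.34
APOA1:
  form: constant
  intercept: 0.16
APOA4:
  form: constant
  intercept: 2.44
LET7G:
  form: log_linear
  intercept: -0.515
  ga_days: 0.0106
  weight: -0.232
  weight_transform: log10
CL_CM:
  form: linear
  intercept: 3.14
  weight: 0.00287
MAP_MMHG:
  form: linear
  intercept: 75.4
  weight: 0.0409
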