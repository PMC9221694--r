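# Best-fit logistic risk equations shipped as fixed fixtures.
# x = intercept + sum(coefficient * transformed predictor);
# risk probability p = e^x / (1 + e^x).
# Predictor vocabulary: markers enter as log10(MoM); race_other is the
# indicator of race other than non-Hispanic Black; earliest_prior_ptb_weeks
# is the earliest gestation (weeks) of a prior preterm birth, 40 if none;
# parity offsets are relative to parity 3+ (coefficient 0).
SPTB_LE32:
  outcome: SPTB_LE32
  intercept: 1.4677
  terms:
    - predictor: PSME2
      transform: log10_mom
      coefficient: 0.5732
    - predictor: LET7G
      transform: log10_mom
      coefficient: 0.8268
    - predictor: race_other
      transform: indicator
      coefficient: -1.8931
    - predictor: earliest_prior_ptb_weeks
      transform: linear
      coefficient: -0.1119
PTB_LT37:
  outcome: PTB_LT37
  intercept: 2.9733
  terms:
    - predictor: PSME2
      transform: log10_mom
      coefficient: 0.1964
    - predictor: race_other
      transform: indicator
      coefficient: -1.3671
    - predictor: smoker
      transform: indicator
      coefficient: -0.8335
    - predictor: earliest_prior_ptb_weeks
      transform: linear
      coefficient: -0.1111
EOP_LT34:
  outcome: EOP_LT34
  intercept: -7.900
  terms:
    - predictor: NAMPT
      transform: log10_mom
      coefficient: 2.2726
    - predictor: APOA1
      transform: log10_mom
      coefficient: 0.8267
    - predictor: nulliparous
      transform: indicator
      coefficient: 3.6091
    - predictor: parity_1_2
      transform: indicator
      coefficient: -7.9772
PE_ALL:
  outcome: PREECLAMPSIA
  intercept: -2.1134
  terms:
    - predictor: NAMPT
      transform: log10_mom
      coefficient: 1.0161
    - predictor: MAP_MMHG
      transform: log10_mom
      coefficient: 21.5283
    - predictor: nulliparous
      transform: indicator
      coefficient: 0.8873
    - predictor: parity_1_2
      transform: indicator
      coefficient: -0.8217
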