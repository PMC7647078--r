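{
  "criterion": "xingtai_cmp_criterion.csv",
  "D": "xingtai_cmp_D.csv",
  "P": "xingtai_cmp_P.csv",
  "S": "xingtai_cmp_S.csv",
  "I": "xingtai_cmp_I.csv",
  "R": "xingtai_cmp_R.csv"
}
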