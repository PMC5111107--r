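signatures:
  CCHS:
    name: CCHS
    genes:
    - symbol: BCCIP
      direction: up_is_risk
      weight: 0.543
    - symbol: BNIP3L
      direction: down_is_risk
      weight: -0.416
    - symbol: GADD45B
      direction: up_is_risk
      weight: 0.596
    - symbol: INSIG2
      direction: up_is_risk
      weight: 0.538
    - symbol: TP53
      direction: down_is_risk
      weight: -0.177
    rule:
      kind: linear_cutoff
      intercept: 1.301
      cutoff_mode: fixed
      cutoffs: 4.526
    labels:
    - label: low_risk
      prognosis: good
    - label: high_risk
      prognosis: bad
    housekeeping: ~
    delta_ct: ~
    training_sets: ~
  Yuen3:
    name: Yuen3
    genes:
    - symbol: TAZ
      direction: up_is_risk
    - symbol: AXL
      direction: up_is_risk
    - symbol: CTGF
      direction: up_is_risk
    rule:
      kind: tally
      reference: median
    labels:
    - label: '0'
      prognosis: good
    - label: '1'
      prognosis: intermediate
    - label: '2'
      prognosis: intermediate
    - label: '3'
      prognosis: bad
    housekeeping: ~
    delta_ct: ~
    training_sets: ~
  ColoGuidePro:
    name: ColoGuidePro
    genes:
    - symbol: DMBT1
      direction: up_is_risk
    - symbol: NT5E
      direction: up_is_risk
    - symbol: SEMA3A
      direction: up_is_risk
    - symbol: WNT11
      direction: up_is_risk
    - symbol: CXCL9
      direction: down_is_risk
    - symbol: OLFM4
      direction: down_is_risk
    - symbol: UGT2B17
      direction: down_is_risk
    rule:
      kind: tally
      reference: median
      threshold: 3
    labels:
    - label: good_prognosis
      prognosis: good
    - label: poor_prognosis
      prognosis: bad
    housekeeping: ~
    delta_ct: ~
    training_sets: ~
  Oncodefender:
    name: Oncodefender
    genes:
    - symbol: BMI1
      direction: unsigned
    - symbol: VEGFA
      direction: unsigned
    - symbol: H3F3B
      direction: unsigned
    - symbol: ETV6
      direction: unsigned
    - symbol: RPS10
      direction: unsigned
    rule:
      kind: product_ratio
      terms:
      - num:
        - BMI1
        - VEGFA
        den: H3F3B
        sign: 1.0
      - num:
        - ETV6
        - H3F3B
        den: RPS10
        sign: -1.0
      housekeeping_adjust: yes
      cutoff_mode: cohort_median
    labels:
    - label: low_risk
      prognosis: good
    - label: high_risk
      prognosis: bad
    housekeeping:
    - B2M
    - GUSB
    - POLR2L
    - PSMB6
    - UBC
    delta_ct: ~
    training_sets: ~
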