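# Default karyotype-cluster mapping: cluster -> {C(Xa:A) label: weight}.
# C(1:3) is adjacent to both C(1:2) and C(2:3) and is split half-and-half.
# Labels not listed here count toward the residual. Extend freely.
x1:
  C(1:2): 1.0
  C(1:1): 1.0
  C(1:3): 0.5
x2:
  C(2:2): 1.0
  C(3:2): 1.0
x3:
  C(2:3): 1.0
  C(3:3): 1.0
  C(1:3): 0.5
x4:
  C(2:4): 1.0
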