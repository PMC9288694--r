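synthetic_mrf_pwms.txt
  Synthetic JASPAR-style position count matrices constructed for this
  package: two E-box-binding myogenic-factor-like motifs (MYOD-like,
  MYOG-like) and two non-muscle decoys (GC-box-like, TATA-like). They are
  stand-ins built by hand, not matrices obtained from JASPAR; use real
  database matrices for any biological inference.
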