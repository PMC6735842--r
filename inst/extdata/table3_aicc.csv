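candidate_model,aicc
VS.TSW.MCT.endo.PD.PY,20.35
PY,26.72
MCT.PY,29.20
endo,36.04
PD,40.30
VS,47.79
VS.TSW,50.09
null,50.13
MCT,52.28
TSW,52.31
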