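ae,cost_per_event,incidence_trt,incidence_ctrl
nausea,71.00,0.07,0.06
anaemia,73.68,0.12,0.10
neutrophil,466.00,0.14,0.12
neutropenia,466.00,0.07,0.08
wbc,466.00,0.08,0.07
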