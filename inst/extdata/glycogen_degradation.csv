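"time_s","flux_mM_per_s"
0,0.0223003183131244
30,0.0111501591565622
100,0.0133801909878747
200,0.0245303501444369
300,0.0312204456383742
400,0.0223003183131244
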