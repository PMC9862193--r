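"time_s","flux_mM_per_s"
0,0.0206281142530989
20,0.0618843427592967
50,0.0773554284491209
100,0.0515702856327473
200,0.0257851428163736
300,0.0180495999714615
400,0.0206281142530989
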