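{
  "GLCi": 0.00380189673972492,
  "G6P": 0.8,
  "F6P": 0.15,
  "FBP": 0.15,
  "DHAP": 0.3,
  "GAP": 0.025,
  "BPG": 0.015,
  "P3G": 0.9,
  "P2G": 0.12,
  "PEP": 0.7,
  "PYR": 1.2,
  "ACE": 0.3,
  "G1P": 0.046,
  "UDPG": 0.49,
  "T6P": 0.01,
  "TREc": 0.025,
  "G3P": 0.15,
  "GLYCEROL": 9.45,
  "GLYCOGEN": 55.6,
  "ATP": 2.5,
  "ADP": 1,
  "AMP": 0.4,
  "NAD": 1.45,
  "NADH": 0.15,
  "PI": 25,
  "TREv": 0.73,
  "GLCec": 0.678365336201427,
  "TREec": 0.0189,
  "VOL": 1
}
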