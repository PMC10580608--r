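{
  "rows": ["attention_orientation", "memory", "fluency", "language", "visuospatial"],
  "columns": ["gc", "gf", "grw", "gq", "gsm", "glr", "gv", "gs", "ga"],
  "weights": [
    [28, 0, 0, 0, 28, 0, 0, 28, 16],
    [15, 0, 0, 0, 39, 46, 0, 0, 0],
    [25, 25, 0, 0, 0, 50, 0, 0, 0],
    [61, 0, 8, 0, 0, 0, 0, 0, 31],
    [0, 12, 0, 12, 13, 0, 63, 0, 0]
  ]
}
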