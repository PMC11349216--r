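{
  "adaptor": "CGGAGATGTGTATAAGAGACAG",
  "feature_barcode": "GTATGTCCGCTCGAT",
  "spacer_lens": [10, 9],
  "anchor_len": 20,
  "anatomy": {
    "cell_barcode_len": 16,
    "umi_len": 10,
    "tso": "TTTCTTATATGGG"
  }
}
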