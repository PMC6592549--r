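anchor: '3.32'
auxiliary_acidic: '5.46'
site_residues:
- '3.32'
- '3.33'
- '4.56'
- '5.46'
- '6.48'
- '6.51'
- '7.39'
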