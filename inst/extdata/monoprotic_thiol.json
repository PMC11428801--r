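{
  "name": "monoprotic thiol (logk 8)",
  "provenance": "fixture",
  "sites": [
    {
      "label": "S",
      "is_redox_site": true,
      "chalcogen": "S"
    }
  ],
  "micro_logk": [
    {
      "site": "S",
      "context": [],
      "logk": 8
    }
  ]
}
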