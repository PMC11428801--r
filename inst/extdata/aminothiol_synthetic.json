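{
  "name": "synthetic aminothiol",
  "provenance": "fixture",
  "sites": [
    {
      "label": "N",
      "is_redox_site": false
    },
    {
      "label": "S",
      "is_redox_site": true,
      "chalcogen": "S"
    },
    {
      "label": "O",
      "is_redox_site": false
    }
  ],
  "micro_logk": [
    {
      "site": "N",
      "context": [],
      "logk": 10.5
    },
    {
      "site": "N",
      "context": [
        "S"
      ],
      "logk": 9.9
    },
    {
      "site": "N",
      "context": [
        "O"
      ],
      "logk": 10.1
    },
    {
      "site": "N",
      "context": [
        "S",
        "O"
      ],
      "logk": 9.5
    },
    {
      "site": "S",
      "context": [],
      "logk": 8.5
    },
    {
      "site": "S",
      "context": [
        "N"
      ],
      "logk": 7.9
    },
    {
      "site": "S",
      "context": [
        "O"
      ],
      "logk": 8.2
    },
    {
      "site": "S",
      "context": [
        "N",
        "O"
      ],
      "logk": 7.6
    },
    {
      "site": "O",
      "context": [],
      "logk": 2.2
    },
    {
      "site": "O",
      "context": [
        "N"
      ],
      "logk": 1.8
    },
    {
      "site": "O",
      "context": [
        "S"
      ],
      "logk": 1.9
    },
    {
      "site": "O",
      "context": [
        "N",
        "S"
      ],
      "logk": 1.5
    }
  ]
}
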