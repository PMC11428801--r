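{
  "name": "synthetic disulfide dimer",
  "provenance": "fixture",
  "sites": [
    {
      "label": "N1",
      "is_redox_site": false
    },
    {
      "label": "N2",
      "is_redox_site": false
    },
    {
      "label": "O1",
      "is_redox_site": false
    },
    {
      "label": "O2",
      "is_redox_site": false
    }
  ],
  "micro_logk": [
    {
      "site": "N1",
      "context": [],
      "logk": 9.2
    },
    {
      "site": "N1",
      "context": [
        "N2"
      ],
      "logk": 8.8
    },
    {
      "site": "N1",
      "context": [
        "O1"
      ],
      "logk": 9
    },
    {
      "site": "N1",
      "context": [
        "N2",
        "O1"
      ],
      "logk": 8.6
    },
    {
      "site": "N1",
      "context": [
        "O2"
      ],
      "logk": 9
    },
    {
      "site": "N1",
      "context": [
        "N2",
        "O2"
      ],
      "logk": 8.6
    },
    {
      "site": "N1",
      "context": [
        "O1",
        "O2"
      ],
      "logk": 8.8
    },
    {
      "site": "N1",
      "context": [
        "N2",
        "O1",
        "O2"
      ],
      "logk": 8.4
    },
    {
      "site": "N2",
      "context": [],
      "logk": 9.2
    },
    {
      "site": "N2",
      "context": [
        "N1"
      ],
      "logk": 8.8
    },
    {
      "site": "N2",
      "context": [
        "O1"
      ],
      "logk": 9
    },
    {
      "site": "N2",
      "context": [
        "N1",
        "O1"
      ],
      "logk": 8.6
    },
    {
      "site": "N2",
      "context": [
        "O2"
      ],
      "logk": 9
    },
    {
      "site": "N2",
      "context": [
        "N1",
        "O2"
      ],
      "logk": 8.6
    },
    {
      "site": "N2",
      "context": [
        "O1",
        "O2"
      ],
      "logk": 8.8
    },
    {
      "site": "N2",
      "context": [
        "N1",
        "O1",
        "O2"
      ],
      "logk": 8.4
    },
    {
      "site": "O1",
      "context": [],
      "logk": 1.9
    },
    {
      "site": "O1",
      "context": [
        "N1"
      ],
      "logk": 1.7
    },
    {
      "site": "O1",
      "context": [
        "N2"
      ],
      "logk": 1.7
    },
    {
      "site": "O1",
      "context": [
        "N1",
        "N2"
      ],
      "logk": 1.5
    },
    {
      "site": "O1",
      "context": [
        "O2"
      ],
      "logk": 1.8
    },
    {
      "site": "O1",
      "context": [
        "N1",
        "O2"
      ],
      "logk": 1.6
    },
    {
      "site": "O1",
      "context": [
        "N2",
        "O2"
      ],
      "logk": 1.6
    },
    {
      "site": "O1",
      "context": [
        "N1",
        "N2",
        "O2"
      ],
      "logk": 1.4
    },
    {
      "site": "O2",
      "context": [],
      "logk": 1.9
    },
    {
      "site": "O2",
      "context": [
        "N1"
      ],
      "logk": 1.7
    },
    {
      "site": "O2",
      "context": [
        "N2"
      ],
      "logk": 1.7
    },
    {
      "site": "O2",
      "context": [
        "N1",
        "N2"
      ],
      "logk": 1.5
    },
    {
      "site": "O2",
      "context": [
        "O1"
      ],
      "logk": 1.8
    },
    {
      "site": "O2",
      "context": [
        "N1",
        "O1"
      ],
      "logk": 1.6
    },
    {
      "site": "O2",
      "context": [
        "N2",
        "O1"
      ],
      "logk": 1.6
    },
    {
      "site": "O2",
      "context": [
        "N1",
        "N2",
        "O1"
      ],
      "logk": 1.4
    }
  ]
}
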