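{
  "seed": 1,
  "n_reads": 5000,
  "n_samples": 3,
  "entries": [
    {
      "n_studies": 5,
      "profile": {
        "violations": [],
        "used_capture": true
      }
    },
    {
      "n_studies": 5,
      "profile": {
        "violations": [
          "untrimmed_adapters"
        ],
        "used_capture": true
      }
    },
    {
      "n_studies": 19,
      "profile": {
        "violations": [
          "aligned_only_no_raw"
        ],
        "used_capture": true
      }
    },
    {
      "n_studies": 4,
      "profile": {
        "violations": [],
        "used_capture": false
      }
    },
    {
      "n_studies": 6,
      "profile": {
        "violations": [
          "untrimmed_adapters"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 3,
      "profile": {
        "violations": [
          "aligned_only_no_raw"
        ],
        "used_capture": false
      }
    }
  ]
}
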