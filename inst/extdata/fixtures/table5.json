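{
  "seed": 5,
  "n_reads": 5000,
  "n_samples": 3,
  "entries": [
    {
      "n_studies": 6,
      "profile": {
        "violations": [
          "no_paper_total",
          "under_archive"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 4,
      "profile": {
        "violations": [
          "no_paper_total"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 17,
      "profile": {
        "violations": [
          "under_archive"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 15,
      "profile": {
        "violations": [],
        "used_capture": false
      }
    }
  ]
}
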