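{
  "seed": 2,
  "n_reads": 5000,
  "n_samples": 3,
  "entries": [
    {
      "n_studies": 2,
      "profile": {
        "violations": [],
        "used_capture": false
      }
    },
    {
      "n_studies": 1,
      "profile": {
        "violations": [
          "alignments_as_runs",
          "mapq_filter",
          "length_filter"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 1,
      "profile": {
        "violations": [
          "alignments_as_runs",
          "mapq_filter"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 7,
      "profile": {
        "violations": [
          "alignments_as_runs",
          "length_filter"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 5,
      "profile": {
        "violations": [
          "aligned_only_no_raw"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 7,
      "profile": {
        "violations": [
          "aligned_only_no_raw",
          "mapq_filter",
          "length_filter"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 3,
      "profile": {
        "violations": [
          "aligned_only_no_raw",
          "mapq_filter"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 7,
      "profile": {
        "violations": [
          "aligned_only_no_raw",
          "length_filter"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 9,
      "profile": {
        "violations": [
          "raw_only_no_alignments"
        ],
        "used_capture": false
      }
    }
  ]
}
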