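{
  "seed": 3,
  "n_reads": 5000,
  "n_samples": 3,
  "entries": [
    {
      "n_studies": 4,
      "profile": {
        "violations": [
          "no_read_groups",
          "invalid_bam",
          "sample_overregistration",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 2,
      "profile": {
        "violations": [
          "no_sm",
          "lb_mismatch",
          "invalid_bam",
          "sample_overregistration",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 7,
      "profile": {
        "violations": [
          "sm_mismatch",
          "no_lb",
          "invalid_bam",
          "sample_overregistration",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 2,
      "profile": {
        "violations": [
          "sm_mismatch",
          "no_lb",
          "sample_overregistration",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 8,
      "profile": {
        "violations": [
          "sm_mismatch",
          "lb_mismatch",
          "duplicate_sample_suffix",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 1,
      "profile": {
        "violations": [
          "sm_mismatch",
          "lb_mismatch",
          "no_accession_reuse",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 5,
      "profile": {
        "violations": [
          "multi_sm",
          "lb_mismatch",
          "no_accession_reuse",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 4,
      "profile": {
        "violations": [
          "no_accession_reuse",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 1,
      "profile": {
        "violations": [
          "raw_only_no_alignments",
          "no_accession_reuse",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 8,
      "profile": {
        "violations": [
          "raw_only_no_alignments",
          "no_library_protocol"
        ],
        "used_capture": false
      }
    }
  ]
}
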