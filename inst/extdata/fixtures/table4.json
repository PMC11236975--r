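{
  "seed": 4,
  "n_reads": 5000,
  "n_samples": 3,
  "entries": [
    {
      "n_studies": 1,
      "profile": {
        "violations": [],
        "used_capture": false
      }
    },
    {
      "n_studies": 2,
      "profile": {
        "violations": [
          "date_freetext_only",
          "date_no_c14"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 3,
      "profile": {
        "violations": [
          "no_coords",
          "date_freetext_only",
          "date_no_c14"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 1,
      "profile": {
        "violations": [
          "no_coords",
          "date_freetext_only",
          "date_no_c14",
          "no_voucher"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 3,
      "profile": {
        "violations": [
          "no_coords",
          "no_date",
          "no_voucher"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 2,
      "profile": {
        "violations": [
          "no_coords",
          "no_date",
          "tissue_freetext_only",
          "no_voucher"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 3,
      "profile": {
        "violations": [
          "geo_freetext_only",
          "no_date",
          "tissue_freetext_only",
          "no_voucher"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 10,
      "profile": {
        "violations": [
          "geo_freetext_only",
          "no_date",
          "no_tissue",
          "no_voucher"
        ],
        "used_capture": false
      }
    },
    {
      "n_studies": 17,
      "profile": {
        "violations": [
          "no_geo",
          "no_date",
          "no_tissue",
          "no_voucher"
        ],
        "used_capture": false
      }
    }
  ]
}
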