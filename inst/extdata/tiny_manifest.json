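{
  "transcripts": {
    "n_rows": 12,
    "accessions": ["NM_000001", "NM_000004", "NM_000002", "NM_000003", "NM_000005", "NM_000006", "NM_000007", "NM_000008", "NM_000009", "XM_000010", "NM_000011", "NM_000012"]
  },
  "snp_table": {
    "n_file_rows": 31,
    "n_records": 30,
    "per_chrom": {
      "1": 17,
      "2": 13
    },
    "duplicates_collapsed": 1,
    "n_qualifying": 28
  },
  "filter_report": {
    "n_input": 12,
    "removed_accession": 1,
    "removed_chromosome": 1,
    "removed_noncoding": 0,
    "removed_duplicate_tss": 1,
    "kept": 9,
    "kept_utr_positive": 7,
    "kept_utr_zero": 2
  },
  "contents": {
    "utrge0_TSS_500": {
      "NM_000001": 3,
      "NM_000002": 2,
      "NM_000003": 2,
      "NM_000005": 1,
      "NM_000006": 1,
      "NM_000007": 2,
      "NM_000008": 2,
      "NM_000009": 1,
      "NM_000012": 1
    },
    "utrge0_TSS_1000": {
      "NM_000001": 4,
      "NM_000002": 3,
      "NM_000003": 2,
      "NM_000005": 2,
      "NM_000006": 1,
      "NM_000007": 3,
      "NM_000008": 2,
      "NM_000009": 1,
      "NM_000012": 1
    },
    "utrge0_CRS_500": {
      "NM_000001": 4,
      "NM_000002": 2,
      "NM_000003": 2,
      "NM_000005": 2,
      "NM_000006": 1,
      "NM_000007": 2,
      "NM_000008": 1,
      "NM_000009": 1,
      "NM_000012": 1
    },
    "utrgt0_TSS_500": {
      "NM_000001": 3,
      "NM_000002": 2,
      "NM_000005": 1,
      "NM_000006": 1,
      "NM_000008": 2,
      "NM_000009": 1,
      "NM_000012": 1
    },
    "utrgt0_CRS_500": {
      "NM_000001": 4,
      "NM_000002": 2,
      "NM_000005": 2,
      "NM_000006": 1,
      "NM_000008": 1,
      "NM_000009": 1,
      "NM_000012": 1
    },
    "utrgt0_CRS_1000": {
      "NM_000001": 6,
      "NM_000002": 3,
      "NM_000005": 3,
      "NM_000006": 2,
      "NM_000008": 2,
      "NM_000009": 1,
      "NM_000012": 2
    }
  },
  "effective_length_exceptions": {
    "NM_000003": 300
  },
  "snp_rich": {
    "min_6": [],
    "min_2": ["NM_000001", "NM_000002", "NM_000003", "NM_000007", "NM_000008"]
  }
}
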