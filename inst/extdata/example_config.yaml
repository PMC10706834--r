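k_value: 0.43
lod_pct: 0.2
loq_max_abs_deviation: 25
seed: 1
output_dir: out
simulator:
  n_droplets: 20000
  droplet_volume_nl: 0.85
  extraction_cv: 0.05
assays:
  - species_label: Atlantic salmon
    gene: myoglobin
    accession: NM_001140642
    fwd_primer: GAGAGGTCACAGGGATAGGA
    rev_primer: CAAACCAGCACTTAGAATTTAC
    probe: AACTGGAAACTTACATTTGAAGCAG
    reporter_dye: HEX
    expected_amplicon_bp: 93
  - species_label: Rainbow trout
    gene: myoglobin
    accession: NM_001171862
    fwd_primer: TTGCTTGTGACTTCCAGA
    rev_primer: AGAGGAACAACGCACATT
    probe: ACTGGAAAAGTGTATGAGGCAAAGC
    reporter_dye: FAM
    expected_amplicon_bp: 141
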