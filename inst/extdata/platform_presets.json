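{
  "platform": ["HiSeq 2500", "HiSeq 2500", "HiSeq X", "DNBSEQ-G400",
               "DNBSEQ-T7", "NovaSeq 6000", "NovaSeq 6000", "NovaSeq 6000",
               "NovaSeq X Plus", "NovaSeq X Plus"],
  "mode": ["Rapid Run", "Rapid Run", "NA", "FCL", "NA", "S4", "S4", "S4",
           "10B", "25B"],
  "protocol": ["162PE", "259PE", "150PE", "150PE", "150PE", "150PE", "151PE",
               "161PE", "161PE", "161PE"],
  "read_length_bp": [162, 259, 150, 150, 150, 150, 151, 161, 161, 161],
  "paired": [true, true, true, true, true, true, true, true, true, true],
  "output_label": ["97Gb", "155Gb", "900Gb", "540Gb", "1.5Tb", "3Tb", "3Tb",
                   "3.2Tb", "3Tb", "8Tb"],
  "flowcells_per_run": [2, 2, 2, 2, 4, 2, 2, 2, 2, 2],
  "clusters_per_flowcell": [3e8, 3e8, null, null, null, null, null, null,
                            null, null]
}
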