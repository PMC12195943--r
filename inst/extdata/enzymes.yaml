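# Default specificity table for the three-protease gastric/pancreatic system.
# side: C-terminal = cut after the target residue, N-terminal = cut before.
# blocked_by_next (optional) lists residues on the distal side of the bond
# that veto the cut. Published platform tables carry richer subsite
# exceptions; supply your own table to match a specific platform exactly.
enzymes:
  - name: pepsin
    ec: 3.4.23.1
    rules:
      - residue: "F"
        side: C-terminal
      - residue: "L"
        side: C-terminal
  - name: trypsin
    ec: 3.4.21.4
    rules:
      - residue: "K"
        side: C-terminal
      - residue: "R"
        side: C-terminal
  - name: chymotrypsin A
    ec: 3.4.21.1
    rules:
      - residue: "Y"
        side: C-terminal
      - residue: "W"
        side: C-terminal
      - residue: "F"
        side: C-terminal
      - residue: "L"
        side: C-terminal
      - residue: "N"
        side: C-terminal
      - residue: "H"
        side: C-terminal
      - residue: "M"
        side: C-terminal
      - residue: "I"
        side: N-terminal
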