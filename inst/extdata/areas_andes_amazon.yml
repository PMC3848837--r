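# Geographic areas and connectivity for the Andes/Amazon/Atlantic Forest
# analysis: the Amazon is the only hub connecting the three regions, and
# ancestral ranges may span at most two areas.
areas:
  - code: A
    name: Amazon
  - code: B
    name: Andes
  - code: C
    name: Atlantic Forest
adjacency:
  - [A, B]
  - [A, C]
max_range_size: 2
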