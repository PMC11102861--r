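# Assay substrate presets: 7-mer body + 20-nt tails; mixed tails carry
# non-adenosine residues at tail positions 7 and 14 from the 3' end.
- name: A20
  body: UCUACAU
  tail: AAAAAAAAAAAAAAAAAAAA
- name: A20G
  body: UCUACAU
  tail: AAAAAAGAAAAAAGAAAAAA
- name: A20U
  body: UCUACAU
  tail: AAAAAAUAAAAAAUAAAAAA
- name: A20C
  body: UCUACAU
  tail: AAAAAACAAAAAACAAAAAA
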