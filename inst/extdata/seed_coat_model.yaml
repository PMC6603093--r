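loci:
- name: R
  chromosome: '3'
  dominance_note: dotted black dominant to green/red background
- name: T1
  chromosome: '5'
  dominance_note: tan1 dominant to red
- name: W
  chromosome: '6'
  dominance_note: non-clump dominant to clump
- name: D
  chromosome: '8'
  dominance_note: modifier; acts only when R, T and W are dominant
rules:
- pattern: R_ T_ W_ D_
  phenotype: flat black
- pattern: R_ T_ W_ dd
  phenotype: dotted black
- pattern: rr T_ W_ __
  phenotype: green
- pattern: R_ tt W_ __
  phenotype: tan
- pattern: R_ T_ ww __
  phenotype: clump
- pattern: rr tt W_ __
  phenotype: red
- pattern: R_ tt ww __
  phenotype: white tan-tip
- pattern: rr __ ww __
  phenotype: white pink-tip
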