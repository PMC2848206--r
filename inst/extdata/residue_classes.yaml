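# Default residue-class scheme for consensus lines.
# Evaluation order is most-specific first; h (broad hydrophobic) last.
threshold: 0.7
order: [l, s, p, h]
classes:
  h: ACFILMVWY
  l: ILV
  s: ACDGNPSTV
  p: CDEHKNQRST
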