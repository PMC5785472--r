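# Product specification for sceliphrolactam: a 26-membered polyene
# macrolactam primed with a 3-amino-2-methylpropionate starter, requiring
# eleven chain extensions (nine malonyl, two methylmalonyl). The
# per-extension unit states are transcribed from the published structure
# (they are drawn, not tabulated, in the source scheme, so this table is a
# figure-derived reconstruction): eight enoyl positions form the polyene,
# ketones at extensions 2 and 6, and the R-configured hydroxyl at
# extension 7 (carbon C-11) installed by the B-type KR of module 6. The
# cis double bond between C-14 and C-15 is the extension-5 enoyl. C-10 and
# C-12 hydroxyls are cytochrome P450 tailoring, not PKS chemistry.
name: sceliphrolactam
formula: {"C": 28, "H": 35, "N": 1, "O": 6}
ring_size: 26
starter: 3-amino-2-methylpropionate
branch_positions: [3, 9]
target_units:
  - {position: 1,  alpha: H,   beta: enoyl,    geometry: E}
  - {position: 2,  alpha: H,   beta: ketone}
  - {position: 3,  alpha: CH3, beta: enoyl,    geometry: E}
  - {position: 4,  alpha: H,   beta: enoyl,    geometry: E}
  - {position: 5,  alpha: H,   beta: enoyl,    geometry: Z}
  - {position: 6,  alpha: H,   beta: ketone}
  - {position: 7,  alpha: H,   beta: hydroxyl, stereo: R}
  - {position: 8,  alpha: H,   beta: enoyl,    geometry: E}
  - {position: 9,  alpha: CH3, beta: enoyl,    geometry: E}
  - {position: 10, alpha: H,   beta: enoyl,    geometry: E}
  - {position: 11, alpha: H,   beta: enoyl,    geometry: E}
position_annotations:
  C-10: {unit: 7, site: alpha}
  C-11: {unit: 7, site: beta}
  C-12: {unit: 6, site: alpha}
  C-14: {unit: 5, site: alpha}
  C-15: {unit: 5, site: beta}
  C-26: {unit: 3, site: methyl}
  C-27: {unit: 9, site: methyl}
tailoring:
  - {kind: hydroxylation, site: C-10, agent: sceD}
  - {kind: hydroxylation, site: C-12, agent: sceE}
  - {kind: amide_deprotection, site: N-1, agent: sceF}
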