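# Motif/signature tables for PKS domain scanning and classification.
# Anchors are POSIX extended regular expressions matched against the
# protein; a domain window of width_up/width_down residues is drawn around
# the anchor start. Catalytic rules are either a fixed residue at an offset
# from the anchor start (0-based) or a pattern that must occur inside the
# domain window.
domains:
  KS:
    anchor: "DTA.SS"   # catalytic Cys wildcarded so ablation keeps the hit
    width_up: 20
    width_down: 110
    catalytic:
      - {name: KS_cys, offset: 3, residue: C}
  AT:
    anchor: "GH..G"
    width_up: 20
    width_down: 110
    catalytic:
      - {name: AT_ser, offset: 2, residue: S}
  DH:
    anchor: ".ALLG....P"
    width_up: 20
    width_down: 110
    catalytic:
      - {name: DH_his, offset: 0, residue: H}
  ER:
    anchor: "GGVGMA"
    width_up: 20
    width_down: 110
    catalytic: []
  KR:
    anchor: "GGTG.LG"
    width_up: 20
    width_down: 110
    catalytic:
      - {name: KR_tyr, pattern: "Y...N"}
  ACP:
    anchor: "G.D.L"
    width_up: 20
    width_down: 110
    catalytic:
      - {name: ACP_ser, offset: 3, residue: S}
  TE:
    anchor: "GW..G"
    width_up: 20
    width_down: 110
    catalytic:
      - {name: TE_ser, offset: 2, residue: S}

# Acyltransferase substrate specificity: a short window at a fixed offset
# downstream of the GHSxG active-site motif is compared against reference
# patterns. The YASH/HAFH convention is the canonical methylmalonyl/malonyl
# discriminator from the AT-specificity literature; edit here to swap in
# alternative residue sets.
at:
  specificity_offset: 30   # residues from anchor start to window start
  window_length: 4
  patterns:
    methylmalonyl: "YASH"
    malonyl: "HAFH"

# Ketoreductase typing. B-type carries the (L/V)D(D/N) motif and yields
# R-configured beta-hydroxyls; the A-type tryptophan criterion is
# extrapolated from the KR-typing literature (flagged as such in reports).
kr:
  window_offset: 10        # search window start, residues after anchor start
  window_length: 60
  b_motif: "[LV]D[DN]"
  a_residue: "W"

# Docking-domain heuristic for protein termini outside the first/last
# domain hit: sliding-window heptad periodicity score (fraction of a/d
# positions that are hydrophobic, and of other positions that are polar,
# maximised over frames and windows).
docking:
  min_len: 25
  score_threshold: 0.8
  hydrophobic: "LIVMF"
  polar: "EKQRATSDNG"
  class_tags:              # short tag embedded next to the heptads
    D1: "DGSN"
    D2: "DGSS"
    D3: "DGSW"
    D4: "DGSY"
  pairing:                 # compatible (C-terminal class, N-terminal class)
    - [D1, D1]
    - [D2, D2]
    - [D3, D3]
    - [D4, D4]
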