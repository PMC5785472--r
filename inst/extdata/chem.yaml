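# Chemistry tables: monoisotopic element masses (CODATA/AME-sourced),
# adduct definitions, the starter-unit library and protecting-group
# formula deltas.
element_masses:
  "C": 12.0
  "H": 1.00782503207
  "N": 14.0030740048
  "O": 15.9949146196
  "Na": 22.9897692809
  "S": 31.97207100
  "P": 30.97376163

# Adducts are neutral-atom additions; reported m/z is the neutral
# monoisotopic mass rounded to 4 decimals plus the adduct atom mass
# rounded to 4 decimals (the standard "calcd" tabulation convention;
# electron mass neglected).
adducts:
  "[M+H]+": {"H": 1}
  "[M+Na]+": {"Na": 1}
  "M": {}

# Starter units for beta-amino-acid primed macrolactams. ring_atoms counts
# the atoms the starter contributes to the macrolactam ring, including the
# amide nitrogen; methyl_branches counts exocyclic CH3 groups on starter
# ring carbons (alpha_methyl marks the branch sitting next to the
# thioester/carboxyl carbon, as in 3-amino-2-methylpropionate).
starters:
  3-amino-2-methylpropionate:
    ring_atoms: 4
    alpha_methyl: true
    methyl_branches: 1
    amine_protected: true
  3-aminopropionate:
    ring_atoms: 4
    alpha_methyl: false
    methyl_branches: 0
    amine_protected: false
  3-methylaspartate:
    ring_atoms: 4
    alpha_methyl: true
    methyl_branches: 1
    amine_protected: true
  3-aminobutyrate:
    ring_atoms: 4
    alpha_methyl: false
    methyl_branches: 1
    amine_protected: false

# Formula delta of the amide protecting group installed on the starter
# amine during chain assembly and removed by tailoring (amide_deprotection).
protecting_groups:
  glycyl: {"C": 2, "H": 3, "N": 1, "O": 1}
default_protecting_group: glycyl
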