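# Default product-type grouping for count_by_type(). Matching is
# case-insensitive substring matching on the product/type column, so a
# hybrid cluster ("NRPS-T1PKS") counts toward every group it mentions.
# Named-product clusters (Filipins, Factumycin, ...) only count toward a
# class group if the class knowledge is encoded here; edit to taste.
groups:
  NRPS: ["NRPS"]
  RiPP: ["Lantipeptide", "Thiopeptide", "Lassopeptide"]
  Terpene: ["Terpene"]
  PKS:
    - "PKS"
    - "Filipins"          # type I modular PKS product
    - "Sceliphrolactam"   # type I modular PKS product
    - "Factumycin"        # type I modular PKS product
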