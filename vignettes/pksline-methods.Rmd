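---
title: "Auditing modular PKS assembly lines: methods and design notes"
author: "pksline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing modular PKS assembly lines: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksline)
```

## The problem

Type I modular polyketide synthases (PKS) are assembly lines: each module
performs one chain extension, and under the collinearity rule the number
and order of modules along the chromosome mirror the number and order of
extension reactions. A macrolactam of ring size $R$ built on a
$\beta$-amino-acid starter contributing $A$ ring atoms (amide nitrogen
included) therefore demands

$$E_{req} = \frac{R - A}{2}$$

extension modules, each extension adding two ring atoms
($R = 2E + A$). When a sequenced biosynthetic gene cluster (BGC) encodes
fewer modules than its product demands, two hypotheses compete: a
*trans*-acting module encoded elsewhere in the genome docks into the
complex, or one module acts *iteratively*, catalysing two successive
extensions. `pksline` turns that reasoning — usually done by hand over
annotation printouts — into a reusable, tested pipeline:

1. locate and classify catalytic domains in PKS proteins
   (`scan_domains()`, `classify_at_substrate()`, `classify_kr_type()`,
   `check_catalytic_activity()`);
2. group domains into modules and order them across genes
   (`build_modules()`, `order_assembly_line()`, `detect_docking()`);
3. predict the polyketide backbone, cyclize and compute formula/mass
   (`predict_backbone()`, `macrolactamize()`, `molecular_formula()`,
   `monoisotopic_mz()`);
4. audit against a product spec and enumerate deficit hypotheses
   (`audit_collinearity()`, `find_trans_candidates()`,
   `enumerate_iterative_hypotheses()`);
5. summarise a genome's BGC landscape (`occupancy()`,
   `count_by_type()`).

The worked case shipped with the package is the sceliphrolactam (*sce*)
cluster of *Streptomyces* sp. SD85: a 26-membered polyene macrolactam
whose cluster encodes ten extension modules where eleven are required,
with the two iterative-module schemes (sceQ or sceR running twice with
the KR toggled between passes) recovered by the exhaustive search.

## Domain signatures

Scanning is anchored-regex based, not profile-HMM. Each domain class is
located by a conserved anchor motif (configurable in
`inst/extdata/signatures.yaml`) and a fixed-width window is drawn around
the anchor. This is deliberate: the package consumes either
annotation-validated real input (annotations are passed through and
validated when present) or its own synthetic fixtures, and a regex table
keeps every rule inspectable and swappable without code changes. The
anchor patterns wildcard the catalytic position itself, so a point
mutant of an active-site residue is still *located* and then reported
catalytically *inactive* — ablating one residue flips exactly one call
(a locality property the test suite checks).

Classification rules:

* **AT substrate.** The specificity window sits at a configurable
  offset downstream of the GHSxG active-site serine; `YASH` calls
  methylmalonyl-CoA (alpha-methyl branch), `HAFH` calls malonyl-CoA,
  anything else is `unknown`. The window convention is the canonical one
  from the AT-specificity literature; the exact residue set the original
  annotators inspected is not published, so the table is data, not code.
* **KR type.** The conserved `(L/V)D(D/N)` motif in the typing window
  calls a B-type KR, which predicts an R-configured beta-hydroxyl. The
  A-type call (S-configured product) uses a tryptophan criterion from
  the KR-typing literature; because only the B-type motif is stated for
  this system, the A rule is marked `extrapolated` in its evidence
  field. A KR failing the catalytic-tyrosine rule is `inactive` and
  contributes no stereochemistry.
* **Activity.** Per-class essential-residue rules (KS cysteine, AT
  serine, DH histidine of HxxxGxxxxP, KR tyrosine, ACP/TE serine of the
  phosphopantetheine/thioesterase motif). Active iff nothing is missing.

## Modules, order and docking

A module opens at each KS anchor and collects domains up to the next KS;
a leading ACP before the first KS of the first protein is the loading
module (index 0), which for beta-amino-acid starters is modelled as a
bare ACP loaded in trans — the starter-synthesis enzymology is
represented declaratively (a `starter_unit`), never simulated. Gene
order comes from genomic coordinates alone (reversed on the minus
strand); mixed strands require an explicit override rather than a guess.

Docking domains are detected with a sliding-window heptad-periodicity
score over the terminal regions outside the first/last domain hit: a
window of at least `docking$min_len` (25 aa) residues must reach
`docking$score_threshold` (0.8) on
min(hydrophobic fraction at heptad a/d positions, polar fraction
elsewhere), maximised over the seven register frames. This is a cheap
stand-in for structural prediction of the docking fold; annotations can
be passed through instead, and the pairing of dock classes is a config
table. The defaults were fixed once against the generator's designed
termini (score ≈ 1) and random filler (false-positive rate below a
percent at these lengths) and are not tuned per dataset.

## Backbone chemistry and the atom ledger

Extension unit $i$ derives from module $i$: alpha substituent CH3 iff
the AT is methylmalonyl; beta state ketone / hydroxyl / enoyl /
methylene for no KR / KR / KR+DH / KR+DH+ER active. Stereochemistry of
hydroxyls follows the KR type (B → R, A → S); enoyl geometry defaults to
E because no domain rule predicts cis bonds — a per-position geometry
override table carries experimentally established Z bonds (the
C14–C15 cis bond of sceliphrolactam is extension 5 in the shipped
spec).

The molecular formula is assembled from an explicit ledger, never from
a drawn structure: starter ring atoms and branches; two carbons per
extension with alpha hydrogens adjusted for methyl branches and enoyl
bonds; per-beta-state contributions (ketone +O, hydroxyl +O +2H, enoyl
+1H, methylene +2H); the amide carbonyl oxygen counted once at ring
closure; declarative tailoring deltas (hydroxylation +O with the carbon
hydrogen retained; amide deprotection removes the configured
protecting-group delta — the reactive starter amine is modelled as
protected during assembly, glycyl-like delta by default, and freed by a
tailoring event). Degrees of unsaturation are computed twice — from the
formula ($C - H/2 + N/2 + 1$) and by counting ring, carbonyls and
double bonds on the backbone graph — and must agree; the suite checks
the identity on randomly generated backbones.

Masses: monoisotopic element masses live in `inst/extdata/chem.yaml`.
Reported adduct m/z follows the standard "calcd" tabulation convention:
the neutral molecular mass and the neutral adduct atom mass are each
rounded half-even to 4 decimals and then summed, with electron mass
neglected. This is the convention under which the published calcd
values for sceliphrolactam (C28H35NO6, [M+H]+ 482.2542), filipin III
and factumycin are all reproduced exactly; summing at full precision
and rounding once would differ in the last digit for sceliphrolactam
(482.2543). Internal arithmetic is full precision
(`monoisotopic_mass()`); rounding happens only at the reporting
boundary.

## The audit and the hypothesis search

`audit_collinearity()` computes the deficit $D = E_{req} - M_{enc}$.
At $D = 0$ the predicted and target unit states are compared per
position; the default granularity compares alpha substituent and beta
state only, because stereochemistry and geometry are motif-assigned
rather than iteration logic (strict mode is available). The verdict
enum is `collinear` / `deficit` / `excess`, plus `mismatch` for equal
counts with positional disagreement — a case the three-way verdict
could not express honestly.

`find_trans_candidates()` scans genes outside the audited cluster for a
stand-alone module with exactly the required composition (default
KS-AT-ACP: the mystery extension leaves its beta-keto group unreduced)
and, by default, docking ends at both termini. Relaxing the docking
requirement can only grow the candidate set (a monotonicity the tests
assert).

`enumerate_iterative_hypotheses()` is an exhaustive two-pass search for
$D = 1$: every extension module $m$ and every ordered pair
$(S_1, S_2)$ of activity subsets of $m$'s reductive domains is
simulated as the $E_{req}$-extension backbone
$[1..m\,\text{with}\,S_1,\; m\,\text{with}\,S_2,\; m{+}1..]$ and kept
when it reproduces the target states. Two design rules encode the
biology: a pass may only switch **off** domains the protein physically
carries (programmed iteration toggles activity; it cannot conjure a
domain), and the DH is allowed to toggle along with the KR — whether it
may is not settled, so surviving hypotheses record exactly which
toggles they need. Hypotheses with identical resulting backbones for
the same module are collapsed. Deficits of 2 or more raise a clear
not-implemented error rather than guessing multi-iteration semantics.
The suite checks the enumeration against an independently written
brute-force oracle on randomly generated single-deficit fixtures
(exact set equality), and the sce case returns exactly the sceQ
(KR on, then off) and sceR (KR off, then on) schemes.

## BGC landscape statistics

`occupancy()` merges overlapping intervals before summing — "occupy"
means coverage, and merging is the only convention that cannot
double-count — with inclusive spans ($to - from + 1$), matching the
1-based inclusive coordinates used throughout. On the shipped 52-row
SD85 cluster table with the 8,625,724 bp genome length this yields
1,828,293 bp = 21.2%. Note the rounded megabase figure is 1.83; the
commonly quoted 1.82 Mb is a truncation of the same total.
`count_by_type()` matches case-insensitive substrings so hybrid
clusters count toward every group they mention; because the table
mixes product names ("Filipins", "Factumycin") with class labels, the
name-to-class knowledge lives in an editable mapping
(`inst/extdata/type_groups.yaml`), and counts that depend on that
mapping (e.g. a total PKS tally) are reported but not asserted.

The genome length is an explicit input, never inferred from intervals:
published genome lengths for this strain differ between sections
(8,625,724 vs 8,625,764 bp), and the package does not adjudicate;
the shipped examples use 8,625,724.

## The synthetic-data generator

Real PKS sequences cannot be bundled, so fixtures are built from fixed
160-residue domain scaffolds: neutral filler plus the anchor motifs and
signature windows at known offsets, docking heptads at protein
junctions, and a ground-truth record (architecture, anchor coordinates,
expected backbone units, dock classes) emitted alongside. The filler
alphabet omits every residue any rule requires (no C, D, G, H, N, S, W,
Y), so motifs cannot arise by chance — asserted at generation time by
counting anchor matches against the truth. All randomness flows through
the caller's seed via `withr::with_seed`; the global RNG state is
untouched and identical seeds reproduce byte-identical fixtures.

The shipped `sce_fixture()` encodes the sceliphrolactam architecture:
five proteins (sceN: loading + modules 1–2, sceO: 3–4, sceQ: 5, sceR:
6, sceS: 7–10 + TE), methylmalonyl windows in modules 3 and 8, B-type
KRs, a KR-less ketone module (2), a DH-less KR module in sceR, and four
compatible docking junctions. The per-protein module distribution is
drawn, not tabulated, in the published scheme, so this transcription is
figure-derived; it is consistent with the published protein lengths
(sceQ at 1824 aa ≈ one full reducing module, sceR at 1582 ≈ one,
sceS at 5150 ≈ four) and with the B-type KR of module 6 placing the
R-configured C-11 hydroxyl at extension 7 under either iterative
scheme. The per-extension target states in
`inst/extdata/sceliphrolactam.yaml` (eight enoyls, ketones at
extensions 2 and 6, hydroxyl at 7, methyls at 3 and 9) are the unique
assignment consistent with the published formula C28H35NO6 and its 12
degrees of unsaturation after the two P450 hydroxylations (C-10, C-12)
and amide deprotection; the end-to-end formula check in the suite
confirms it, but because it is figure-derived it is treated as a
qualitative check, not a reported target.

What the generator does *not* emulate: sequence divergence, HMM-grade
domain boundaries, trans-AT architectures, NRPS grammar, or real
docking folds. Passing tests therefore demonstrate the pipeline's
logic — grouping, ordering, arithmetic, enumeration, bookkeeping — on
clean signals, not detection performance on noisy natural sequences;
for real input the intended route is annotation passthrough.

## Worked example

```{r example}
fx <- sce_fixture()
line <- order_assembly_line(fx$genes)
line

spec <- sceliphrolactam_spec()
audit_collinearity(line, spec)

hyps <- enumerate_iterative_hypotheses(line, spec)
for (h in hyps) print(h)

bb <- macrolactamize(backbone_from_units(spec$starter, spec$target_units))
bb <- apply_tailoring(bb, spec$tailoring)
molecular_formula(bb)
monoisotopic_mz(molecular_formula(bb), "[M+H]+")
```

## Numerical and scale choices

* Coordinates are 1-based inclusive everywhere (GenBank convention);
  all spans are $to - from + 1$.
* Rounding: masses half-even at 4 decimals at the reporting boundary
  only; occupancy megabases to 2 decimals, percentages to 1.
* Ties in gene ordering are broken lexically by gene id, making every
  ordering total and reproducible.
* Test problem sizes: fixtures of 3–10 modules, enumeration oracles on
  4–8 extensions with 100 random single-deficit instances, coverage
  oracles on 30–50 kb toy genomes with up to 200 intervals. These sizes
  exercise every code path while keeping the default suite fast;
  nothing in the method scales worse than the two-pass enumeration,
  which is $O(M \cdot 4^{|red|})$ with $|red| \le 3$.

## Known limitations

* Motif scanning is not a homology search; distant natural sequences
  need external annotation (which the scanner validates and passes
  through).
* Only single-deficit iteration is searched; module skipping,
  stuttering and multi-pass iteration are out of scope.
* The stereochemical model is per-unit R/S plus per-bond E/Z; no
  global stereo model, no P450 regioselectivity prediction (tailoring
  sites are declared inputs), no isotope patterns.
* The starter model tracks ring atoms, methyl branches and amine
  protection; it does not simulate starter biosynthesis.
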