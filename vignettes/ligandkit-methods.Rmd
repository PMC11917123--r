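---
title: "ligandkit: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ligandkit: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

ligandkit is a desk-scale toolkit for the small-molecule side of
macromolecular structural biology: it reads chemical-component definitions
and assembly structures, repairs chemically impossible valence states,
computes descriptors and scaffolds, measures atom-level similarity between
ligands, reconstructs multi-component bound molecules from covalent
connectivity, types protein–ligand contacts geometrically, assigns
functional roles (cofactor-like, reactant-like, drug-like), aggregates
per-atom interaction statistics, and applies ligand-quality flagging rules.
This vignette explains each method, its assumptions, the tunable parameters,
and the design decisions taken where more than one reading was defensible.

## The molecule model

A molecule is an attributed graph: atoms carry an element symbol, a formal
charge, optional 2D and 3D coordinates and an optional source atom name;
bonds carry an integer order (1–3), an aromatic flag and a dative flag.
Hydrogens may be explicit, but every operation works on the heavy-atom graph
and completes hydrogens implicitly against a valence table (element, formal
charge) → allowed total bond orders. Aromatic bonds contribute 1.5 to an
atom's bond-order sum; dative (coordination) bonds contribute 0. The default
table covers H, B, C, N, O, P, S, Se, Si, As and the halogens; metals are
deliberately absent — in this model metals bind by coordination, not
valence, and are exempt from valence checks. The table ships as an ordinary
R list so a user can swap in house conventions wholesale.

Aromaticity is taken from explicit aromatic flags (as in dictionary files)
or written by fixtures on six-membered alternating rings. There is no
extended Hückel perception: a five-membered heteroaromatic drawn kekulized
stays kekulized, which keeps the implicit-hydrogen model simple and
predictable.

## Sanitization

Deposited component definitions sometimes encode impossible valences
(a neutral tetravalent nitrogen, an iron "covalently" bonded to four
porphyrin nitrogens). `sanitize()` repairs these iteratively, one action per
offending atom per sweep, until clean or `max_iter` (10) is reached:

1. **bond-retyped** — if the over-valent atom has a bond to a metal, that
   bond becomes dative and stops counting towards valence. This is applied
   first: where a metal is involved, the chemically correct reading of an
   over-valent centre is a coordination bond, not an exotic charge state.
   A haem-like fragment therefore sanitizes by retyping its Fe–N bonds
   while the pyrrole nitrogens keep charge 0.
2. **charge-set** — a formal charge under which the valence table allows
   the observed bond sum (tetravalent N → +1). Candidates are tried in
   order of increasing magnitude, positive before negative, which matches
   how such states are usually drawn.
3. **bond-order-lowered** — the atom's highest-order bond is demoted by
   one; ties break to the lowest partner atom index, for determinism.

The procedure is idempotent (sanitizing its own output is a no-op), never
increases any atom's valence, and raises a typed error carrying the full
action report when it cannot converge — silent partial repair would be
worse than failure.

## Descriptors

Molecular formula (Hill order) and molecular weight come from the graph
with implicit hydrogens. Canonical SMILES, InChI and InChIKey are generated
by OpenBabel's `obabel` executable from a V2000 molblock; when 3D
coordinates are present they flow into the molblock so stereocentres are
perceived and appear in the InChI stereo layers. Two graphs that differ
only by atom numbering yield the same canonical SMILES, which several
modules exploit as an identity test.

## Scaffolds and fragments

`murcko_scaffold()` implements the classic ring-and-linker framework by
iterative pruning of degree-1 heavy atoms: what survives is exactly the
union of rings plus the acyclic paths connecting them. Exocyclic
substituents — including carbonyl oxygens — are side chains under this
definition and are removed; the operation is idempotent and an acyclic
molecule has an empty scaffold. Scaffold equality elsewhere in the package
means equality of canonical SMILES of the two scaffolds, with the
convention that empty scaffolds never match (grouping all acyclic ligands
as "same scaffold" would be noise, not signal).

`brics_fragments()` cleaves acyclic single bonds whose environment matches
a configurable rule list in the retrosynthetic spirit of BRICS: amide
C(=O)–N, ester C(=O)–O, ether O–C(alkyl), and ring-to-chain junctions by
default. All matching bonds are cut simultaneously; cut ends receive `"*"`
attachment markers, and the heavy-atom multiset of the fragments (markers
aside) always equals the parent's. The rule list is data, not code — a
user can extend it without touching internals.

## PARITY similarity

The similarity score between two ligands is the Jaccard ratio over atoms of
a maximum common substructure:

$$ s(A,B) = \frac{|MCS|}{n_A + n_B - |MCS|} \in [0,1] $$

The MCS is found as a maximum clique on the modular product of the two
heavy-atom graphs: vertices are element-matching atom pairs, and two
vertices are compatible when their atom pairs agree on bond existence.
Agreement on *existence* (not order) is the default: archive depictions of
the same chemical species disagree routinely on tautomer and charge-state
drawing, and an order-sensitive match would punish that; a `strict_bonds`
mode is available when order fidelity matters. The common substructure may
be disconnected, which is what makes the score behave sensibly for
molecules sharing several separated moieties (adenine + phosphate chain).

The clique search is an owned branch-and-bound with a greedy-colouring
bound and a node-expansion budget (default $10^6$). Within budget the
result is exact; on exhaustion the best-so-far substructure is returned
with `timed_out = TRUE` rather than failing — a usable lower bound beats an
error in batch settings. Determinism comes from fixed vertex order and
first-found-maximum tie-breaking. The functional-role classifiers use a
smaller default budget ($5 \times 10^4$): their thresholds (0.6, 0.7) sit
far from the scores their negative cases produce, so a bounded search
changes no decisions while keeping entry-level annotation interactive.
An identical-graph shortcut (equal InChIKey connectivity blocks score 1.0
immediately) removes the most common and most expensive case, a ligand
compared against its own reference structure.

Stereoisomer detection is deliberately not similarity-based: two molecules
are stereoisomers when their InChI formula, connectivity and hydrogen
layers agree and their stereo layers differ.

Related-ligand grouping (`related_ligands()`) partitions a reference set
with priority stereoisomer > same scaffold > similar, using an inclusive
threshold of 0.6 for "similar" — a score of exactly 0.6 is in.

## Bound-molecule inference and CLC identifiers

Within an assembly, non-polymer, non-water component instances form the
nodes of a connectivity graph whose edges are *covalent* links only.
Connected components are the bound molecules. Metal-coordination links
never merge — a Mg coordinated by a ligand is not part of it (an override
exists for users who disagree). Waters are solvent and excluded entirely.
Instances covalently attached to a polymer chain are reported separately as
"polymer-attached" (modified-residue-like) rather than as free ligands.
bmIDs (`bm1`, `bm2`, …) follow the (chain, residue-number) order of each
component's first member, so numbering is reproducible across runs.

Each multi-component molecule's chemical graph is rebuilt by fusing the
instances' dictionary graphs at the link atoms, and its InChIKey keys a
registry that mints sequential `CLC_` + six-digit identifiers. Identifiers
are never reassigned; a curated reference (PRD) table, keyed by sorted
component multiset, takes precedence over automatic assignment. Registry
ordinals are local to a registry file: reproducing any particular archive's
numbering is explicitly out of scope.

## Contact typing

Contacts are evaluated geometrically in four categories — atom–atom,
atom–plane, plane–plane, plane–group — against an editable rule list.
The defaults follow the conventions of protein–ligand interaction
databases: vdW tolerance 0.1 Å, clash tolerance 0.6 Å, hydrogen bond
donor–acceptor ≤ 3.5 Å with D–H⋯A ≥ 120° when hydrogens exist, weak
(C–H) hydrogen bond ≤ 3.8 Å, ionic ≤ 4.0 Å, metal ≤ 3.0 Å, hydrophobic
(C/S) ≤ 4.5 Å, halogen ≤ 4.0 Å, ring-centroid pairs ≤ 6.0 Å with
face-to-face below 30° between normals, edge-to-edge above 60°, and
offset in between; cation–π ≤ 4.5 Å and donor–π ≤ 4.0 Å. These numbers
are conventions, not measurements — they live in one list, every test
pins that list explicitly, and changing them changes the output, not the
code.

Atom typing is derived from the dictionary graphs (donor = N/O with a
hydrogen to give, acceptor = uncharged N/O, anion/cation from formal
charges plus terminal P/S oxygens, hydrophobe = C/S with only C/H/S
neighbours); the twenty standard amino acids ship as built-in component
definitions so protein atoms type without external files. Ring planes are
5–7-membered dictionary rings whose observed coordinates fit a plane with
RMSD ≤ 0.1 Å (centroid = mean, normal = smallest principal axis); a
cyclohexane chair fails this test by construction. Planar groups for the
plane–group category are amides detected as C(=O)–N triples — backbone
cross-residue amides are not assembled across instance boundaries, a
simplification that trades a rare contact class for a much simpler
contract; guanidinium and carboxylate participation is already covered
through their charged atoms in the atom–plane and ionic rules.

A pair may carry several compatible subtypes (a hydrogen bond is usually
also a vdW contact); a clash excludes all bonding subtypes. Covalently
linked pairs are excluded. Candidate pairs come from a uniform spatial grid
with cell size equal to the global cutoff — exact, and linear in scene
size. Where structures lack hydrogens, hydrogen bonds fall back to
distance-only criteria, since most deposited structures cannot resolve
hydrogen positions; `add_polar_hydrogens()` provides a naive geometric
protonation (one H per unsatisfied donor, along the negated bond-vector
sum, O–H 0.96 Å / N–H 1.01 Å) for angle-aware runs. It is a stand-in with
known limits: no tautomer or rotamer optimization, no pKa reasoning.

## Functional roles

The cofactor path is a two-stage similarity gate against curated cofactor
classes (template molecule, representative molecule, per-class threshold,
EC number set): a ligand must meet the class threshold against both
template and representative, and the entry must carry an EC number matching
the class (prefix-aware, so `1.1.1.-` covers `1.1.1.42`). Passing the
similarity stages without the EC match flags the ligand for manual review
instead of annotating it. The reactant path compares the ligand to the
participants of reactions mapped to the binding protein and annotates at a
minimum similarity of 0.7; both 0.7 and the per-class cofactor thresholds
are read as inclusive ("minimum" means the value itself qualifies). The
drug path is set membership: the ligand (by InChIKey, falling back to
identifier) must map to a drug whose pharmacologically active target set
contains the protein accession. Roles are non-exclusive and recorded with
the evidence (class, reaction, scores) needed to recompute every positive
decision. The shipped reference tables are small curated JSON fixtures
(two cofactor classes); production use expects user-supplied tables — the
package never downloads anything.

## Aggregation and quality flags

Interaction frequencies are aggregated per ligand atom in two
normalizations: percent of the ligand's total interactions, and percent of
each amino-acid type's total interactions (each amino-acid column sums to
100). An optional subtype filter restricts contacts before counting.
Tables carry full precision; rounding is a display concern.

Quality flagging consumes externally computed metrics: geometric Z-scores
(outlier when |Z| > 2.0, two-sided — the convention names deviations
"above 2.0" without a sign, and deviations are symmetric), RMSZ =
sqrt(mean Z²) per category (ideally within [0, 1]), torsion flags when the
local density measure is below 5%, ring flags when the ring torsion RMSD
exceeds 60°, and density-fit flags when RSCC < 0.8 or RSR > 0.4. All
boundaries are strict: a value exactly at a threshold is not flagged.
Computing Z-scores against a small-molecule geometry library, or RSCC/RSR
from maps, is out of scope by design.

## Synthetic fixtures

The package is testable offline because its study inputs are generated, not
downloaded. `gen_molecule()` builds valence-correct molecules by
construction (random spanning tree, ring closures and bond-order raises
only within spare valence) over a C/N/O/S palette with rough 3D embedding;
`gen_assembly()` places such components in space with declared covalent and
metal links, surrounds one ligand with a toy pocket of real amino-acid
types, and — crucially — returns its own ground-truth partition computed by
an independent union-find, so bound-molecule inference can be tested
against the generator rather than against itself. Two hand-shaped synthetic
entries emulate well-known archive situations: a Chromomycin-like
two-chain entry (two six-component covalently linked ligands plus a
coordinated Mg) and an NAD-cofactor entry (twelve NAD copies and six diol
copies bound to a dehydrogenase-like protein).

What the generator does not emulate is worth stating: no experimental
noise or missing atoms, no alternate conformations, no realistic pocket
geometry (residue atoms are scattered near a centre, so contact tests
check rule arithmetic rather than binding-site realism), and no stereo
centres in random molecules. Passing tests therefore demonstrate
correctness of the algorithms under clean inputs, not robustness to every
archive pathology.

Test and acceptance runs use deliberately modest problem sizes — molecules
of 3–12 heavy atoms for oracle comparisons (where exhaustive enumeration is
feasible), assemblies of ≤ 200 atoms for contact oracles, 100 seeded
assemblies for the partition suite — chosen so the full suite completes in
about a minute while still exercising every rule and boundary.

## Numerical and degenerate-input choices

Distances and coordinates are Cartesian Å throughout; there is no
fractional-coordinate support (assemblies are consumed after expansion).
Ties in the depiction argmin go to the first candidate; the depiction
penalty is `w_cross · crossings + w_overlap · overlaps` with defaults 1.0 /
0.5 and an overlap threshold of 0.5 × median bond length — the criteria
are principled, the weights are conventions and configurable. Empty
molecules score 0 similarity against anything (not an error); an empty
library search returns an empty hit list; an empty contact table aggregates
to an empty frequency table rather than dividing by zero; an empty Z-score
category reports its RMSZ as absent. Residue numbers are opaque keys — no
insertion-code arithmetic. Parsing ignores every mmCIF category it does not
interpret, and is insensitive to row and column order within the tables it
does.

## Known limitations

The protonation stand-in, the fixed-weight depiction score and the
six-ring-only aromaticity model are the main simplifications, all noted
above. PARITY scores from a budget-exhausted search are lower bounds, and
the classifiers' smaller default budget assumes threshold margins like
those in the shipped reference tables; a user running borderline
comparisons should raise the budget. The mmCIF surface is a dialect, not
the grammar: component atom/bond tables, atom sites and links — nothing
else is interpreted.
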