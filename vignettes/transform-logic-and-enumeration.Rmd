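---
title: "Reaction transforms, match logic, and library enumeration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction transforms, match logic, and library enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Forward enumeration of virtual compound libraries starts from a *transform*:
a codified reaction type that couples an atom-mapped reaction pattern
(SMARTS/SMIRKS) with chemist-written constraints. Given files of purchasable
building blocks, the engine must (i) find blocks whose structure matches each
reactant slot's keying pattern, (ii) evaluate the slot's logic program on
every match to veto or re-rate the application, (iii) apply the mapped
reaction over the Cartesian product of survivors, and (iv) emit rated,
deduplicated product records. The value of the approach is that synthetic
feasibility is encoded *by chemists, per reaction*, in a small readable rule
language rather than in code.

rxnforge implements that pipeline end to end: the rule language (lexer,
parser, canonical serializer), its evaluator, the pattern engine with two
SMARTS extensions, the enumeration engine with staged accounting, dual
XML/JSON transform files, block-file I/O, SDF/CSV/InChIKey outputs, a CLI,
and a seeded synthetic block generator used by the test suite.

## The logic language

One statement has the shape

```
if <subject> <relation> <predicate> [offpath|onpath] then <action>
```

*Subjects* name chemical objects relative to the keying-pattern match:
`atom 1` (the block atom bound to map index 1), `alpha to atom 2` (all atoms
bonded to that atom), `bond between atom 2 and atom 3`, `molecule`, or a
loop variable. *Relations* follow the verb distinction: `is`/`are` takes
qualitative predicates (`aromatic`, `primary center`, element tests like
`carbon atom`, `the origin of amine1 group`), `has`/`have` takes quantitative
ones (`at least 1 positive charge`, `at most 2 chlorines`, bare counts such
as `one hydrogen` meaning *exactly*). `offpath` restricts the subject's
object set to atoms/bonds outside the match; `onpath` to those inside.
*Actions* are `kill`, `raise|lower rating
slightly|moderately|strongly|severely`, and `ghost <SMILES>` (designate a
balancing fragment). Statements chain with `and if` / `or if`; subjects and
predicates chain with plain `and` / `or`. Loops iterate object classes:

```
foreach carbon atom offpath defined as carbon_atom in molecule {
  if carbon_atom is aromatic then raise rating slightly
}
```

Keywords are case-insensitive, `//` comments run to end of line, and
newlines are ordinary whitespace, so single-line and multi-line spellings
parse identically.

### Semantics that the source description leaves open

These were genuine design choices; each is documented here and exercised by
tests:

* **Chain precedence.** `and if`/`or if` evaluate strictly left to right,
  left-associative, with short-circuiting — the flat IFTTT-style reading a
  non-programmer expects. There is no hidden precedence of `and if` over
  `or if`.
* **Multi-object subjects are existential.** `alpha to atom 2 is aromatic`
  is true if *any* neighbour qualifies. `atom 1 or atom 2 is X` is true if
  either mapped atom qualifies; `and` requires both.
* **`alpha to atom N` does not exclude onpath atoms** by default; append
  `offpath` to opt in.
* **Numeric rating.** Only four qualitative categories are prescribed, plus
  positive-scoring retention. The numeric table here: base 50, steps
  slightly = 5, moderately = 10, strongly = 20, severely = 35, final value
  clamped to [0, 100]. A single `severely` is survivable (50 − 35 = 15);
  two are not. A final value of exactly 0 counts as non-positive and is
  dropped. Any monotone table satisfies the stated behaviour; this one is
  frozen and documented rather than tunable.
* **Kill short-circuits** the rest of the program. Because the kill flag is
  monotone this is observationally equivalent to running on, and much
  cheaper.
* **Named sets** are the minimal "collected set" reading:
  `define set hets as heteroatoms offpath` collects objects for later loops
  (`foreach atom defined as h in hets { ... }`). The richer "sets and
  functions" language feature is shown nowhere with syntax and is
  deliberately **not implemented**; a parse error names the construct rather
  than guessing.
* **Implicit hydrogens** are not objects: they cannot be iterated (explicit
  error), are never offpath members, and `has N hydrogens` reads the atom's
  total hydrogen count.

## Patterns, extensions, and matching

Keying patterns are standard SMARTS plus two atom attributes:

* `z<n>` — the atom has exactly *n* heteroatom neighbours, read as directly
  bonded atoms that are neither carbon nor hydrogen (the established meaning
  of this extension). `[C;z2:1]` matches dimethoxymethane's central carbon,
  not propane's.
* `^e<n>` — *experimental*: the atom's valence-electron count
  (outer-shell electrons of the element minus formal charge) equals *n*.
  The attribute exists to reserve a file-format slot for electron-count
  constraints (one- and three-electron systems); it deliberately does not
  attempt radical-bond chemistry.

Extension tokens are stripped from the pattern before it reaches the host
toolkit (RDKit) and enforced as post-filters on candidate matches, so the
core pattern stays portable. Matches are **symmetry-deduplicated**: all
automorphic images covering the same atom set count once (benzene's ring
pattern yields one binding, not twelve); distinct atom sets count
separately (1,4-diiodobenzene has two aryl-iodide sites). Whether the
original engine counts automorphs once or many times is unstated upstream;
this choice prevents duplicate products and is a documented divergence
risk. Each binding carries the map-number table and the exact
onpath/offpath partition of atoms and bonds (onpath bonds are the bonds
whose two endpoints are both matched).

Aromaticity, valence and sanitization are the host toolkit's default
perception. Parity with CDK-based engines is explicitly not claimed; a
pattern can match under one aromaticity model and not another.

## Generation pipeline and accounting

Per slot: *screen* (pattern-only — this is the "compatible reactant" figure
of the two-stage accounting), then *logic* on every binding of every
compatible block. A block survives a slot if at least one binding is
unkilled with positive rating; the surviving binding with the highest
rating is used for generation (ties broken toward the lowest sorted matched
atom indices). Enumeration walks the Cartesian product in deterministic
file order (slot 1 slowest), aggregates per-slot ratings with the
**minimum rule** — a chain is as favourable as its worst constraint; the
alternative (summing deltas) was rejected as unbounded — applies the mapped
reaction in bounded-size batches, and deduplicates by the product's
standard InChIKey only (parents and ghosts excluded; first seen wins).
Killed and non-positive combinations are dropped unless kill filtering is
disabled, in which case they are emitted flagged. Ghost fragments
(transform templates plus any `ghost` actions) ride on records and are
written to SDF unless hidden. Parallel runs partition slot-1 blocks and
must reproduce the serial output exactly; this is tested.

Reaction application notes: unmapped reactant-side pattern atoms are
deleted by the mapped rewrite (the iodide's I, the boronic acid's B(OH)2,
the acid's OH); products failing valence sanitization are counted and
excluded, never fatal; multiple products from symmetric sites within one
combination are deduplicated by canonical SMILES before record emission.

## File formats

`.slice` is XML, `.jslice` is JSON; both carry identical content and
round-trip losslessly (logic is stored as text and re-parsed at load, so
files stay human-readable and syntax errors surface at load time with file
context). The element/key names are this package's own stable, documented
schema: the upstream formats' names are not published, so byte-level
compatibility with files produced elsewhere is not claimed and not
attempted. Block files are TSV `(id, smiles)` with tolerant header
detection; single-column SMILES files get sequential ids. The group
library is an editable TSV `(name, smarts, origin)` with a 0-based origin
atom position, seeded with primary/secondary/tertiary amines, carboxylic
and boronic acids, sulfonamide, azide, terminal alkyne, and one aryl
halide per halogen.

## What the synthetic generator emulates — and what it does not

`make_fixtures()` emulates the deposited building-block sets: TSV rows of
drug-like SMILES each guaranteed (by construction and by a group-library
check) to carry its class's functional group. Scaffold templates per class
are decorated with random short C/O substituents — never nitrogen,
halogens, boron or acidic groups — so a block carries exactly the
functional class of its template and screening counts are predictable.
Generation is seeded and byte-deterministic. It does **not** emulate real
vendor catalogues: no stereochemistry, no salts or charged species, no
multi-functional blocks, no molecular-weight or property distributions, and
only benzene/alkyl scaffold diversity. A green end-to-end test therefore
establishes the engine's bookkeeping (screen/logic/enumerate/dedupe
identities), not chemical coverage of commercial space; the upstream
headline counts over a 284k commercial set are out of scope by contract.

## Numerical and degenerate-input choices

Ratings are integers; clamping happens once on the final value, not per
delta. An empty logic program yields rating 50, no ghosts, no trace. An
empty block list or a slot with zero survivors yields a valid empty record
set with full accounting. Unparseable block rows are counted and reported,
never silently dropped; two identical runs produce byte-identical CSVs.
Transforms are validated before writing and after reading: mandatory
id/name/version, metric bounds [0, 100], compilable patterns, every
logic-referenced map index present in its slot's keying pattern, every
product-side map with a reactant-side counterpart; unknown group names are
warnings (the library is user-editable), everything else an error.

## Known limitations

* SMARTS beyond what the host toolkit accepts is rejected, and aromaticity
  parity with other engines is not guaranteed.
* The predicate vocabulary is a closed, documented table; the upstream
  vocabulary is only exemplified, so this table is a documented superset of
  the examples, not a fidelity claim.
* One worker process round trip per batched operation (~1 s startup) makes
  single-molecule calls expensive; all package paths batch, and a session
  cache absorbs repeated parses.
* Multi-step synthesis is achieved by piping outputs back in as blocks;
  there is no internal route planner, no docking, no property prediction.
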