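# rxnforge

Rule-based forward enumeration of virtual compound libraries from
chemist-written reaction transforms.

## Who this is for

Medicinal chemists and cheminformaticians who want to encode a reaction
type once — as an atom-mapped SMARTS/SMIRKS pattern plus a small, readable
IF–THEN rule program — and then enumerate rated, synthetically plausible
products from building-block files at scale, without writing code per
reaction.

## The model

A **transform** bundles: identity metadata (id, name, version, append-only
history), optional quality metrics on a 0–100 scale (yield, reliability,
reputation, selectivities, condition flexibility, thermodynamics), an
atom-mapped reaction `reactants >> product`, one **logic program** per
reactant slot, and **ghost** fragments (small formal by-products such as
water that balance the reaction).

Logic statements follow

```
if <subject> <relation> <predicate> [offpath|onpath] then <action>
```

evaluated per pattern match. Subjects reference the match by map number
(`atom 1`, `alpha to atom 2`, `bond between atom 2 and atom 3`,
`molecule`); `is` takes qualitative predicates (`aromatic`,
`carbon atom`, `the origin of amine1 group`), `has` takes quantitative
ones (`at least 1 positive charge`, `at most 2 chlorines`,
`one hydrogen` = exactly one); `offpath` restricts to atoms outside the
match. Actions: `kill`, `raise|lower rating
slightly|moderately|strongly|severely` (steps 5/10/20/35 from base 50,
clamped to [0, 100]), `ghost <SMILES>`. Statements chain with
`and if`/`or if` (strict left-to-right, short-circuiting); loops iterate
object classes:

```
foreach carbon atom offpath defined as carbon_atom in molecule {
  if carbon_atom is aromatic then raise rating slightly
}
```

Generation screens each slot's blocks by pattern (the "compatible"
count), runs the logic on every match (the "surviving" count), walks the
Cartesian product of survivors in deterministic file order, scores each
combination as the **minimum** of its slot ratings, drops killed and
non-positive combinations, applies the mapped reaction, and deduplicates
by product InChIKey. SMARTS is extended with `z<n>` (exactly n heteroatom
neighbours) and the experimental `^e<n>` (valence-electron count).

Molecule-level primitives (SMILES/SMARTS/SMIRKS, InChIKey, molblocks) are
delegated to RDKit through a batched `python` worker
(`inst/python/chembridge.py`); the language, evaluator, engine and all
file formats are implemented in R.

## Worked example

```r
library(rxnforge)

t <- read_transform(system.file("extdata", "suzuki_iodo.slice",
                                package = "rxnforge"))
t
#> <rf_transform> TF_SUZUKI_IODO 'Suzuki-Miyaura cross-coupling (iodo)' v1
#>   reaction: [c:1][I].[c:2][BX3]([OX2H])[OX2H]>>[c:1][c:2]
#>   slots: 2, logic blocks: 2, ghosts: 0

blocks1 <- make_fixtures(seed = 11, n_per_class = 5, classes = "aryl_iodide",
                         path = "iodides.tsv")
blocks2 <- make_fixtures(seed = 12, n_per_class = 5, classes = "boronic_acid",
                         path = "boronics.tsv")
readLines(blocks1, n = 3)
#> id    smiles
#> ARYL_IODIDE_0001  Ic1ccc(CCCC)cc1
#> ARYL_IODIDE_0002  Ic1ccc(CC(C))cc1

recs <- enumerate_products(t, list(read_blocks(blocks1), read_blocks(blocks2)))
recs
#> <rf_products> 25 record(s)
#>   compatible per slot: 5 x 5; surviving after logic: 5 x 5
#>   combinations reacted: 25; duplicates suppressed: 0; sanitize failures: 0
#>                             product_smiles                    inchikey
#> 1            CCCCc1ccc(-c2ccc(CCOC)cc2)cc1 WEPOJGZCKIAGMT-UHFFFAOYSA-N
#> 2  CCCCc1ccc(-c2cccc(CC(C)(C)C(C)CC)c2)cc1 IGIMRFYUJCICHE-UHFFFAOYSA-N
#> ...
#>               r1_id             r2_id rating killed ghosts
#> 1  ARYL_IODIDE_0001 BORONIC_ACID_0001     50  FALSE
```

Reading the numbers: all 5×5 block pairs pass the aryl-iodide /
arylboronic-acid keying patterns ("compatible"), none are killed by the
transform's logic (no off-path iodide, amine or boron in these fixtures,
so "surviving" equals "compatible"), every combination couples to a
unique biaryl, and the combination rating is min(50, 55) = 50 — the
boronic-acid slot's `raise rating slightly` cannot lift a product above
its worst slot. The acylsulfonamide stock transform
(`acylsulfonamide.slice`) additionally emits a water ghost per product
and demonstrates kill logic.

Write outputs, or use the CLI:

```r
write_outputs(recs, generation_options(), sdf = "out.sdf", csv = "out.csv",
              inchikeys = "keys.txt")
```

```sh
Rscript inst/cli/rxnforge --transform suzuki_iodo.slice \
  --blocks1 iodides.tsv --blocks2 boronics.tsv \
  --out-csv out.csv --max-products 1000 --emit-config run.cfg
```

The CLI prints per-slot compatible/surviving counts and products written,
supports `--hide-ghosts`, `--no-kill-low-rated`, `--no-dedupe`,
`--inchikey-only`, `--workers N`, `--trace log.jsonl` (per-statement
firing log), and `--config run.cfg` to reproduce a run exactly.

## File formats

* Transforms: `.slice` (XML) and `.jslice` (JSON) — identical content,
  lossless round-trip; logic stored as readable text, parsed at load.
* Blocks: TSV `(id, smiles)`, header optional; single-column SMILES files
  accepted (ids auto-assigned).
* Group library: TSV `(name, smarts, origin)` with a 0-based origin atom
  position (`inst/extdata/group_library.tsv`).
* Outputs: SDF V2000 with named data fields, RFC-4180 CSV, InChIKey list.

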