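"""Batched cheminformatics worker.

Reads a single JSON request object from stdin and writes a JSON response to
stdout.  All molecule-level primitives (SMILES parsing, SMARTS substructure
search, SMIRKS reaction application, InChIKey hashing, molblock rendering)
are delegated to RDKit; everything else -- the transform language, logic
evaluation, rating algebra, enumeration bookkeeping -- lives on the R side.

Atom and bond indices in all responses are 0-based (converted on the R side).
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, inchi

RDLogger.DisableLog("rdApp.*")

PT = Chem.GetPeriodicTable()


def mol_graph(mol):
    """Flatten an RDKit mol into plain lists for JSON transport."""
    ri = mol.GetRingInfo()
    atoms = []
    for a in mol.GetAtoms():
        atoms.append({
            "symbol": a.GetSymbol(),
            "aromatic": a.GetIsAromatic(),
            "charge": a.GetFormalCharge(),
            "n_h": a.GetTotalNumHs(),
            "degree": a.GetDegree(),
            "in_ring": a.IsInRing(),
            "ring_count": ri.NumAtomRings(a.GetIdx()),
            "outer_electrons": PT.GetNOuterElecs(a.GetAtomicNum()),
        })
    bonds = []
    for b in mol.GetBonds():
        order = {Chem.BondType.SINGLE: 1, Chem.BondType.DOUBLE: 2,
                 Chem.BondType.TRIPLE: 3}.get(b.GetBondType(), 1)
        bonds.append({
            "a1": b.GetBeginAtomIdx(),
            "a2": b.GetEndAtomIdx(),
            "order": order,
            "aromatic": b.GetIsAromatic(),
            "in_ring": b.IsInRing(),
        })
    return {"n_atoms": mol.GetNumAtoms(), "n_rings": ri.NumRings(),
            "atoms": atoms, "bonds": bonds,
            "rings": [list(r) for r in ri.AtomRings()],
            "canonical": Chem.MolToSmiles(mol)}


def op_parse(req):
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
        else:
            g = mol_graph(mol)
            g["ok"] = True
            out.append(g)
    return out


def op_match(req):
    """Match one SMARTS against many molecules.

    Returns, per molecule, the list of matches; each match is the list of
    molecule atom indices in pattern-atom order (uniquify=False: all
    automorphic images are reported, deduplication is an R-side concern).
    """
    patt = Chem.MolFromSmarts(req["smarts"])
    if patt is None:
        return {"ok": False, "error": "invalid SMARTS: " + req["smarts"]}
    uniquify = bool(req.get("uniquify", False))
    res = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            res.append(None)
        else:
            ms = mol.GetSubstructMatches(patt, uniquify=uniquify,
                                         maxMatches=100000)
            res.append([list(m) for m in ms])
    return {"ok": True, "matches": res}


def op_smarts_info(req):
    out = []
    for s in req["smarts"]:
        patt = Chem.MolFromSmarts(s)
        if patt is None:
            out.append({"ok": False, "error": "invalid SMARTS: " + s})
        else:
            out.append({"ok": True,
                        "n_atoms": patt.GetNumAtoms(),
                        "map_nums": [a.GetAtomMapNum()
                                     for a in patt.GetAtoms()]})
    return out


def op_react(req):
    """Apply one SMIRKS to a batch of reactant combinations.

    Each combo is a list of reactant SMILES (one per slot).  Products are
    sanitized; failures are reported per combo, never fatal.  Distinct
    products from symmetric match sites are deduplicated by canonical
    SMILES within a combo.
    """
    rxn = AllChem.ReactionFromSmarts(req["smirks"])
    if rxn is None:
        return {"ok": False, "error": "invalid SMIRKS"}
    want_key = bool(req.get("inchikey", False))
    cache = {}
    out = []
    for combo in req["combos"]:
        mols = []
        bad = False
        for smi in combo:
            if smi in cache:
                m = cache[smi]
            else:
                m = Chem.MolFromSmiles(smi)
                cache[smi] = m
            if m is None:
                bad = True
            mols.append(m)
        if bad:
            out.append({"ok": False, "error": "unparseable reactant"})
            continue
        try:
            prods = rxn.RunReactants(tuple(mols))
        except Exception as e:  # noqa: BLE001 - reported, not raised
            out.append({"ok": False, "error": str(e)})
            continue
        seen = {}
        n_fail = 0
        for tup in prods:
            for p in tup:
                try:
                    Chem.SanitizeMol(p)
                    csmi = Chem.MolToSmiles(p)
                except Exception:  # valence failures etc.
                    n_fail += 1
                    continue
                if csmi not in seen:
                    seen[csmi] = inchi.MolToInchiKey(p) if want_key else ""
        out.append({"ok": True,
                    "products": list(seen.keys()),
                    "inchikeys": list(seen.values()),
                    "n_sanitize_failures": n_fail})
    return out


def op_inchikey(req):
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        out.append(None if mol is None else inchi.MolToInchiKey(mol))
    return out


def op_molblock(req):
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append(None)
        else:
            AllChem.Compute2DCoords(mol)
            out.append(Chem.MolToMolBlock(mol))
    return out


def op_canon(req):
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        out.append(None if mol is None else Chem.MolToSmiles(mol))
    return out


OPS = {
    "parse": op_parse,
    "match": op_match,
    "smarts_info": op_smarts_info,
    "react": op_react,
    "inchikey": op_inchikey,
    "molblock": op_molblock,
    "canon": op_canon,
    "ping": lambda req: {"ok": True, "rdkit": Chem.rdBase.rdkitVersion},
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"ok": False, "error": "unknown op: %r" % op}, sys.stdout)
        return
    json.dump(OPS[op](req), sys.stdout)


if __name__ == "__main__":
    main()
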