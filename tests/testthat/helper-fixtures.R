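# Shared fixtures: a 50-molecule panel, stock transforms, and an
# independent raw-matching oracle that talks to the host toolkit directly
# (bypassing the package's bridge and post-processing).

PANEL_SMILES <- c(
  benzene = "c1ccccc1", toluene = "Cc1ccccc1", phenol = "Oc1ccccc1",
  aniline = "Nc1ccccc1", iodobenzene = "Ic1ccccc1",
  diiodobenzene = "Ic1ccc(I)cc1", chlorobenzene = "Clc1ccccc1",
  bromobenzene = "Brc1ccccc1", pyridine = "c1ccncc1", furan = "c1ccoc1",
  thiophene = "c1ccsc1", naphthalene = "c1ccc2ccccc2c1",
  cyclohexane = "C1CCCCC1", ethane = "CC", propane = "CCC",
  ethanol = "CCO", acetic_acid = "CC(=O)O", benzoic_acid = "OC(=O)c1ccccc1",
  ethyl_acetate = "CCOC(C)=O", acetone = "CC(C)=O",
  diethylamine = "CCNCC", triethylamine = "CCN(CC)CC",
  benzylamine = "NCc1ccccc1", methanesulfonamide = "CS(N)(=O)=O",
  benzenesulfonamide = "NS(=O)(=O)c1ccccc1",
  phenylboronic_acid = "OB(O)c1ccccc1", phenylacetylene = "C#Cc1ccccc1",
  propargyl_alcohol = "C#CCO", benzyl_azide = "[N-]=[N+]=NCc1ccccc1",
  nitrobenzene = "O=[N+]([O-])c1ccccc1",
  trifluoroacetic_acid = "OC(=O)C(F)(F)F", anisole = "COc1ccccc1",
  styrene = "C=Cc1ccccc1", dichloromethane = "ClCCl",
  chloroform = "ClC(Cl)Cl", dimethoxymethane = "COCOC",
  pyrrole = "c1cc[nH]c1", morpholine = "C1COCCN1", piperidine = "C1CCNCC1",
  tetrahydrofuran = "C1CCOC1", dioxane = "C1COCCO1",
  benzaldehyde = "O=Cc1ccccc1", acetophenone = "CC(=O)c1ccccc1",
  benzamide = "NC(=O)c1ccccc1", acetamide = "CC(N)=O",
  indole = "c1ccc2[nH]ccc2c1", quinoline = "c1ccc2ncccc2c1",
  isopropanol = "CC(C)O", tert_butylbenzene = "CC(C)(C)c1ccccc1",
  cyclopentanone = "O=C1CCCC1")

panel_mols <- function() rf_parse_smiles(PANEL_SMILES)

stock_transform <- function(which = c("suzuki", "acylsulfonamide"),
                            dialect = "slice") {
  which <- match.arg(which)
  f <- if (which == "suzuki") "suzuki_iodo" else "acylsulfonamide"
  read_transform(system.file("extdata", paste0(f, ".", dialect),
                             package = "rxnforge"))
}

# Suzuki pattern without any logic, for pure-combinatorics tests
toy_transform_nologic <- function() {
  rf_transform(id = "TOY", name = "toy biaryl coupling", version = "1",
               smirks = "[c:1][I].[c:2][BX3]([OX2H])[OX2H]>>[c:1][c:2]")
}

block_rec <- function(id, smiles) {
  list(id = id, smiles = smiles, mol = rf_parse_smiles(smiles)[[1]])
}

# ---- independent oracle: raw substructure search in the host toolkit -----
# A separate, minimal python path (not the package's worker script): returns
# the set of distinct matched-atom sets (1-based, sorted within a match).
oracle_script <- function() {
  path <- file.path(tempdir(), "oracle_match.py")
  if (!file.exists(path)) {
    writeLines(c(
      "import json, sys",
      "from rdkit import Chem, RDLogger",
      "RDLogger.DisableLog('rdApp.*')",
      "req = json.load(sys.stdin)",
      "patt = Chem.MolFromSmarts(req['smarts'])",
      "out = []",
      "for smi in req['smiles']:",
      "    mol = Chem.MolFromSmiles(smi)",
      "    ms = mol.GetSubstructMatches(patt, uniquify=True, maxMatches=100000)",
      "    out.append(sorted(set(tuple(sorted(a + 1 for a in m)) for m in ms)))",
      "json.dump(out, sys.stdout)"), path)
  }
  path
}

oracle_match_sets <- function(smarts, smiles) {
  js <- jsonlite::toJSON(list(smarts = smarts, smiles = as.list(smiles)),
                         auto_unbox = TRUE)
  out <- system2(rf_python(), shQuote(oracle_script()),
                 input = as.character(js), stdout = TRUE)
  res <- jsonlite::fromJSON(paste(out, collapse = ""),
                            simplifyVector = FALSE)
  lapply(res, function(per_mol)
    lapply(per_mol, function(m) as.integer(unlist(m))))
}

binding_atom_sets <- function(bindings)
  lapply(bindings, function(b) sort(b$onpath_atoms))

# canonicalize a list of integer vectors for set comparison
setify <- function(l) sort(vapply(l, function(v)
  paste(sort(v), collapse = ","), ""))
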