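# Program corpus shared by the grammar round-trip and acceptance suites.
# PAPER_STATEMENTS holds every worked statement of the language docs
# verbatim; EXTRA_PROGRAMS exercises the rest of the grammar.

PAPER_STATEMENTS <- c(
  "if atom 1 is the origin of amine1 group or if atom 1 is the origin of amine2 group then lower rating moderately",
  "if atom 1 is carbon atom and if atom 1 is aromatic then kill",
  "if atom 1 or atom 2 is the origin of amine1 group then kill",
  "if atom 1 is carbon atom and aromatic then kill",
  "if atom 1 or atom 2 is carbon atom and aromatic then kill",
  "foreach carbon atom offpath defined as carbon_atom in molecule { if carbon_atom is aromatic then raise rating slightly }",
  "if atom 1 is aromatic then kill",
  "if atom 1 has at least 1 carbon atom attached to it then kill",
  "if atom 1 has one hydrogen then kill")

EXTRA_PROGRAMS <- c(
  "",
  "if atom 1 has at least 1 positive charge then lower rating severely",
  "if atom 1 has at most 2 chlorines then raise rating slightly",
  "if molecule has at least 2 rings then lower rating slightly",
  "if molecule has exactly 0 heteroatoms then kill",
  "if atom 2 is not aromatic then lower rating strongly",
  "if atom 1 is primary center then raise rating moderately",
  "if atom 1 is secondary center or tertiary center then lower rating slightly",
  "if bond between atom 1 and atom 2 is in a ring then kill",
  "if bond between atom 1 and atom 2 is double bond then kill",
  "if atom 1 is charged then ghost O",
  "if atom 1 is the origin of carboxylic_acid group then ghost O",
  "if alpha to atom 1 is heteroatom then lower rating moderately",
  "if alpha to atom 2 is halogen offpath then lower rating slightly",
  "if atom 1 has two hydrogens and if atom 1 is aliphatic then raise rating slightly",
  "if molecule has at least 1 negative charge then kill",
  "if atom 1 is cyclic and aromatic then raise rating slightly",
  "foreach nitrogen atom offpath defined as n_at in molecule { if n_at is the origin of amine1 group then kill }",
  "foreach ring defined as r in rings { if r is aromatic then raise rating slightly }",
  "foreach heteroatom defined as h in molecule { if h is oxygen atom then lower rating slightly }",
  "foreach atom offpath defined as x in molecule { if x is halogen then lower rating slightly }",
  "foreach carbon atom defined as outer in molecule { foreach oxygen atom defined as inner in molecule { if inner is cyclic then kill } }",
  "define set hets as heteroatoms offpath\nforeach atom defined as h in hets { if h is nitrogen atom then lower rating slightly }",
  "if atom 1 is aromatic then kill\nif atom 2 is aromatic then raise rating slightly\nif molecule has at least 1 ring then lower rating slightly")

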