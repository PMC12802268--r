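{
  "id": "TF_SUZUKI_IODO",
  "name": "Suzuki-Miyaura cross-coupling (iodo)",
  "version": "1",
  "history": [
    {
      "timestamp": "2026-01-01T00:00:00",
      "note": "initial encoding"
    }
  ],
  "references": [
    "classic Pd-catalysed biaryl coupling"
  ],
  "comments": "",
  "conditions": "Pd(PPh3)4, K2CO3, dioxane/water, 80 C",
  "metrics": {
    "yield": 80,
    "reliability": 90
  },
  "pattern": {
    "smirks": "[c:1][I].[c:2][BX3]([OX2H])[OX2H]>>[c:1][c:2]",
    "reactants": [
      "[c:1][I]",
      "[c:2][BX3]([OX2H])[OX2H]"
    ],
    "product": "[c:1][c:2]"
  },
  "logic": [
    "foreach iodine atom offpath defined as extra_i in molecule {\n  if extra_i is iodine atom then kill\n}\nforeach nitrogen atom offpath defined as n_at in molecule {\n  if n_at is the origin of amine1 group or if n_at is the origin of amine2 group then kill\n}\nforeach chlorine atom offpath defined as cl_at in molecule {\n  if cl_at is chlorine atom then lower rating slightly\n}\nforeach bromine atom offpath defined as br_at in molecule {\n  if br_at is bromine atom then lower rating moderately\n}",
    "foreach boron atom offpath defined as b_at in molecule {\n  if b_at is boron atom then kill\n}\nif atom 2 is aromatic then raise rating slightly"
  ],
  "ghosts": []
}
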