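{
  "id": "TF_ACYLSULFONAMIDE",
  "name": "Acylsulfonamide from sulfonamide and carboxylic acid",
  "version": "1",
  "history": [],
  "references": [],
  "comments": "",
  "conditions": "EDC/DMAP, DCM, rt",
  "metrics": [],
  "pattern": {
    "smirks": "[SX4:1](=[OX1:2])(=[OX1:3])[NX3;H2:4].[CX3:5](=[OX1:6])[OX2H1]>>[S:1](=[O:2])(=[O:3])[N:4][C:5]=[O:6]",
    "reactants": [
      "[SX4:1](=[OX1:2])(=[OX1:3])[NX3;H2:4]",
      "[CX3:5](=[OX1:6])[OX2H1]"
    ],
    "product": "[S:1](=[O:2])(=[O:3])[N:4][C:5]=[O:6]"
  },
  "logic": [
    "foreach carbon atom offpath defined as c_at in molecule {\n  if c_at is the origin of carboxylic_acid group then kill\n}",
    "foreach nitrogen atom offpath defined as n_at in molecule {\n  if n_at is the origin of amine1 group then lower rating moderately\n}"
  ],
  "ghosts": [
    "O"
  ]
}
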