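<?xml version="1.0" encoding="UTF-8"?>
<transform id="TF_ACYLSULFONAMIDE" version="1">
  <description>
    <name>Acylsulfonamide from sulfonamide and carboxylic acid</name>
    <history/>
    <references/>
    <comments/>
  </description>
  <metrics/>
  <pattern>
    <smirks>[SX4:1](=[OX1:2])(=[OX1:3])[NX3;H2:4].[CX3:5](=[OX1:6])[OX2H1]&gt;&gt;[S:1](=[O:2])(=[O:3])[N:4][C:5]=[O:6]</smirks>
    <reactant index="1" smarts="[SX4:1](=[OX1:2])(=[OX1:3])[NX3;H2:4]"/>
    <reactant index="2" smarts="[CX3:5](=[OX1:6])[OX2H1]"/>
    <product smarts="[S:1](=[O:2])(=[O:3])[N:4][C:5]=[O:6]"/>
  </pattern>
  <conditions>EDC/DMAP, DCM, rt</conditions>
  <logic reactant="1">foreach carbon atom offpath defined as c_at in molecule {
  if c_at is the origin of carboxylic_acid group then kill
}</logic>
  <logic reactant="2">foreach nitrogen atom offpath defined as n_at in molecule {
  if n_at is the origin of amine1 group then lower rating moderately
}</logic>
  <ghosts>
    <ghost smiles="O"/>
  </ghosts>
</transform>
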