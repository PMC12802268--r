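<?xml version="1.0" encoding="UTF-8"?>
<transform id="TF_SUZUKI_IODO" version="1">
  <description>
    <name>Suzuki-Miyaura cross-coupling (iodo)</name>
    <history>
      <event timestamp="2026-01-01T00:00:00" note="initial encoding"/>
    </history>
    <references>
      <reference>classic Pd-catalysed biaryl coupling</reference>
    </references>
    <comments/>
  </description>
  <metrics>
    <metric name="yield" value="80"/>
    <metric name="reliability" value="90"/>
  </metrics>
  <pattern>
    <smirks>[c:1][I].[c:2][BX3]([OX2H])[OX2H]&gt;&gt;[c:1][c:2]</smirks>
    <reactant index="1" smarts="[c:1][I]"/>
    <reactant index="2" smarts="[c:2][BX3]([OX2H])[OX2H]"/>
    <product smarts="[c:1][c:2]"/>
  </pattern>
  <conditions>Pd(PPh3)4, K2CO3, dioxane/water, 80 C</conditions>
  <logic reactant="1">foreach iodine atom offpath defined as extra_i in molecule {
  if extra_i is iodine atom then kill
}
foreach nitrogen atom offpath defined as n_at in molecule {
  if n_at is the origin of amine1 group or if n_at is the origin of amine2 group then kill
}
foreach chlorine atom offpath defined as cl_at in molecule {
  if cl_at is chlorine atom then lower rating slightly
}
foreach bromine atom offpath defined as br_at in molecule {
  if br_at is bromine atom then lower rating moderately
}</logic>
  <logic reactant="2">foreach boron atom offpath defined as b_at in molecule {
  if b_at is boron atom then kill
}
if atom 2 is aromatic then raise rating slightly</logic>
  <ghosts/>
</transform>
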