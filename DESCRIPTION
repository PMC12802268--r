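Package: rxnforge
Title: Chemist-Written Reaction Transforms and Virtual Library Enumeration
Version: 0.1.0
Authors@R: person("rxnforge", "maintainers", role = c("aut", "cre"),
    email = "maintainers@rxnforge.invalid")
Description: A transform language and generation engine for rule-based
    virtual synthesis.  Transforms couple an atom-mapped reaction pattern
    (SMARTS/SMIRKS, with heteroatom-neighbour-count and electron-count
    extensions) with an IFTTT-style logic language evaluated per pattern
    match: conditions on atoms, bonds, rings and the whole molecule can
    kill a reaction application, adjust its favourability rating in four
    qualitative steps, or designate ghost fragments that formally balance
    the reaction.  The engine screens building-block files, enumerates the
    Cartesian product of surviving reactants, applies the mapped reaction
    through RDKit (driven via a batched python worker), and writes rated,
    InChIKey-deduplicated product libraries as SDF, CSV or key lists.
    Includes dual XML/JSON transform serialization, a command-line
    interface, and a seeded synthetic building-block generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    optparse,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: python (>= 3.8) with rdkit, resolvable as 'python' on
    the PATH or via options(rxnforge.python=).
Config/testthat/edition: 3
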