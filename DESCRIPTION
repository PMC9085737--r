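Package: epitomap
Title: Mimotope-Guided Conformational Epitope Mapping on Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates a phage-display-derived mimotope peptide on an antigen by
    end-gap-free (overlap) pairwise alignment and characterizes the implicated
    surface patch on the antigen's 3D structure: solvent-accessible surface
    area by sphere-point quadrature with buried/intermediate/exposed
    classification, inter-chain neighbor and hydrogen-bond detection, grouping
    of candidate epitope residues by exposure and contact, pairwise nonbonded
    interaction-energy decomposition over an interface selection, and
    contact-based binding-affinity (dG/Kd) prediction. Includes a synthetic
    structure and peptide generator with known ground truth for validation,
    and a single-call pipeline producing a machine-readable epitope report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
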