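Package: extremoprot
Title: Comparative Sequence and Structure Analysis of Extremostable Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for comparing extremostable (acidic, alkaline,
    halophilic, thermophilic, psychrophilic) proteins against their
    non-extremostable orthologs. Computes amino-acid composition profiles
    and binned occurrence distributions, sequence-level physicochemical
    descriptors (net charge, isoelectric point, hydrophobic and
    polar/nonpolar fractions), Needleman-Wunsch global alignment with
    affine gaps, Kabsch rigid-body superposition with iterative outlier
    rejection, backbone phi/psi/omega torsions with peptide-bond
    planarity classification, Ramachandran region assignment, and
    distance-based salt-bridge detection.  Includes a synthetic generator
    for group-biased sequences and torsion-controlled backbones so every
    stage runs without external downloads, plus group-level statistics
    (Student's t-tests, identity-versus-RMSD Pearson correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
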