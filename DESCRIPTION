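Package: quadlock
Title: Irregular G-Quadruplex Motifs, Intra-Locked Topology Analysis and
    Melting Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying DNA G-quadruplexes formed by irregular
    short G-tract sequences. Enumerates putative quadruplex sequence (PQS)
    query families in which a chosen number of G-tracts are relaxed to
    isolated guanines, scans sequences and genomes for exact matches, and
    emits BED intervals. Analyses multi-model atomic coordinates of
    G-quadruplexes: glycosidic torsion (chi) computation and syn/anti
    classification, Hoogsteen hydrogen-bond detection, G-tetrad assembly
    from directed 4-cycles, stacking order and tetrad polarity, loop
    taxonomy (propeller, edgewise, diagonal, bulge and V-shaped loops with
    same- or reverse-polarity subtypes), detection of intra-locked
    two-block architectures, and superposed pairwise ensemble RMSD.
    Generates NMR-style distance, dihedral, hydrogen-bond and planarity
    restraint tables from a declared topology, and extracts melting
    temperatures from two-state circular dichroism melting curves with
    linear folded/unfolded baselines. Includes generators for synthetic
    planted-motif FASTA benchmarks, idealized multi-layer G-quadruplex
    coordinate sets with known topology, and simulated van't Hoff melting
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
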