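Package: mitodyn
Title: Repeat-Mediated Recombination Dynamics and Translational Capacity
    of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the structural and functional consequences of
    large recombining repeats in plant mitochondrial genomes. Detects identical
    direct-repeat families and their shared flanking "extensions" on circular
    genomes, enumerates the alternative master-circle conformations and
    repeat-flanking pairs generated by inter-copy recombination, quantifies
    flanking-pair support from paired-end (subclone) reads, tests for
    recombinational equilibrium, and predicts virtual Southern blot restriction
    fragments. Also computes the codon decoding capacity of an organellar tRNA
    gene set under expanded wobble rules, evaluates the free energy of a fixed
    RNA secondary structure with a reduced nearest-neighbor model together with
    a permutation test for structure conservation, and detects gene-conversion
    tracts between diverged homologs with a maximal-segment statistic and
    permutation p-values. A seeded synthetic-data module generates every input
    with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
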