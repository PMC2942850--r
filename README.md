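# mitodyn

Structural and functional dynamics of repeat-rich plant mitochondrial
genomes, in R.

Angiosperm mitochondrial genomes are conventionally drawn as a single
"master circle", but when a genome carries a family of large identical
repeats in direct orientation, homologous recombination among the copies
continuously reshuffles the single-copy regions between them.  With `n`
identical copies there are `n²` possible ordered (left flank, right flank)
junctions and `(n − 1)!` distinct master-circle conformations (counted up to
rotation, not reflection — direct repeats fix segment orientation); when all
junctions occur at similar stoichiometry the genome is at *recombinational
equilibrium*.  `mitodyn` provides the computational toolkit for studying
this regime, together with the downstream analyses such a genome invites:

* **Synthetic data with ground truth** — seeded generators for circular
  genomes with a planted n-copy identical direct repeat, per-copy flanking
  "extensions" shared by subsets of copies, planted restriction sites,
  equilibrium mixtures of junction molecules, Sanger-style paired-end
  subclone reads, tRNA gene sets, structured RNA sequences and mutants, and
  three-sequence alignments with a planted gene-conversion tract.
* **Repeat structure** — native detection of maximal exact repeat families
  on circular sequences and computation of the pairwise shared-flank
  ("extension") matrices.
* **Recombination dynamics** — conformation and flanking-pair
  combinatorics; classification of read pairs into junction support counts;
  a chi-square test (plus Shannon evenness) for recombinational
  equilibrium; in-silico restriction digestion and virtual Southern band
  prediction.
* **tRNA decoding capacity** — closure of a tRNA gene set under expanded
  wobble rules (G34 reads C/U, U34 superwobble in family boxes,
  lysidine-modified C34 reads A as isoleucine, initiator reads AUG only),
  with a bundled gene set for the *Silene latifolia* mitochondrial
  complement.
* **RNA structure conservation** — a reduced nearest-neighbor free-energy
  evaluator for *fixed* secondary structures, substitution classification
  (loop / conservative / compensatory / disruptive), and a permutation test
  asking whether an observed diverged sequence preserves a conserved fold
  better than sequences with the same number of random substitutions.
* **Gene conversion** — condensation of an alignment to polymorphic sites,
  Ruzzo–Tompa maximal-segment detection of high-identity fragments
  (match +1, mismatch −g), and order-permutation p-values.

## Worked example

```r
library(mitodyn)

# a circular genome with a 1362 bp repeat in 6 identical direct copies
gt <- make_genome(genome_spec(seed = 7))
gt$genome
#> <circular_genome> synthetic_circular_genome: 40572 bp (circular)

fam <- compute_extensions(gt$genome,
                          find_repeat_families(gt$genome, min_length = 50)[[1]])
fam
#> <repeat_family> 6 identical copies of 1362 bp (direct)
#>   extensions computed: left max 250, right max 300

count_master_circles(6)           # distinct master-circle conformations
#> [1] 120
nrow(enumerate_flanking_pairs(6)) # possible junctions
#> [1] 36

# equilibrium pool -> subclone reads -> junction support at 7x coverage
pool <- make_equilibrium_molecules(gt$genome, gt$truth)
reads <- make_read_pairs(pool, coverage = 7, seed = 7)
sup <- support_from_read_pairs(reads, gt$genome, family_from_truth(gt$truth))
sup
#> <pair_support> 54 supporting pairs over 36 flanking pairs (16 with >= 2);
#>   0 uninformative, 0 skipped, 0 conflicting

# virtual Southern: one probe, six bands
u <- gt$truth$unique_intervals
virtual_southern(pool, c(u$end[6] - 505, u$end[6] - 5))
#> <virtual_blot> 6 hybridising molecule(s), 6 distinct band(s):
#>   6679, 6696, 6712, 6729, 6745, 6762

# decoding capacity of the bundled mitochondrial tRNA set
cap <- capacity_summary(build_decoding_table(make_trna_set()))
cap$codons_decoded; cap$amino_acids_covered
#> [1] 17
#> [1] 9
```

At 7× coverage only a minority of the 36 junctions reach the ≥ 2-subclone
evidentiary bar (the classic under-sampling signature), while 50× coverage
supports all 36; the six distinct virtual-Southern band sizes are the
fingerprint of an equilibrium mixture of all six recombination products
seen by one probe.  `run_pipeline()` ties all stages into one seeded,
config-driven run with a JSON report; see the methods vignette
(`vignettes/mitodyn-methods.Rmd`) for the models, parameter choices and
their rationale.

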