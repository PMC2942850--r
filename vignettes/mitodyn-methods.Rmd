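---
title: "Models and methods behind mitodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodyn)
```

This vignette explains the models implemented in `mitodyn`, the assumptions
they make, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## 1. Repeat-mediated genome conformations

### The model

A circular genome carries `n` identical copies of a "core" repeat in direct
orientation, separated by `n` distinct single-copy regions.  Homologous
recombination between any two copies exchanges the flanking arrangement, so
any of the `n` "left" flanks can come to sit across a core copy from any of
the `n` "right" flanks: `n²` ordered flanking pairs.  A master circle — one
circular molecule containing every single-copy region once — corresponds to
a cyclic order of the `n` single-copy segments.  Because the repeats are
direct, every segment keeps a fixed orientation, so conformations are
counted up to rotation but **not** reflection: `(n − 1)!` distinct master
circles (`120` at `n = 6`), and `sum over k of choose(n, k) * (k − 1)!`
subgenomic circles carrying `k < n` repeat loci (295 for `n = 6`,
`k <= 5`).  `count_master_circles()`, `enumerate_master_circles()`,
`enumerate_flanking_pairs()` and `count_subgenomic_circles()` implement
these; enumeration is capped at `n = 8` since the list grows factorially.

Flanking sequence identical across *all* copies belongs to the core by
maximality; sequence shared by only a subset of copies forms per-copy
"extensions".  `compute_extensions()` quantifies these as the matrix of
longest shared flank prefixes/suffixes over copy pairs; the matrices obey
the nested-subset property (the extension shared by a superset of copies is
never longer than that of a subset).

### Repeat detection

`find_repeat_families()` finds maximal exact repeat families natively: the
circular sequence is doubled, every window of the minimum reportable length
is hashed, duplicated windows are grouped by their occurrence pattern, runs
of diagonal-consistent windows become maximal blocks, and blocks explained
by a larger family's accumulated territory (extension shells around the
core) are absorbed so that one biological repeat family is reported once.
Detection is exact-match only — the repeats of interest are identical, and
homogenised by the very recombination under study.  A mononucleotide
Shannon entropy floor (default 1.0 bits over the core) suppresses
low-complexity degenerate "families" such as homopolymer runs; hits are
deduplicated modulo genome length and never exceed it.

### Junction support from read pairs

`support_from_read_pairs()` emulates the subclone-conflict logic of shotgun
assembly: a read pair supports flanking pair `(i, j)` when the forward read
anchors uniquely in left flank `i`, the reverse read uniquely in right
flank `j`, and the implied span — forward read start, through one core copy
plus applicable extensions, to the reverse read end — is a plausible insert.
Reads are located by exact full-length matching (seeded by a 32-mer index
of the doubled genome); reads wholly inside the core or a shared extension
are multi-mapping and their pairs are skipped.  A same-region placement
counts as "consistent/uninformative" only when its direct span is itself a
plausible insert; an impossibly short direct span forces the junction
interpretation (this matters for the junction joining the two flanks of a
single gap).  The evidentiary bar follows the multiple-subclone convention:
a flanking pair is *supported* at `min_support = 2` independent pairs.

`equilibrium_test()` formalises the band-intensity argument for
recombinational equilibrium as a chi-square goodness-of-fit of the `n²`
support counts against uniformity (`df = n² − 1`), plus a normalised
Shannon evenness index.  The uniformity null assumes equal detection
probability across junctions; with strongly unequal extension lengths the
informative window differs between junctions, so on read-derived counts the
test is a test of *uniform detection*, not of equilibrium alone — for a
pure calibration check, feed it multinomial counts.

### Virtual Southern blots

`virtual_southern()` digests every junction molecule of an equilibrium pool
at each exact occurrence of the recognition site (cut point at the site
start) and records the fragment containing the probe.  With one distinctly
placed site per single-copy region, a probe in one flank of a 6-copy repeat
hybridises to exactly 6 distinct fragment sizes — one per recombination
product; molecules differing only beyond their nearest cut sites collapse
into one band.  Probes overlapping the core, a shared extension, or a cut
site are rejected.  Junction molecules are treated as linear spans long
enough to contain the nearest cut on both sides of the probe; a molecule
that is not gets an explicit error rather than a silent truncated band.

## 2. The synthetic genome generator

`genome_spec()`/`make_genome()` realise the study conditions: 6 identical
direct copies of a 1362 nt core.  Free parameters were fixed once, as
follows, and are stated here because they are *choices*, not measurements:

* **Single-copy regions: 5400 nt each** (genome 40,572 nt).  Real
  single-copy regions are tens of kilobases; the scaled size keeps
  whole-pipeline simulations fast while preserving the sampling regime of
  interest (see coverage below).
* **Extensions: 0–450 nt per copy and side**, nested-prefix structure, one
  zero-length copy per side (an extension shared by all copies would be
  core).  The published range for such extensions reaches ~1.6 kb; the
  scaled values keep every junction detectable at high coverage under the
  scaled single-copy length, since a junction's informative window shrinks
  by the sum of its two extension lengths.
* **Reads: Sanger-like, 700 nt, error-free, inserts uniform 4000–6500 nt**
  (the classic subclone size selection).  An optional uniform substitution
  error rate exists as a knob; the analyses here depend on pairing
  geometry, not base quality.
* **Coverage is genome coverage**: `make_read_pairs()` draws
  `coverage × genome_length / mean_insert` pairs.  At 7× this reproduces
  the under-sampling regime in which a minority-to-majority of the 36
  junctions reach 2-subclone support (each junction expects only a few
  informative clones); at 50× all 36 saturate.  The expected number of
  informative pairs per junction is approximately
  `coverage/mean_insert × (mean_insert − core − 2·ext) × L/(36·(L_mol − mean_insert))`,
  which guided the scaling.
* **Junction molecules: span `min(gap − 100, 2750)` nt per side** — just
  longer than the largest insert, so nearly every placement on a molecule
  straddles its junction, as a junction-containing subclone does.
* **Guard bases** make ground truth exact: the base immediately beyond each
  planted extension is forced to differ from the master-extension
  continuation (and pairwise between copies with equal extension lengths),
  so the emitted genome's shared-flank lengths equal the planted
  `min(len_i, len_j)` exactly rather than "min plus chance matches".
* **Screening**: the generator removes chance occurrences of the enzyme
  site and any unplanned exact repeat of ≥ 50 nt (configurable floor) by
  point substitutions in unique sequence (or consistently in the
  core/master extensions), so detection tests have a clean truth.
* **Enzyme sites: EcoRI (GAATTC)**, one per single-copy region at distinct
  offsets inside the window where a site serves both flank roles of a
  default-span molecule.

What the generator does **not** emulate: real base composition or gene
content; indels; chimeric, branched or linear molecule physics;
substoichiometric conformations.  Passing tests therefore show that the
*algorithms* recover planted structure and that the statistics are
calibrated under the stated model — not that real blots or real assemblies
behave this cleanly.

All generators are pure functions of `(spec, seed)`; `run_pipeline()`
splits one global seed deterministically per stage (multiplicative
congruential step), so independent implementations can match the structure
of the streams though not the byte streams themselves.

## 3. tRNA decoding capacity

`build_decoding_table()` closes a gene set under expanded wobble rules
keyed on anticodon position 34: G34 reads C (Watson–Crick) and U (GU
wobble); unmodified C34 reads G; lysidine-modified C34 reads A only and
switches identity to isoleucine; U34 reads A and G, extended to all four
third-position bases ("superwobble") when the codon box is four-fold
degenerate; A34 reads U.  A gene decodes only codons whose translation
matches its amino-acid identity, the initiator tRNA decodes AUG only, and
stop codons are never decoded.  The rule set is the realisation that
reproduces the published decoding grid for the *Silene latifolia*
mitochondrial tRNA complement (shipped as
`inst/extdata/silene_latifolia_table1.tsv`: 11 genes, 5 of chloroplast
origin, 2 potential pseudogenes): 17 of 61 sense codons, 9 of 20 amino
acids, pseudogenes included.  The genetic code defaults to the standard
code (used by plant mitochondria) and is pluggable.

## 4. Fixed-structure RNA energetics and the conservation test

`evaluate_energy()` scores a sequence on a *given* secondary structure by
the unique loop decomposition of a pseudoknot-free fold: stacking terms
over adjacent base pairs, size-dependent hairpin/bulge/internal penalties
(log-extrapolated beyond the tabulated sizes with coefficient
`1.0785 kcal/mol`), affine multiloop terms (`3.4 + 0.4·branches`), exterior
loop zero.  This is deliberately a *reduced* nearest-neighbor model:

* loop penalties depend on loop **size only** — no sequence-dependent
  mismatches, dangles, or terminal-AU penalties;
* stacking energies are **averaged over pair orientation**, so the energy
  depends only on each pair's composition class (A:U, C:G, G:U).  A
  compensatory substitution pair that flips a pairing's orientation (C:G to
  G:C) therefore leaves the free energy *exactly* unchanged — the model
  treats fully compensated change as energetically neutral, which is the
  property the conservation test needs from its comparator.  Absolute
  values from full parameter sets (e.g. RNAeval's) are *not* reproduced and
  are not a goal; the test below only ever compares sequences under one
  consistent model.

Parameters ship as an editable TSV (`inst/extdata/nn_energy_params.tsv`),
values at 37 °C in kcal/mol derived from the published nearest-neighbor
tables by orbit-averaging.

`classify_substitutions()` assigns each difference from a reference to
loop / helix-conservative (partner unchanged, pair still valid, e.g.
A:U → G:U) / helix-compensatory (both partners substituted, valid pair) /
helix-disruptive.

`conservation_test()` implements the structure-conservation permutation
test: with `k` = Hamming distance between reference and observed sequence,
draw `N` mutants by placing exactly `k` substitutions uniformly at distinct
positions with uniform base choice (the most literal null; transition bias
and with-replacement variants are out of scope), score everything on the
fixed reference structure in lenient mode (a disrupted pair loses its
stacking terms, default penalty 0), and report the add-one empirical
p-value `(1 + #{null dG <= observed dG})/(N + 1)` — never exactly zero; with
10,000 replicates, zero exceedances prints as p < 1e-4.  Mutants are *not*
refolded: the question is conservation of one conserved structure, not
ensemble thermodynamics.  `example_5s_structure()` provides a synthetic
118-nt five-helix layout (35 pairs) mimicking the architecture of plant 5S
rRNA without copying any real sequence; it is labelled synthetic and used
as the default simulation substrate.

## 5. Gene-conversion fragments

`condense_alignment()` reduces an alignment to the sites that carry
information for a designated pair: columns polymorphic somewhere in the
alignment, without gaps in either pair member; each site is a pair
match or mismatch.  (How sites monomorphic in the pair but polymorphic in
the alignment are treated varies between published implementations; this
condensation includes them as match sites, which is what makes a conversion
tract visible at all.)  `max_scoring_fragments()` scores +1 per match and
−g per mismatch (g = 1 by default, the classic mismatch cost) and returns
**all** maximal scoring segments via the Ruzzo–Tompa algorithm — segments
that cannot be improved by extension or trimming, reported
highest-scoring-first with zero-sum flanks trimmed (canonical form: the
shortest leftmost-in-score-ties interval).  `conversion_pvalue()` permutes
the *order* of the match/mismatch states (composition held fixed) and
compares each fragment's score to the null distribution of the permutation
maximum — distribution-free, and matching the significance style of the
classic fragment statistic.  Power rises with tract length and with
recipient–donor background divergence; a 50-column tract at 30% background
divergence with a close outgroup (the scenario of a chloroplast-to-
mitochondrion rRNA conversion) is detected at p ≤ 1e-3 essentially always.

`make_conversion_alignment()` plants the scenario: ancestor A, donor
diverged at `donor_divergence`, outgroup diverged at `outgroup_divergence`
(default 0.02 — organelle rRNA evolves slowly), recipient equal to A except
inside the tract, which is copied from the donor (a clean conversion).

## 6. Problem sizes and test design

The shipped tests run the full machinery at reduced scale, chosen as the
package's own trade-off between statistical resolution and a suite that
runs in well under an hour on one core: 100-seed batches for planted-repeat
recovery and junction-support saturation; 200 seeds for null-uniformity
checks (Kolmogorov–Smirnov); permutation tests at N = 999 in power checks
and N = 199 in calibration sweeps, with the single headline planted-tract
check at N = 9,999; exhaustive oracles (all-substring fragment scans,
recursive energy decomposition, brute-force cyclic enumeration) are applied
on inputs up to a few hundred sites where they are exact.  Every stochastic
assertion states its seed; thresholds (e.g. "p ≤ 0.01 in ≥ 95% of seeds")
are properties of the stated study conditions, not tuned quantities.

## 7. Known limitations

* Exact-match repeat detection only; diverged or inverted repeats are out
  of scope (the recombination model itself assumes direct orientation).
* Read location assumes error-free reads and forward-strand uniqueness; the
  generator never plants inverted repeats, so reverse-strand multi-mapping
  is not scanned for.
* The equilibrium chi-square inherits the equal-detectability assumption
  discussed above.
* The energy model is a comparator, not a thermodynamic predictor; no MFE
  folding, pseudoknots, or suboptimal ensembles.
* The conversion statistic is single-pair (recipient vs donor); genome-wide
  multi-pair scans with global multiplicity correction are not implemented.
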