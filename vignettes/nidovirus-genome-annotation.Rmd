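---
title: "Methods: nidovirus-like genome annotation and the genome-size association test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nidovirus-like genome annotation and the genome-size association test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nidoscan)
```

# Scope and coordinate conventions

`nidoscan` annotates a single positive-strand RNA virus genome of the
nidovirus architectural type and tests the association between a binary
lineage trait and genome size. All public coordinates are 1-based and
inclusive (the GenBank convention), so coordinates printed in the
comparative-genomics literature can be used verbatim. Internally the
sequence is held on the DNA alphabet; `U` is mapped losslessly to `T`
on input and the source alphabet is recorded, so repeats and heptamer
motifs are compared on a single alphabet regardless of how they were
written. `N` is permitted but never matches in any repeat, pairing or
heptamer comparison, and other IUPAC ambiguity codes are collapsed to
`N` — the conservative choice for motif discovery. Standard file
formats go through established libraries: FASTA via Biostrings, GFF3
via rtracklayer/GenomicRanges.

# ORF annotation

Two ORF definitions are first-class because nidovirus genomes use both
expression modes:

* **aug**: from the 5'-most AUG of a stop-bounded open stretch to the
  last base of the terminating stop codon;
* **open**: the whole stop-to-stop open stretch (start = first in-frame
  position after the upstream stop). This is the natural coordinate
  system for ORF1b-style regions, which have no initiator AUG and are
  expressed by a -1 ribosomal frameshift from within ORF1a.

Stretches truncated by the sequence end are excluded by default (they
have no defined stop) and can be included with a flag. Stop codons are
the standard set {TAA, TAG, TGA}; alternative genetic codes are out of
scope. The default reporting floor is 300 nt for "major ORF" tables
with a hard floor of 90 nt — the floor is a reporting choice, not a
biological claim, and is exposed as `min_orf_nt`.

The relative frame of two overlapping ORFs is derived from
`(start_b - start_a) mod 3`, mapped as 0 → 0, 1 → +1, 2 → -1, so an
ORF1a/ORF1b pair decoded by -1 frameshifting reports frame -1. UTRs
are delineated from the outermost ORF boundaries; a degenerate UTR is
returned as a zero-length marker (`end = start - 1`) rather than being
dropped.

Protein-level reports cover the statistics commonly quoted for virion
proteins: residue composition (percentages), cysteine counts, candidate
N-glycosylation sequons and hydrophobic stretches. The sequon is
N-X-S/T with X ≠ P by default: proline at X blocks glycosylation
biochemically, but published counts do not always apply the
restriction, so it is a toggle (`sequon_excludes_proline`). Because
"basic residues" is sometimes quoted with and sometimes without
histidine, both K+R and K+R+H percentages are reported rather than
guessing a convention. Hydrophobic stretches are maximal runs of
sliding-window Kyte–Doolittle means above a threshold (window 19 aa,
threshold 1.6 by default — typical transmembrane-screen settings); this
is a deliberately simple indicator of membrane-spanning segments, not a
re-implementation of any specific transmembrane predictor, and no
claim is made about reproducing such scores.

# TRS discovery

The TRS-candidate procedure follows the constrained-repeat logic used
for nidovirus genomes:

1. **Perfect repeat library** (`find_perfect_repeats`): all maximal
   exact direct repeats with unit sizes 4–16 nt and at least two
   occurrences. The enumerator is native (hashing equal-length windows
   and checking flank extendability) rather than wrapping an external
   repeat-detection tool, since the library is only the input to the
   positional filters. A unit is *maximal* when its occurrence set can
   be extended identically neither left nor right; units already at
   the 16-nt cap are kept regardless. Tandem runs (e.g. poly-A) are
   canonicalized to the greedy 5'-most non-overlapping occurrence set,
   which makes degenerate input deterministic; a unit left with fewer
   than two occurrences after canonicalization is dropped (so a 6-nt
   homopolymer yields no unit-4 repeat, but an 8-nt run does).
2. **Positional filter** (`filter_positional`): a candidate TRS repeat
   must have one occurrence entirely 5' of the ORF1a start (the leader
   region) and one entirely inside the 300-nt window immediately
   upstream of a downstream ORF start (the body region).
3. **Near-perfect pairing** (`pair_near_perfect`): leader/body TRS
   pairs are near-perfect and length-preserving, so pairing is
   *ungapped*: every leader window is compared to every equally long
   body window (lengths 10 to `max_unit + 8` by default), and windows
   with mismatch fraction ≤ 0.15 are candidates. Scoring is
   `identities - mismatches`; on each alignment diagonal overlapping
   candidates are reduced to the dominant one (highest score, ties to
   the longer window, then the 5'-most body start), so a pair is
   reported once at its full extent instead of as a cloud of shifted
   sub-windows. With mismatch tolerance 0 the operation reduces to
   exact repeat matching.
4. **Flanked conservation alignment** (`align_flanked`): each pair plus
   20-nt flanks is globally aligned (Needleman–Wunsch/Gotoh). Gaps
   enter only here. The scoring scheme — match +1, mismatch -1, a gap
   of length g costing 2 + (g - 1) — is a package choice; published
   TRS identity figures name no scheme. Since identity percentages may
   or may not count gap columns, both conventions are reported.
5. **sg mRNA prediction** (`predict_sg_mrnas`): sg mRNAs are
   3'-coterminal, so the body segment is `genome_length - junction + 1`
   with the junction at the downstream ORF start by default (the
   body-TRS start is an option); a leader-included length adds the
   leader contribution. Lengths are also reported rounded to 0.1 kb,
   the resolution at which blot-estimated mRNA sizes are quoted.

Multiple leader candidates are allowed and reported independently
(two alternative leader TRSs are a real, if unusual, possibility), and
a downstream ORF for which no window passes the threshold is reported
as an honest absence rather than a forced call.

# -1 frameshift signal

Every 7-nt window of the ORF1a/ORF1b overlap is scored by Hamming
distance against a heptamer library (defaults: the invertebrate-
nidovirus AAAUUUU plus coronavirus- and arterivirus-type motifs) and,
separately, against the generic slippery pattern XXXYYYZ (X ≠ Y,
Z ≠ Y; requiring X ≠ Y keeps the two motif classes distinct, e.g. a
U₇ homopolymer is not a pattern instance). The two scores are kept in
separate columns (`lib_hamming`, `xxxyyyz_hamming`) precisely because a
generic pattern instance can arise by chance in a 40-nt overlap and
should not silently displace a library match; the overall ranking is by
the better of the two, ties to the 5'-most window.

The frameshift geometry fixes which windows are admissible: the last
base of the heptamer is taken as the **doubly-read nucleotide**, read
once as the 3rd base of an ORF1a codon and again as the 1st base of
the first ORF1b-frame codon. The heptamer-relative offset of that
nucleotide is a package convention chosen because it reproduces both
frame identities exactly; windows violating either congruence are
discarded. Distances from the site to the ORF1a stop (downstream) and
to the ORF1b-frame upstream stop are reported; they satisfy
`d_down + d_up = overlap_len - 1` identically.

Downstream structure is assessed by Nussinov base-pair maximization
over a 190-nt window starting immediately 3' of the heptamer (the
exact 5' origin of published fold windows is rarely stated, so the
offset is configurable with default 0). Minimum hairpin loop 3 nt;
G-U wobble pairs allowed by default; pseudoknots are outside the model
by construction. The traceback prefers pairing the 5' base and then
the leftmost partner, making the reported structure deterministic among
co-optimal ones. This replaces thermodynamic folding deliberately: the
package claims only stem-loop presence and topology (pair count,
dot-bracket), never free energies or a specific published fold
geometry.

# The genome-size association test

Given n lineages, k of them trait-positive, the success probability is
fixed at p = k/n (not re-estimated per group). For a size threshold t
the statistic is

Binom(k_below; n_below, p) × Binom(k_above; n_above, p),

evaluated in log space with exact binomial coefficients — n is small
and the headline value is of order 10⁻⁶, so no normal approximation is
appropriate. One threshold is placed at the midpoint of each pair of
consecutive unique sizes (unique sizes - 1 thresholds; the reported
argmin also carries the open size interval it separates, and ties go
to the smallest threshold). The scan depends only on the *ordering* of
sizes, never their absolute values, which the tests verify by a
monotone-transform metamorphic check.

The product-of-binomials minimum is an optimistic (minimized) quantity,
not a calibrated p-value; `permutation_null()` provides the companion
significance check by shuffling trait labels and re-scanning. The two
numbers are reported side by side and never conflated.

`nidovirus_lineages()` ships a 43-lineage reconstruction with 4
trait-positive lineages whose boundary sizes are the published ones
(largest trait-negative 19,600 nt; smallest trait-positive 20,192 nt;
remaining positives in the 26.3–31.7 kb band). The interior
trait-negative sizes are synthetic — only the boundaries and counts are
fixed by published values, and by the ordering property they are all
the headline result depends on. The companion `gap_timeline()` and
`domain_share()` express how the size gap between trait-positive and
trait-negative genomes shrank over time and what fraction of the gap a
set of protein domains could encode (3 nt per codon).

# The synthetic-data generator

`generate_genome()` emulates the target architecture at reduced scale:
default 8 kb total with a 360-nt 5'-UTR, a 3,000-nt ORF1a, a 40-nt
ORF1a/ORF1b overlap in the -1 frame, two downstream AUG ORFs, a ~0.9-kb
3'-UTR and a 25-nt poly(A) tail — the printed proportions of the
insect-borne nidovirus genome at reduced length, chosen so a full
simulate-annotate-verify cycle runs in well under a second. The
background is uniform A/C/G/T; the only non-uniform elements are:

* **boundary codons**: an in-frame stop planted immediately 5' of every
  planted ORF start makes the planted start the 5'-most of its open
  stretch, so recovery is exact by construction;
* **stop scrubbing**: in-frame stops inside planted ORFs are removed by
  resampling free codon positions, iterated across the overlapping
  reading frames until clean; positions owned by planted features are
  never touched, and a specification that forces a fully planted stop
  codon fails with a named constraint error;
* **TRS copies**: the body copy equals the leader copy except for the
  requested number of substitutions (no indels, matching the observed
  length-preserving near-perfect pairs). Substitutions are placed at
  interior positions 3..L-2 and both copies get 8-nt mismatching
  "anti-flank" guards: with the default discovery length cap
  (`max_unit + 8`) any extension, shift or trim of the planted window
  then strictly lowers the pairing score, so the planted extent is the
  unique dominant candidate and recovery at exact coordinates is
  well-defined;
* **slippery site and hairpin**: the heptamer ends on a frame-valid
  doubly-read position inside the overlap (default 18 nt before the
  ORF1a stop end); a stem-loop with complementary arms is planted just
  3' of the ORF1a stop, rejection-sampled so it introduces no
  ORF1b-frame stop.

The generator is deterministic under its seed (byte-identical FASTA),
and every truth feature is recoverable from the emitted sequence by
exact string comparison — the tests check this closed loop directly.

What the generator does *not* emulate: realistic codon usage or
dinucleotide bias, phylogenetic divergence between repeat copies
(substitutions only, no indels), secondary TRS-like decoys outside the
planted ones (decoy repeats are available but placed inside ORF1a), or
chimeric/segmented genomes. Passing recovery tests therefore shows the
algorithms are correct on genomes whose signal-to-background structure
resembles the planted one; it does not show robustness to compositional
biases real genomes may have.

`generate_lineage_table()` likewise emulates the trait/size table: a
"separable" mode that forces the published boundary sizes to be
realized (so the scan's argmin interval is known by construction) and a
"mixed" mode with random trait placement for null comparisons. All
sizes are distinct, so the threshold count is always n_unique - 1.

# Numerical choices, determinism and problem sizes

* Binomial densities via `stats::dbinom(log = TRUE)`; products as sums
  of logs; the argmin uses a 1e-9 log-space tolerance so exact
  mathematical ties resolve to the smallest threshold instead of
  depending on floating-point noise.
* The Nussinov recursion is quadratic in memory with a vectorized inner
  maximization; the 190-nt default window folds in about a second in
  pure R. Exhaustive-enumeration cross-checks run at window lengths
  ≤ 12 where enumeration is exact.
* The global aligner is affine-gap Gotoh; its score is cross-checked
  against an independent aligner (Biostrings::pairwiseAlignment) under
  the equivalent gap parameterization.
* Test problem sizes: repeat-finder/oracle equivalence up to 2.5-kb
  sequences; ORF-finder/oracle on 300-nt sequences; threshold-scan
  brute force at n ≤ 12 including every labeling at n = 5; parameter
  recovery over 100 seeded 8-kb genomes with planted TRS lengths 10–16
  and 0–2 mismatches. These sizes keep the full suite at a few minutes
  on one CPU while leaving every algorithmic path oracle-checked.
* All randomness flows through R's RNG; `generate_genome` seeds from
  its spec, and table generation and permutation tests take explicit
  seed arguments, so identical configuration plus seed gives
  byte-identical reports.

# Known limitations

* ORF labelling in `annotate()` is heuristic (ORF1a = longest AUG ORF;
  ORF1b = longest -1-frame open ORF overlapping it); unusual genome
  plans may need manual labels passed to the stage functions directly.
* The repeat library is capped at 16-nt units by design; longer perfect
  repeats surface as near-perfect pairs instead.
* Stem-loop detection maximizes pair count, which can overcount
  biologically implausible isolated pairs; it is a presence/topology
  indicator, not a folding engine.
* The packaged lineage table's interior is an explicit reconstruction;
  analyses that depend on more than the size ordering and the boundary
  values should build their own table from curated data.
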