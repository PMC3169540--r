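# nidoscan

Comparative-genomic annotation of nidovirus-like positive-strand RNA
virus genomes, and a threshold test linking a genomic trait (such as
presence of the proofreading 3'-5' exoribonuclease, ExoN) to genome
size.

Nidoviruses (arteri-, corona-, toro-/bafini- and roniviruses, and
their insect-borne relatives) share a polycistronic genome plan: two
large 5' replicase ORFs (1a and 1b) expressed as polyproteins pp1a and
pp1ab via a -1 programmed ribosomal frameshift, followed by 3'-proximal
ORFs expressed from 3'-coterminal subgenomic (sg) mRNAs whose synthesis
is guided by transcription-regulating sequences (TRSs) — a leader copy
near the genome 5' end and near-identical body copies just upstream of
the downstream ORFs. `nidoscan` implements the computations used to
establish this architecture from a genome sequence alone, plus the
statistics used to relate ExoN to large genome size:

- **ORF and UTR annotation** (`find_orfs`, `overlap_and_frame`,
  `delineate_utrs`): AUG-to-stop and stop-to-stop ("open") ORFs — the
  latter for frameshift-expressed ORF1b-style regions — with overlap
  lengths and relative reading frames, and protein-level reports
  (`protein_features`): composition, cysteines, N-X-S/T sequons,
  Kyte–Doolittle hydrophobic stretches.
- **TRS discovery** (`find_perfect_repeats`, `filter_positional`,
  `pair_near_perfect`, `align_flanked`, `discover_trs`): maximal exact
  direct repeats with unit sizes 4–16 nt, filtered by the leader/body
  positional constraints (one copy 5' of ORF1a, one inside the 300-nt
  window upstream of a downstream ORF), extended to near-perfect
  ungapped leader/body pairs, scored by a flanked global alignment, and
  turned into sg mRNA size predictions (`predict_sg_mrnas`).
- **-1 frameshift signal scanning** (`scan_slippery`,
  `fold_downstream`, `nussinov`): Hamming-distance scan of the
  ORF1a/ORF1b overlap against a slippery-heptamer library (e.g. the
  ronivirus AAAUUUU) and the generic XXXYYYZ pattern, constrained to
  windows whose last base — the doubly-read nucleotide — is decoded as
  the 3rd base of an ORF1a codon and the 1st base of the first
  ORF1b-frame codon; stem-loop detection downstream by Nussinov
  base-pair maximization (topology only, no free-energy model).
- **Genome-size association** (`scan_thresholds`,
  `partition_probability`): for each threshold separating two unique
  genome sizes, lineages are split into the groups below and above, and
  the test statistic is the product of the two binomial densities of
  the trait-positive counts at a fixed success probability p = k/n.
  With n = 43 lineages, k = 4 trait-positives and perfect separation,
  the minimum is (4/43)^4 (39/43)^39 ≈ 1.7 × 10⁻⁶. A permutation
  companion (`permutation_null`), a size-gap timeline (`gap_timeline`)
  and a domain-share measure (`domain_share`) round out the analysis.
- **Synthetic data with ground truth** (`genome_spec`,
  `generate_genome`, `generate_lineage_table`): seeded
  nidovirus-like genomes with planted ORFs, TRS pairs, slippery
  heptamer, hairpin and poly(A) tail, so every stage is testable
  without downloads.

`annotate()` and `sizetest()` orchestrate the stages; a thin CLI
wrapper lives at `inst/scripts/nidoscan.R`.

## Worked example

```r
library(nidoscan)
sim <- generate_genome(genome_spec(seed = 1))
annotate(sim$record)
```

```
annotation of 'synthetic_seed1' (8000 nt)
  label start  end length_nt frame mode
1 ORF1a   361 3360      3000     0  aug
2 ORF1b  3321 6200      2880     2 open
3  ORF2  6281 6700       420     1  aug
4  ORF3  6801 7130       330     2  aug
5'-UTR (1-360), 3'-UTR (7131-8000)
RFS: best heptamer AAATTTT (ronivirus, hamming 0), doubly-read nt 3342
predicted sg mRNA body segments (kb): ORF2=1.7, ORF3=1.2
```

ORF1b starts inside ORF1a (40-nt overlap, -1 relative frame) and has
no AUG of its own — it is annotated in "open" mode because it is
expressed by ribosomal frameshifting at the slippery heptamer, whose
last nucleotide (position 3342 here) is read twice, once in each frame.
Each downstream ORF's sg mRNA size is the distance from its start to
the genome 3' end (they are 3'-coterminal).

The association test on the packaged 43-lineage reconstruction:

```r
scan_thresholds(nidovirus_lineages())
```

```
threshold scan: 43 lineages, 4 trait-positive (p = 0.0930)
  42 thresholds; min probability 1.66e-06 (~10^-6)
  argmin threshold 19896.0 nt, separating (19600, 20192)
```

The four ExoN-positive lineages all have genomes larger than every
ExoN-negative lineage, so the most discriminating threshold falls
between the largest ExoN-negative genome (19.6 kb) and the smallest
ExoN-positive genome (20.192 kb) — about 20 kb — with a chance
probability of order 10⁻⁶.

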