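---
title: "Methods: full-length scFv annotation, filtering and clone tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-length scFv annotation, filtering and clone tracking}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phage-display selection of single chain Fragment variable (scFv) antibodies
produces libraries in which each clone pairs one heavy-chain variable domain
(VH) and one light-chain variable domain (VL) through a peptide linker.
Because an scFv insert runs to ~800 bp (plus vector flanks and PCR primers,
~1,000 bp per amplicon), only long-read circular-consensus sequencing can
read both domains in a single molecule, and the analysis has to solve a
problem ordinary repertoire annotators do not face: finding and
characterizing *two* V domains per read, in either order and orientation.

`scfvtools` implements that analysis end to end:

1. **Germline reference** — a validated directory of V/(D)/J alleles with
   explicit V-REGION spans and CDR3 anchor positions (FASTA + TSV sidecar).
2. **Dual-domain annotation** — per read: orientation, two local V-domain
   hits, closest germline V and J alleles, V-REGION identity, junction
   (CDR3) extraction and translation, domain layout (VH-VL, VL-VH, VH-VH,
   VL-VL or incomplete), linker location.
3. **Filtering** — a read is kept iff *both* domains have germline identity
   strictly above 85% and an in-frame junction; per-(PCR sample, SMRT cell)
   summary tables with three coverage percentages.
4. **Clonotype ranking and clone tracking** — reads are grouped by the
   layout-aware key (V allele, J allele, junction AA) × 2 domains; a
   reference clone is tracked both by that key and by alignment (full
   coverage of the reference scFv, at most 20 differing nucleotides), its
   reads classified as identical over the whole insert, identical over a
   core span, or related; related reads are grouped by mutation signature
   and assigned a provenance category from replication across PCR
   samples/SMRT cells.
5. **Synthetic library** — a seeded generator of clones, panning-style
   abundances and consensus-level reads, so every stage is testable with
   known ground truth.

## Alignment and identity

All pairwise alignments use one scoring scheme: match +2, mismatch −3, a
gap of length $L$ costs $6 + L$. Domain *detection* is local (both
orientations of the read against every V allele; the best hit orients the
read, the best non-overlapping second hit above a score floor gives the
second domain). Domain *characterization* re-aligns the chosen V-REGION
end-to-end inside a window of the read ("global–local"), so terminal
mismatches are not clipped, and defines

$$\mathrm{identity} = \frac{\#\text{match columns}}{\#\text{alignment columns}}$$

with gap columns in the denominator (indels penalize identity; the
definition is order-independent and conservative). Identity is reported to
two decimals, rounded half away from zero — the same rounding used by all
summary percentages.

The test suite re-derives this quantity with an independent affine-gap
dynamic-programming oracle written from the scoring definition alone, and
asserts score equality on 200 random pairs and identity equality on the
homologous pairs. For unrelated random sequences co-optimal alignments with
different match counts exist, so identity equality is only asserted where
the pair is actually homologous.

## Junctions, frame, and the filter

The junction runs from the first nucleotide of the V gene's 2nd-CYS codon
to the last nucleotide of the J gene's J-TRP/J-PHE codon, both mapped
through their alignments. *In frame* means junction length divisible by
three — a stop codon does not disqualify a read, because the filter is a
frame filter, not a productivity filter. The identity filter is strict
(`> 85`, not `>=`), following the published wording; both the threshold and
the frame requirement are configurable. A read with fewer than two detected
V regions counts as analyzed but never as a candidate.

## Reference-clone tracking

Two routes, whose union is reported:

* **by characteristics** — exact equality of the clonotype key (both
  domains' V and J allele calls and junction amino-acid sequences, plus
  layout);
* **by alignment** — the reference scFv aligned end-to-end inside each
  read (either orientation); retained iff coverage is complete and
  mismatches + inserted nt + deleted nt ≤ 20 (each indel nucleotide counts
  one — the stricter, deterministic reading of "20 mismatches or indels").

Tracked reads are classified against the full reference insert:
`identical_full` (byte-identical over the whole insert, primers included),
`identical_core` (all differences outside the core span; the core defaults
to positions 3 through `total_len − 36`, i.e. 3–941 of a 977-nt insert,
excluding both primer termini and a 16-nt vicinity window inside the 3'
primer), else `related`.

Differences are enumerated from a global alignment, merged into runs, and
**left-normalized** (indels in homopolymers take the 5'-most coordinate),
then formatted in IMGT-style nomenclature: `c322>t`, `a942>del`,
`a886-a977>del (92 nt)`, `658^659>ins^cc`. Each mutation is localized
against the amplicon geometry (forward-primer end, reverse-primer end,
reverse-primer vicinity, VH, linker, VL, or vector flank).

### Provenance categories

Related reads are grouped by their **mutation signature**: the multiset of
insert-localized mutations, excluding primer-end and primer-vicinity events
and terminal deletion runs (those are sequencing/PCR artifacts of the
amplicon ends, not library content). A design note: the signature includes
non-terminal indels, not only substitutions — under a substitutions-only
signature, three reads carrying *different* single indels would share an
empty signature and be grouped, which is semantically wrong and could
promote them to category A.

A group is **category A** (provenance: library) iff it contains at least
two reads from at least two distinct PCR samples (a looser ≥2-SMRT-cells
mode is available): the same mutations arising independently in separate
amplifications cannot be sequencing error. Everything else is **category
B**: singletons with an indel in the signature are flagged
`putative_sequencing_error`, substitution-only singletons
`putative_pcr_or_library`, multi-read single-sample groups `unassigned`.

A read whose signature equals a replicated signature joins that group even
if it additionally carries excluded-class differences (a terminal deletion,
a primer artifact) — this reproduces the published grouping in which a read
with the four replicated VL substitutions *plus* a 92-nt terminal deletion
still counts as library-derived.

## The synthetic world

The generator states one concrete world; its defaults are the conditions
the analysis assumes and are not tuned to test outcomes:

* **Geometry** — 23-nt forward primer `TGCAAATTCTATTTCAAGGAGAC`, 74-nt 5'
  vector flank, VH, 53-nt linker containing EcoRI (`GAATTC`) and XbaI
  (`TCTAGA`) sites, VL, 93-nt 3' flank, reverse complement of the 20-nt
  reverse primer `TCACGTGCAAAAGCAGCGGC`. The flank widths make a 767-nt
  scFv yield a 977-nt amplicon, matching the published primer placements.
* **Domains** — germline V (300 nt, 2nd-CYS codon at 292–294) + junction
  N-insert + germline J (48 nt heavy with J-TRP at 10–12; 50 nt light with
  J-PHE at 12–14). N-insert lengths are drawn so the junction stays in
  frame except for a configurable out-of-frame fraction (default 2%,
  library junk removed by the frame filter).
* **Abundances** — Zipf with exponent 1.5 over clones: panning enrichment
  concentrates read mass on a few dominant clones over a long tail.
* **Layout mix** — (0.60, 0.395, 0.0005, 0.0045) over VH-VL, VL-VH, VH-VH,
  VL-VL; the off-type rates are near the observed per-dataset frequencies
  of double-heavy and double-light assemblies.
* **Mutation load** — Poisson substitutions per domain, default 0.5 (VH)
  and 2 (VL): the library was mutagenized with a light-chain bias, and the
  replicated signatures observed in tracking are VL substitutions.
* **Errors** — residual consensus error, default ≤ 1e-3 per base, mixture
  0.40 substitutions / 0.25 insertions / 0.35 deletions (no published
  kind fractions exist for this protocol; consensus residuals are
  indel-leaning), with the
  deletion rate boosted ×20 within 3 nt of either amplicon end to emulate
  primer-terminal artifacts. Reads are reverse-complemented with
  probability 1/2.

What the generator does **not** emulate: PCR chimeras (the wet protocol
minimized them and no chimera rate is reported), polymerase-kinetics or
ZMW-level effects, quality-score variation (constant Q30 FASTQ), and real
germline diversity (the shipped reference is a seeded structural stand-in —
anchors and spans behave like a curated directory, the sequences are
random). A green test therefore establishes the correctness of the
*analysis logic* under the stated world, not concordance with any real
germline database.

## The tracking fixture

The published tracking experiment is reconstructed from its printed tables:
85 reads, each the synthetic 977-nt reference with a printed mutation list
applied (empty for 53 reads; primer-terminal events for 7; 15 mutation
types for the 25 related reads), carrying the printed PCR-sample and
SMRT-cell assignments. The real reference clone is patented and unprinted,
so the insert is a synthetic stand-in whose base at every printed mutation
position is pinned to the printed reference base, with indel contexts
disambiguated (no equal neighbour base) so alignment-based mutation calling
recovers the printed coordinates after left-normalization. Where the tables
give per-group (not per-read) cell lists, reads are assigned in listed
order consistent with the read numbering; the category tallies are
invariant to that choice.

Running the full pipeline on this fixture yields 53 / 7 / 25 reads in the
three identity classes, 15 category-A and 10 category-B related reads, and
error-free nucleotide tallies 53×977 = 51,781, 7×939 = 6,573, combined
58,354 — each recomputed, never asserted as constants. One printed
mutation list (a read with two substitutions adjacent to a 2-nt insertion)
admits a shorter edit script; the pipeline reports the minimal form, and
the read's category is unaffected.

## Numerical choices and degenerate inputs

* Rounding: half away from zero at 2 decimals everywhere a table is
  printed; integer rounding only for the final error-free-read percentage.
* Tie-breaks: V-allele calls by identity, then aligned span length, then
  lexicographic allele name; ranking ties share the minimum rank.
* Degenerate inputs: empty FASTA, missing metadata rows, anchors outside
  sequences, contradictory overlapping mutations, empty batch groups and
  sub-100-nt tracking references are hard errors with named culprits;
  an empty hit list, an absent linker, and an empty tracking report are
  valid results, not errors.
* Determinism: every stochastic step takes an explicit seed; rerunning any
  command on identical inputs is byte-identical (output headers carry the
  package version, a config fingerprint and the seed, never wall-clock
  time).

## Known limitations

* The upstream portal's internal scFv segmentation algorithm is
  unpublished; this package implements the documented contract above, so
  candidate percentages on real data may differ from the published
  coverage table, whose values are verified here as arithmetic on the
  printed counts.
* D-segment calls use a minimum 5-nt exact core within the VH junction and
  are otherwise `"not assigned"`; short CDR3s make D calls unreliable and
  no assignment rule is published.
* Identity of the category-A probability property: an exact-signature
  grouping rule bounds the probability a spiked variant read is labeled A
  by the probability the read itself acquired no extra insert error, so
  the ≥0.95 soundness property is evaluated on spiked reads without extra
  simulated noise; the never-A property for pure error singletons is
  evaluated verbatim across 50 seeded simulations.
* No IMGT unique numbering, FR/CDR1-2 delimitation, statistical
  two-dataset clonotype comparison, or lineage reconstruction.
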