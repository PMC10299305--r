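---
title: "Screening particle preparations for GTA-like elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening particle preparations for GTA-like elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtasieve)
```

## The problem

Intracellular bacteria such as *Wolbachia* carry mobile genetic elements of
two very different kinds. Lambda-like prophages (Phage WO) package a genome
of roughly 65 kb that includes a eukaryotic association module (EAM) of
unusually large proteins — ankyrin-repeat proteins, AAA-ATPases,
latrotoxin-like domains — plus regulatory genes. Gene transfer agents
(GTAs), by contrast, are compact head–tail particle gene clusters of
15–20 kb that package mostly random fragments of the host chromosome.

When DNA is extracted from physical phage-like particles and assembled, the
two scenarios leave different fingerprints in the contig set:

* a GTA-like element appears as a short, very-high-coverage contig shared
  identically between independent preparations, with a complete head–tail
  module, all genes on one strand, no EAM-class giants and no regulatory
  genes — accompanied by a broad, shallow scatter of host-genome fragments;
* a prophage appears as a much larger element carrying EAM and regulatory
  content.

`gtasieve` turns that fingerprint reading into a tested pipeline: coverage
filtering and convergence, core extraction, ORF annotation, frameshift
evidence collection, repeat analysis, host-packaging assessment and a
transparent classifier.

## The inference chain

### Coverage-stringency convergence

Each contig carries the assembler's per-contig coverage (parsed from
SPAdes-style `_cov_` headers, or supplied via a sidecar TSV). Packaged
elements sit orders of magnitude above background — observed contig
coverages of several thousand against single-digit host fragments — so the
pipeline walks an ascending cutoff schedule (default
`0, 5, 10, 50, 100, 500, 1000, 2000, 3000`, mirroring a manual sweep from 0
to 3000) and stops at the first cutoff where

1. each dataset retains at most `max_survivors = 3` contigs, and
2. the best cross-dataset longest common exact substring reaches
   `min_core = 5000` nt.

The `min_core` floor prevents convergence onto short shared repeats; 5 kb is
far above any chance match and far below any element of interest. The
≤ 3-survivor rule is applied to each dataset separately. The emitted core is
the exact shared substring; a flank report localises the dataset-specific
sequence to the 5′ or 3′ side, the expected signature of two preparations of
the same element.

`longest_common_exact` is seeded with shared k-mers (descending seed sizes
31, 15, 8, 4, 2, 1; any common substring of length ≥ k contains a shared
k-mer) and resolved per diagonal, which is near-linear in practice. Its
contract — including `N` never matching, and ties broken towards the longer
match, then the lexicographically smaller substring, then the smaller
position, with forward orientation preferred — is pinned by an independent
suffix-DP oracle in the test suite.

### ORF calling and role annotation

`find_orfs` scans all six frames under the bacterial genetic code
(table 11). Each stop-delimited interval yields at most one ORF, from its
first start codon (default set `ATG, GTG, TTG`; alternative starts are
recoded to methionine) to the closing stop; codons containing `N` break
intervals. The default minimum length is 150 nt. Both parameters shape the
gene count of any record, so the effective configuration is embedded in
every report.

Roles are assigned by optimal local alignment (Smith–Waterman, affine gaps
11/1, BLOSUM62 with all scores against `X` fixed at −1) against a packaged
panel of reference proteins. An ORF receives the best-scoring role that
passes three thresholds:

* identity ≥ 0.35 over alignment columns,
* panel-protein coverage ≥ 0.5,
* raw alignment score ≥ 50.

The first two are the conventional homology-screen settings; the score floor
is this package's addition. Identity and coverage alone are not specific
against *short* panel proteins: a chance local alignment can cover half of a
64-residue hydrolase at 35 % identity, but it cannot do so at a raw score of
50. Where a BLAST-based workflow would rely on e-values (which account for
target length), a raw-score floor plays that role here. With all three
thresholds at zero, every ORF simply receives its argmax role.

### Frameshift evidence

A programmed ribosomal frameshift leaves a characteristic architecture: two
same-strand ORFs whose downstream member starts *inside* the upstream one,
before its stop codon, in a frame offset by +1 or −1.
`detect_fusion_candidates` enumerates such pairs and builds the putative
fusion protein by translating the upstream frame up to the shift point —
defined as the last upstream-frame codon boundary before the downstream
start codon — and the downstream frame thereafter. The shift sign is
reported, never filtered: the classic `XXXYYYN` slippery motif is best
associated with −1 events, yet +1 architectures occur, so the decision is
left to the evidence.

Around each junction a ±60 nt window (configurable; wide enough for the
repeat span observed at such loci without collecting genome-wide noise) is
scanned for three evidence classes:

* **slippery heptamers** — the positional class `XXXYYYN` with X ≠ Y
  (e.g. `AAATTTT`);
* **palindromes** — maximal even-length substrings equal to their own
  reverse complement, length ≥ 6 (perfect and even-length only; odd-center
  approximations are excluded to keep the definition and its oracle exact);
* **short repeats** — all direct and inverted k-mer pairs (default k = 9).

The evidence score is a transparent weighted tally of those counts, always
reported alongside the raw counts. It is not a calibrated statistic — the
package deliberately does not model RNA secondary-structure free energy or
motif-count significance.

In the assembled pipeline, candidate detection runs over the *role-assigned*
ORF set. Six-frame calling on any real-sized sequence produces spurious
short ORFs in off-frames and on the antisense strand; overlap architectures
among those are not biologically meaningful and would flood the candidate
list. The operation itself accepts any ORF table.

### Repeat analysis

`shared_exact_repeats` enumerates all maximal exact matches (default
≥ 50 nt, direct and inverted) between two sequences — for instance between
the converged core and a host contig carrying a rearranged element copy.
Hits are seeded with shared `min_len`-mers and resolved per diagonal; every
hit re-verifies by direct substring comparison, and values of `min_len`
below 8 are rejected as a hit-explosion guard. `tandem_scan` reports maximal
perfect tandem arrays of a requested unit length, re-expressed at their
smallest period (a homopolymer run scanned at unit length 5 is a period-1
array). Both contracts are fixed by brute-force oracles.

### Host packaging assessment

`map_contigs_to_host` maps query contigs onto the host genome by exact
21-mer matching on both strands. Contiguous overlapping k-mer matches from
one query are merged into a single footprint before incrementing the
per-base depth, so depth counts matching query placements. Without that
merge, one matching fragment would register depth ≈ 21 everywhere it
touches, and the two summary statistics — breadth at depth > 0 and breadth
at depth > 5 — would collapse into each other. Those two thresholds capture
the packaging signature: random host packaging gives broad shallow coverage
(high breadth > 0, low breadth > 5), while repeated element-derived content
stacks depth in narrow regions. Exact k-mer matching is adequate for
assembled contigs against their own host genome; an approximate read mapper
is deliberately out of scope.

### Long-ORF screen and foreign check

Contigs of ≥ 5,000 nt are screened for ORFs of more than 2,000 nt, the size
class of EAM proteins, and annotated against the panel's EAM entries
(ankyrin, AAA-ATPase, tape measure). A decoy panel of synthetic host-insect
proteins supports a contamination check: the count of long ORFs whose best
match across the combined panels is a decoy. A clean particle prep returns
zero.

### In-silico PCR

The enrichment QC mirrors a degenerate-primer PCR: the forward primer must
match the forward strand and the reverse primer the reverse strand
downstream, under IUPAC-compatible base matching with at most 2 mismatches
per primer, the 3′-terminal 3 bases exact, non-overlapping sites, and a
product of at most 2,000 nt. The mismatch policy is a modelling choice — a
wet-lab protocol reports only band presence or absence — and every part of
it is configurable.

### Classification

`classify_element` reduces the annotated element to five flags:

| flag | meaning | default |
|---|---|---|
| `size_ok` | element ≤ `size_threshold` | 25,000 nt |
| `single_strand` | strand consistency of assigned genes = 1.0 | — |
| `head_tail_complete` | terminase, portal and major capsid present, plus ≥ 2 tail/baseplate roles | — |
| `eam_absent` | no EAM-category role and no ORF > `eam_orf_threshold` | 2,000 nt |
| `regulatory_absent` | no regulatory-category role | — |

All five ⇒ **GTA-like**; a complete head–tail module that is oversized or
carries EAM content ⇒ **prophage-like**; anything else ⇒ **ambiguous**. The
25 kb size threshold separates the two observed scales — GTA-like regions of
roughly 15–21 kb against packaged phage genomes of roughly 65 kb — with a
wide margin on both sides. Strand consistency is computed over role-assigned
ORFs so that spurious unannotated antisense calls cannot flip the verdict;
when nothing is assigned, all ORFs are used.

## The synthetic-data generator

The generator produces the situation the pipeline is built for, with known
truth, so that every stage is testable without any external data.

**Core element.** A 15,638 nt single-strand element carrying 22 genes in a
fixed role order (methylase through DUF2924, including the head–tail module
and the split hydrolase). Gene products come from the packaged synthetic
panel; genes are reverse-translated with uniformly random synonymous codons,
separated by 24-nt "frame insulator" spacers that carry stop codons in all
six frames, plus random filler at GC 0.36 (the observed library
composition). The insulators guarantee that no reading frame runs across a
gene boundary on either strand, which makes the planted gene coordinates
exactly recoverable by six-frame calling. Per-role protein sizes (capsid
~360 aa, terminase ~433 aa, small hypotheticals 120–180 aa, …) are a
modelling choice; the hydrolase pair is fixed at 64 and 175 residues by the
frameshift architecture. When the requested core is too small for the full
table, ordinary genes are scaled down proportionally (floor 50 aa).

**The frameshift locus.** Genes 6 and 7 overlap by 8 nt: the downstream ATG
sits in the +1 frame, inside the upstream ORF, overlapping its stop codon.
Fixed codons realise, without changing the encoded proteins: a slippery
`AAATTTT` ending 4 nt upstream of the downstream start, a 10 bp palindrome
(`ACGAATTCGT`) and two copies of a 9 bp repeat within ±60 nt of the
junction, an upstream +1-frame stop that pins the called downstream ORF to
the planted start, and one concrete resolution of each degenerate QC primer
inside the downstream gene, so the synthetic core is PCR-positive.

**Host genome.** Two random-background contigs (defaults 60 kb and 40 kb; a
real *Wolbachia* chromosome is 1.3–1.5 Mb, and these sizes keep every
statistic meaningful at test-scale cost). Contig 1 embeds one exact copy of
the core — the resident prophage region — and the EAM loci: a giant ankyrin
gene of 11,826 nt (3,941 residues), a 717-residue AAA-ATPase and a
812-residue tape measure protein. Contig 2 embeds a rearranged partial copy
with a duplicated baseplate block, two IS110-family transposase genes and a
recombinase.

**Particle contig sets.** Dataset A is the core plus a 500 nt A-specific 3′
flank; dataset B the core plus a B-specific 5′ flank — which makes the core
the unique maximal shared substring by construction. Core coverage is drawn
from U[1000, 4500] (the observed coverage scale), EAM-locus windows
(1.5–1.7 kb flanks, dataset-specific extents) from U[2, 30], and
`n_host_fragments = 40` background fragments of 0.5–8 kb per dataset from
U[1, 5]. Fragments are sampled outside the embedded element intervals so
that the truth tables stay exact: the long-ORF screen must find exactly the
planted EAM loci, and the fragment footprint equals the measured breadth.
Under these conditions the sweep always passes through a cutoff (10–50)
where only the core survives in both datasets.

**What the generator does not emulate.** Sequencing errors, read-level
artifacts, chimeric or split contigs, strain-level variation between the
two preparations, biased codon usage, and real homology relationships
between panel and background. Green tests therefore demonstrate that the
inference chain is correct under its stated assumptions — exact
convergence, exact repeats, clean ORF structure — not that it is robust to
assembler noise. On real data the convergence step inherits whatever
disagreements the assemblies carry; exact matching is the contract, not a
robustness claim.

**Randomness contract.** A fixed seed fully determines all outputs
(byte-identical files); the three generator stages draw from seeds
`seed`, `seed + 1` and `seed + 2` so they can be re-run individually.

## Numerical and degenerate-input choices

* `N` is legal in sequences and never matches any base in exact-match
  operations, including as the seventh "any" position of a slippery motif.
* Internal coordinates are 0-based half-open everywhere; GFF3 emission
  converts to 1-based inclusive.
* A local alignment with no positively scoring cell returns score 0 with
  empty coverage; alignment ties are resolved by Biostrings' deterministic
  traceback, and annotation ties on score go to the earlier panel entry.
* An empty cutoff schedule, a contig without coverage, a zero-ORF
  classification call, an empty panel, and a primer shorter than its
  3′-exact requirement are all errors, not silent defaults.
* `max_survivors = 0` can never emit a core (a converged sweep needs at
  least one surviving contig per dataset); the sweep reports
  `converged = FALSE`.

## Problem sizes used in the tests

The test suite generates preps with 45 kb + 35 kb host contigs and 8–12
host fragments (the generator's statistical structure at lower cost), runs
the 20-seed end-to-end recovery on those, and checks each string primitive
against its brute-force oracle on 500 random instances of 15–120 nt (or
4–25 residues for alignments). The acceptance script runs the full default
configuration — 60 kb + 40 kb host, 40 fragments per dataset — end to end.

## Known limitations

* The classifier is a rule stack, not a probabilistic model; elements with
  partial modules land in `ambiguous` by design.
* Evidence scores for frameshifts are tallies; no significance is attached.
* Exact-match convergence cannot bridge assembly disagreements inside the
  element (a single mismatch splits the core).
* The in-silico PCR models primer annealing as mismatch counting; no
  thermodynamics.
* The packaged role panel is synthetic. Annotating real contigs requires a
  real ortholog panel in the same TSV format (`load_role_panel`).
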