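---
title: "Discovering novel taxa in metagenomic dark matter with metadark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering novel taxa in metagenomic dark matter with metadark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadark)
```

## The problem

Shotgun metagenomes of gut communities contain assembled contigs that a
genus-level classifier confidently places in a genus of interest — say
*Bifidobacterium* — yet that match no characterized species of that
genus. This genomic dark matter is both an opportunity (it encodes the
metabolic repertoire of an uncultured organism) and a challenge (there
is no isolate, so nothing to characterize). `metadark` operationalizes a
discovery loop around it: bin contigs to genus, separate dark matter
from known species and mobile elements, read the dark matter's
carbohydrate-active enzyme repertoire to choose selective carbon
sources for cultivation, and — once isolates exist — confirm novelty by
average nucleotide identity (ANI) and core-genome phylogenomics.

This vignette documents the models and procedures behind each stage,
the tunable parameters with their defaults and rationale, the numerical
conventions, and the limits of what the bundled synthetic validation
can show.

## Genus binning by proteome voting

Genes are predicted by a deterministic six-frame ORF caller: maximal
stop-to-stop ORFs beginning at ATG/GTG/TTG, at least 80 residues
(`min_aa`, configurable). This is deliberately not a trained gene
finder — for classification by proteome content, a complete and
reproducible ORF set matters more than precise gene boundaries.
Overlapping calls (reverse-strand "shadow" ORFs) are resolved greedily,
longest first, wherever gene *content* is counted.

Each predicted protein is searched against the panel proteome with a
5-mer prefilter (candidates must share at least two 5-mers; property
tests confirm the prefilter never drops a pair at ≥70% identity over
≥100 residues) followed by Smith–Waterman alignment under BLOSUM62 with
gap open −11 / extend −1. The search thresholds default to 30% identity
over 50% query coverage — loose on purpose: binning aims at genus-level
sensitivity, and species-level attribution is the novelty screen's job,
mirroring the two-stage logic of the workflow. The winning genus is the
one with the highest summed alignment score; `support` is the fraction
of hit-bearing genes that voted for it. Records shorter than 300 nt, or
records in which no ORF reaches `min_aa`, fall back to nucleotide-level
seeding against the panel genomes (ORF calling is unreliable there; the
fallback keeps short spike-in fragments detectable). A random sequence
with neither ORF nor nucleotide evidence stays `unclassified`.

Abundance profiles are bp-weighted and always sum to one including the
unclassified mass. The 0.2% reporting floor only affects rendering;
machine-readable output retains every genus exactly, so a genus spiked
at 0.1% is still present in the JSON.

## The novelty screen

Contigs of the target genus are screened in a fixed evaluation order:

1. **Length.** Only contigs strictly longer than 5,000 bp proceed
   (`min_len = 5000`); shorter contigs give too little evidence at any
   level and are labeled `too_short`.
2. **Mobile elements.** The fraction of genes whose best hit among
   phage/plasmid marker proteins outscores their best panel hit; at
   ≥0.5 (`mobile_gene_fraction`) the contig is a `mobile_element`. This
   automates what is otherwise a manual curation step; contigs with a
   borderline fraction (0.3–0.5) are listed for human review instead of
   being auto-decided. The package ships a small synthetic placeholder
   marker set (capsid/terminase/integrase/relaxase-like labels);
   substitute a real database via `build_panel(mobile_markers=)`.
3. **Known-species tests**, against each panel genome:
   - *nucleotide*: the contig is cut into 1,020-nt fragments, each
     seeded by exact 15-mers onto the genome and scored on the modal
     diagonal; the contig matches a genome when fragments at ≥95%
     identity (`nt_known_identity`) cover ≥75% of it (`nt_known_cov`);
   - *protein*: mean best-hit identity to a single genome ≥96%
     (`prot_known_identity`) over at least half of the contig's genes;
   - *whole-sequence*: union coverage of the anchored fragments at the
     nucleotide identity threshold ≥75% (`wga_known_cov`). This test
     shares the anchor machinery with the nucleotide test but asks only
     for coverage, so it can rescue contigs whose per-fragment mean
     identity straddles the threshold.
4. Everything else is a `novel_candidate`; a contig with no genes and
   no nucleotide hits is retained conservatively with a `no_evidence`
   flag rather than silently dropped.

The three cutoffs are declared defaults, not reproductions of published
ones: the nucleotide threshold is aligned with the 95% ANI species
boundary, the protein threshold sits slightly above it because amino
acid identity exceeds nucleotide identity for closely related genomes,
and both coverages ask that most of the contig be explained, not just a
conserved island. Every report echoes the thresholds in its header.
Lowering `nt_known_identity` can move contigs only from
`novel_candidate` to `known_species`, never the reverse — this
monotonicity is property-tested.

## Glycobiome and substrate recommendation

Dark-matter genes are assigned to glycosyl-hydrolase families by best
hit against a labeled GH reference set at ≥40% identity over ≥70%
coverage — GH families are conserved across genera at roughly this
level, and the threshold is configurable. Relative family abundances
feed a rule table mapping GH signatures to carbon sources:

| pattern | substrate |
|---|---|
| GH13 with a pullulanase label | pullulan |
| GH13 with an amylase label | starch |
| (GH10 or GH11) and (GH43 or GH3 β-xylosidase) | xylan |
| GH53 | arabinogalactan |

A rule fires only when all of its conjuncts are present; the substrate
score is the summed weight × relative abundance of supporting families,
and every recommendation lists its supporting gene ids. How GH presence
is best converted into a cultivation shortlist is genuinely open; the
rule table makes the mapping explicit and editable (TSV) rather than
burying it in code, with all default weights at 1. The xylan rule
requires both an endo-xylanase and a β-xylosidase because either alone
is weak evidence of complete xylan utilization. Rules act on GH
evidence only — transport and regulatory loci are not required, which
can overcall substrates for organisms that degrade but do not import a
glycan.

## Fragment-based ANI and the species boundary

The query genome is cut into consecutive non-overlapping 1,020-nt
fragments; each is mapped onto the subject by exact 15-mer seeding. If
the seed support concentrates on one diagonal the placement is scored
gaplessly (a Hamming comparison, excluding N positions); if the seeds
spread over nearby diagonals — indels — the fragment is realigned with
affine gaps against the implied window. Fragments are kept at ≥30%
identity and ≥70% aligned coverage; one-way ANI is the mean identity of
kept fragments and reciprocal ANI the mean of both directions. These
are the conventional fragment parameters of alignment-based ANI, kept
configurable and recorded in output headers. When no fragment passes,
the result is an explicit no-homology state — never an ANI of 0 — and
the species call becomes `undefined`.

The boundary rule is strict: reciprocal ANI < 95% ⇒ distinct species;
exactly 95% ⇒ same species. Parameter-recovery tests confirm that for
substitution rates of 1–10% on megabase genomes the recovered ANI sits
within 1 unit (empirically within ~0.05) of the expected
`100·(1 − rate)`. Because identity is computed over aligned columns,
indels depress fragment coverage before they depress identity — a
documented property, not a bug.

## Core-genome phylogenomics

Ortholog clusters are connected components of a protein similarity
graph: edges require ≥50% identity with ≥50% bidirectional coverage,
after the same 5-mer prefilter used everywhere else. Connected
components (rather than Markov clustering) keep the procedure
deterministic and dependency-free; cluster ids are stable across runs
because components are ordered by their sorted member lists. Core
clusters are present in every genome; single-copy core clusters have
exactly one member per genome, and the difference counts the
paralogous core excluded from the phylogeny.

For the tree, each single-copy core gene contributes a pairwise
p-distance matrix (1 − identity/100 from global protein alignments),
and the genome distance is the gene-length-weighted mean. This is the
package's stated substitution for concatenating aligned core proteins:
it preserves the distance signal that neighbor joining consumes while
avoiding a multiple-sequence-alignment dependency. The NJ
implementation is the canonical Saitou–Nei agglomeration with
deterministic tie-breaking (smallest current pair indices); negative
branch lengths arising from non-additivity are clamped to zero with the
deficit moved to the sibling branch, preserving path lengths. On
additive matrices NJ is exact — validated against round-trips from
random trees up to 12 taxa and against a brute-force least-squares
oracle over all 15 five-taxon topologies. The final tree is rooted on a
user-chosen outgroup.

Bootstrap supports resample *genes* with replacement — not alignment
sites, because the pipeline never builds a site-level supermatrix. Per
replicate only the length-weighted combination of precomputed per-gene
distance matrices is redone, so 1,000 replicates cost seconds. The
support of an internal edge is the percentage of replicate trees
containing the same bipartition (bipartitions are canonicalized to be
invariant to taxon input order); supports appear as internal node
labels in the Newick output. Gene-resampling supports read like gene-
tree concordance: strongly heterogeneous genes lower them even when
site-level support would be high.

## The synthetic study conditions

All validation runs on simulated data with known truth:

- **Genomes** are i.i.d. base sequences at a target GC with implanted
  ORFs (ATG…stop, 300–1,500 nt) covering ≥60% of the genome, each
  preceded by an in-frame stop so ORF callers recover exact
  coordinates; intergenic bases are adjusted minimally so realized GC
  hits the target.
- **Divergence** is per-site substitution at a chosen rate (uniform
  alternative base), so expected identity is `100(1 − rate)`. The
  `preserve_orfs` mode emulates purifying selection: start/stop codons
  are immutable and substitutions that would create an in-frame stop
  are redirected, so gene content survives deep divergence (at the cost
  of ~1% of sites being protected, a bias well inside all stated
  tolerances). Protein-level fixtures draw replacement residues
  uniformly, so realized amino-acid distance is 19/20 of the nominal
  rate.
- **Communities** mix genome fragments at chosen bp abundances with
  exponential contig lengths calibrated to a target N50; **spike-ins**
  titrate a target genome into a background at decreasing bp fractions
  with the last contig trimmed to hit the fraction exactly (floor of
  300 nt per contig).
- Every generator is seed-deterministic: same arguments, byte-identical
  output.

Problem sizes used by the tests and the acceptance script — 1-Mb
genomes for ANI, a four-genome panel of 60-kb genomes for
binning/screening, ~400 kb of background for the titration, six
proteomes of ~54 genes for the pangenome, 20 random matrices for NJ —
were chosen as the smallest sizes at which the statistical tolerances
above are meaningful; all complete on a single CPU in a few minutes.

What the synthetic conditions do **not** emulate: sequencing error and
chimeric assembly, codon bias and GC skew, repeat-induced misassembly,
horizontal transfer between panel members, rearrangements and indels at
realistic rates, and the composition of real GH/mobile databases (the
shipped reference sets are labeled synthetic placeholders). Passing
tests therefore demonstrate that the algorithms do what they claim
under controlled divergence — not that default thresholds are optimal
for any particular real community.

## Numerical conventions and degenerate inputs

- Coordinates are 0-based half-open internally; GFF3 export converts to
  1-based inclusive.
- Alignment identity is computed over aligned columns; for nucleotides,
  columns containing N are excluded from the denominator (N is neither
  match nor mismatch).
- Nucleotide scoring: match +1, mismatch −1, gap open −5, extend −2;
  proteins: BLOSUM62, gap open −11, extend −1. The underlying dynamic
  programming is Biostrings' C implementation.
- Ties are broken deterministically everywhere: best hits by higher
  identity then lexicographically smaller genome id, genus votes by
  name, NJ joins by smallest pair indices, substrate ranks by name.
- Empty inputs are contracts, not crashes: an empty contig file is an
  input error; an all-N contig yields no ORFs; a genome with zero
  proteins is a hard error for clustering (the core would be
  undefined); an empty core yields a warning and no tree; `n_reps = 0`
  yields a tree without supports and a warning.
- `run_discovery`/`run_confirmation` reports embed the tool version and
  a config hash, contain no timestamps, and are byte-identical across
  re-runs with the same seed.

## Known limitations

The ORF caller will miss genes using rare start codons or split by
frameshifts. The novelty screen's automated mobile-element test is a
surrogate for expert curation, and a real screen reduced its contig set
partly by manual criteria that cannot be reproduced exactly — reports
flag the surrogate accordingly. Ortholog cluster counts are sensitive
to the identity/coverage thresholds, so absolute cluster numbers are
not comparable across parameterizations (core/single-copy/paralog
*differences* are much more stable). ANI is exact alignment-based and
quadratic-ish in genome count; for hundreds of genomes a sketching
method would be preferable. The glycobiome rules encode positive GH
evidence only.
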