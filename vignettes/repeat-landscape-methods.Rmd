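---
title: "Methods: repeat-landscape characterization from unassembled reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-landscape characterization from unassembled reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In large plant genomes most of the DNA is repetitive — LTR
retrotransposons, DNA transposons, satellite arrays, rDNA — and in an
allopolyploid like hexaploid oat (*Avena sativa*, AACCDD) repeat
families can be confined to one subgenome, shared between two, or
spread across all three. Because assembly of such genomes is hard and
unnecessary for this question, the repeat landscape can be read
directly from unassembled whole-genome shotgun reads: k-mer spectra
measure how much of the genome is repetitive; graph-based clustering
of read overlaps groups reads into repeat families; consensus and
periodicity analysis characterize tandem monomers; and mapping each
subgenome's reads back onto family fragments estimates per-subgenome
copy numbers and genome specificity.

`repeatscape` implements this workflow at desk scale with a fully
truth-annotated synthetic genome generator, so every stage can be
validated against planted ground truth rather than eyeballed.

## Synthetic genomes and reads

`repeat_family_spec()` parameterizes one family: satellites (a monomer
tiled into contiguous arrays — FISH-visible arrays are tens of kb, so
contiguous is the default), LTR retroelements (two identical terminal
repeats around internal domains in a stated order), DNA transposons
(terminal inverted repeats around a transposase), rDNA units
(concatenated components of fixed lengths, e.g. the 45S unit
ETS-18S-ITS1-5.8S-ITS2-26S = 3197+1811+260+168+216+3407 = 9059 bp), and
free-form templates. Each planted copy is independently mutated at the
family's per-copy divergence (substitutions only — no indels in this
version, which keeps overlap identity exact and period estimation
ungapped). Domain sequences come from a bundled synthetic exemplar
library; each family additionally diverges its exemplar-derived parts
by a `template_divergence` (default 12%) so that two families sharing a
domain (e.g. Gypsy-like and Copia-like elements both carrying RT) stay
well-separated at the DNA level, as real superfamilies are, while
remaining detectable by the scanner.

`assemble_genome()` inserts all copies into random background (default
GC 0.4323, the average GC of oat shotgun reads) without overlap and
records exact truth: intervals (0-based half-open, BED convention),
base proportions, and per-subgenome copy counts. `simulate_reads()`
emulates the sequencing design: 2 × 250 bp pairs from 500 bp inserts,
uniform fragment positions, fixed "I" quality (real library quality
profiles are not modelled), substitution errors at 0.5% by default.
Depth is expressed in *genome equivalents* relative to a stated 1C
size, not the realized sequence length, mirroring how assumed genome
sizes are used with real data.

## k-mer repetitivity

`count_kmers()` counts canonical k-mers (lexicographic minimum of motif
and reverse complement; stranded mode retained for oracle tests);
windows containing non-ACGT characters are skipped. The cumulative
repetitivity curve is

$$C(f) = \frac{\sum_{m\,:\,n_m/GE \ge f} n_m}{\sum_m n_m},$$

the fraction of sequenced bases in motifs occurring at least $f$ times
per genome equivalent. The numerator is occurrence-weighted — a genome
fraction, not a count of distinct motifs — because the quantity of
interest is "what share of the genome lies in repeats this common".
$C$ is non-increasing in $f$ by construction, and doubling a family's
copy number shifts $C$ upward at the family-isolating threshold; both
are tested. Note that per-copy divergence individualizes a share of a
family's k-mers (a copy-private mutation creates motifs seen only at
the sequencing depth of one copy), so $C(10)$ at k = 16 sits somewhat
below the planted repeat fraction on diverged families.

## Read clustering

Edges of the read-overlap graph follow the criterion: an overlap
spanning at least 50% of the shorter read at at least 90% identity,
on either strand. Identity is matches over alignment columns within
the overlapping segment. Because the simulator is substitution-only,
the optimal overlap alignment is gap-free, and `find_overlaps()`
evaluates gap-free extensions along diagonals proposed by shared
14-mers (an exact-seed prefilter; abundant satellite seeds are
deterministically downsampled). Small instances are checked in the
test suite against two independent oracles: an exhaustive all-offset
alignment oracle and a Biostrings ends-free dynamic-programming
alignment with prohibitive gap penalties.

Clusters are connected components, refined in three deterministic
steps for large sparse components (density < 0.05, size > 100):

1. **Greedy modularity** (`igraph::cluster_fast_greedy`) splits
   components fused by "bridge" reads — at full coverage the entire
   genome becomes one component, because flanking single-copy regions
   tile into chains that touch every inserted repeat.
2. **Thick-seam merge-back**: two communities are re-merged when at
   least `max(50, 0.2 × smaller size)` edges cross between them.
   Plain modularity happily cuts genuine families along thick seams
   (the LTR/internal junction of a retroelement, one arc of a
   tandem-repeat ring); such seams carry hundreds of read overlaps,
   whereas the chance-adjacency bridges between a repeat and its
   flanks carry a handful.
3. **Peripheral pruning**: in clusters above 50 reads, members whose
   within-cluster degree is below `max(3, 0.05 × median degree)`
   return to the unclustered pool. A read straddling an insertion
   junction carries less than a qualifying overlap of family sequence;
   it can only attach through the few other reads of its own junction,
   and drags flanking single-copy reads with it. Family cores are
   orders of magnitude denser, so the median-scaled cut removes
   exactly this periphery. On the reference simulation this step
   reduces the systematic inflation of dispersed-element cluster
   proportions from about +1.5–2 points to under +1 point. (The
   original full-scale workflow sidesteps this regime entirely by
   clustering a ~3–8% read subset, i.e. far below 1× coverage, where
   junction reads almost never pair.)

Cluster ids rank by size (CL1 largest). Proportions use all reads
entered as denominator, singletons included — the table's summary
counters (clusters ≥ 0.01%, ≥ 1%, top-15 cumulative share) follow the
conventions of published repeat-composition tables. Mate pairs whose
reads land in different clusters define the first-order neighbour
graph; clusters without neighbours are flagged as probe-eligible.

## Consensus building

`build_consensus()` is a deterministic greedy overlap-layout-consensus:
seed at the read of highest overlap degree (ties by id), place the
rest along a maximum-weight spanning tree of the overlap graph, vote
per column (ties A<C<G<T). Two choices matter:

* Tree weights are `identity × (1 + |offset|)` — identity alone
  collapses a tandem array onto a single monomer window (offset-0
  stacks carry no layout information), whereas favouring extending
  overlaps lets the layout walk the array. For tandem clusters the
  placements are only defined up to monomer multiples; that ambiguity
  preserves the period, which is all downstream analysis needs.
* After voting, the consensus is trimmed to its longest well-supported
  run (support ≥ max of 10% of peak and half the median), and a
  consensus whose reverse complement matches more than half of itself
  — a layout that stitched an element copy head-to-head against a
  reverse-complement copy — is folded to its longer arm.

A related artifact motivates one annotation rule below: when an
element's terminal repeats are longer than the minimum qualifying
overlap (125 bp here), reads lying entirely within the LTR connect the
element's two ends and can rotate the consensus, scrambling linear
domain order. The bundled demonstration uses short (TRIM-like) LTRs;
for real data with kb-scale LTRs the domain-order call should be read
with this caveat (a known limitation).

## Cluster annotation

`scan_domains()` aligns each exemplar locally (Smith–Waterman via
Biostrings, match 2 / mismatch −3 / gap open 5 / extend 2) against the
consensus and its reverse complement; hits need ≥ 70% identity over
≥ 50% of the exemplar. `classify_superfamily()` is rule-based: RT, RH
and INT all present and ordered RT-RH-INT on the evidence strand call
Gypsy; INT-RT-RH calls Copia; rDNA exemplar hits call rDNA;
TRANSPOSASE without retro domains calls DNA_transposon; RT without INT
is a low-confidence LINE; strong tandem periodicity without domains
calls tandem/satellite; anything else is unclassified. The evidence
strand is the one carrying the majority of retro-domain hits; on a
tie, the call is accepted only if both strands independently yield the
same superfamily (the palindromic-consensus case), otherwise
unclassified. Duplicated domains with conflicting implied orders give
unclassified with a note, never an error.

`classify_shape()` quantifies the visual cluster-graph vocabulary with
ordered rules on graph metrics: a long chordless cycle (girth ≥ 8 of
the pendant-pruned 2-core) → circle; normalized diameter ≥ 0.5 → line;
hub dominance (max/mean degree) ≥ 5 → star; pendant mass ≥ 30% off a
dense core → ray; else amorphous (always, below 10 nodes). The
thresholds are calibrated on constructed graphs (rings, stars, paths),
which the tests pin down; at full 5× coverage real family subgraphs
are dense enough that most present as amorphous — the distinctive
shapes emerge at the sparse, low-coverage end of clustering. A thick
ring (tandem repeat much longer than a read at high coverage) has
girth 3 and is *not* detected as a circle; this is a known limitation
of the girth-based cycle test.

## Tandem structure

`detect_periodicity()` computes the lag-identity profile
$\mathrm{id}(\ell) = \#\{i: s_i = s_{i+\ell}\}/(L-\ell)$ — the
quantitative analogue of self-dotplot diagonal spacing (and the tests
check the two agree). The fundamental period is the smallest local
maximum with identity ≥ 0.70 (chosen so monomers diverged up to ~15%
still peak above threshold); a higher-order period is the smallest
larger lag at an integer multiple (±1 bp) of the fundamental with
identity ≥ 0.95, reported only when the fundamental itself stays below
0.95 (0.95 separates a homogeneous HOR unit from halves diverged by
≥ ~3%). A dimer array built from a 116 bp unit and an ~8%-diverged
partner — the divergence between the halves is not documented for the
motivating example, so 8% is an exposed parameter — yields fundamental
116 bp and HOR 232 bp across every tested seed. `max_lag` defaults to
2000 bp, covering the satellite monomer range; units as long as rDNA
are handled as rDNA, not satellites.

## Copy number and genome specificity

A read maps to a probe fragment when its best local alignment (either
strand) covers ≥ 50% of the read at ≥ 90% identity, counted once per
read. Copies per 1C are base-normalized by default:

$$\widehat{c} = \frac{\text{mapped reads} \times \text{read length}}
{\text{fragment length} \times \text{genome equivalents}},$$

with a raw reads-per-genome-equivalent mode also available, since
either reading of "reads per genome equivalent" is defensible. The
estimator is coverage-invariant in expectation (tested by averaging
replicate simulations, since a single run at desk-scale depth carries
~3–4% binomial sampling noise). Note the unit: the estimate counts
copies *of the fragment*, so a 600 bp slice of a 43 bp-monomer
satellite array reports array bases per 600 bp unit, while a fragment
inside a dispersed element reports element copy number directly.

`classify_specificity()` takes copies per subgenome sample: the
qualifying set is every subgenome with at least `alpha = 0.2` of the
maximum and at least `floor` copies (default 10; the bundled
demonstration sets 5, matching its much smaller copy-number scale —
its smallest genuinely planted family has 11 copies per subgenome and
background fragments map at 1–2). The set maps onto the configured
categories (each subgenome alone, A+D, all); a set matching no
category (e.g. C+D) is reported as its smallest configured superset
*with a warning flag* rather than forced, so unexpected combinations
stay observable; everything below the floor is an explicit
"undetected". Probe candidates come from clusters with few first-order
neighbours, as the best-supported consensus slice within 80–600 bp,
with a dinucleotide-entropy floor (1.5 bits) rejecting low-complexity
fragments.

## The reference simulation

`hexaploid_demo_config()` fixes the study conditions used throughout
the analysis scripts and the end-to-end tests: subgenomes A/C/D with
100 kb background each at 43% GC; satellites of 43 bp (C-specific, 400
copies), 150 bp (A-specific, 100 copies), 340 bp (D-specific, 40
copies) and 360 bp (A+D, 25+25 copies) monomers; a Gypsy-like element
(1100 bp, 110 bp LTRs, 25 copies per subgenome, all genomes) and a
Copia-like element (1000 bp, 60 bp LTRs, 11 copies per subgenome),
planting a genome-wide Gypsy:Copia base ratio of exactly 2.5:1 — the
same ratio scale reported for oat, where Gypsy elements are roughly
2.5× as abundant as Copia; per-copy divergence 2% (young, homogeneous
families); 5× coverage per subgenome sample. On this simulation the
pipeline recovers every family's genome proportion within ±2 points,
all four monomer lengths exactly, the Gypsy:Copia ratio within
[2.0, 3.0], all five specificity categories, and the 100-copy family's
copy number within ±10%.

## What the synthetic data does not emulate

Passing these tests shows the machinery is correct under the stated
model; real shotgun data additionally contain indels and structured
error profiles, nested and truncated insertions, solo LTRs,
organellar DNA (an exemplar-based exclusion list stands in for
chloroplast filtering), microsatellites below the k-mer range, PCR
duplicates, and far larger family inventories at far lower relative
coverage. The problem sizes here (hundreds of kb, thousands of reads)
were chosen so the whole validation runs on one CPU in minutes; they
are three to four orders of magnitude below a real oat read set, and
quantities that depend on genome scale (e.g. the share of clusters
above 0.01%) are not comparable to published values.
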