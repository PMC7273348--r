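---
title: "Reconstructing the evolution of the gibberellin operon from gene blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the evolution of the gibberellin operon from gene blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockevol)
```

## The problem

The bacterial gibberellin (GA) biosynthetic operon is a gene cluster of up
to eleven families — cyp115, cyp112, cyp114, fd, sdr, cyp117, ggps, cps, ks,
idi and the accessory ggps2 — that occurs in gammaproteobacterial plant
pathogens and, with much more variable gene content, in alphaproteobacterial
rhizobia. Its scattered distribution, elevated GC content relative to the
host chromosome, and conflicts between gene trees and species trees all
point to horizontal transfer, while the gains, losses and rearrangements
within rhizobia record the selective pressures of symbiosis. `blockevol`
implements the comparative-genomics side of that analysis as a reusable,
fully tested pipeline: ortholog and pseudogene classification, gene-block
assembly, an event-based block distance, maximum-parsimony ancestral
reconstruction under alternative phylogenies, phylogenetic-diversity taxon
reduction, and a sliding-window GC screen — together with a generative
simulator that makes every stage testable without downloading a single
genome.

Families are written as the single letters `a`–`k` (`a` = cyp115, `b` =
cyp112, …, `j` = idi, `k` = ggps2). The anchors `a` and `k` follow the
published figure legends; mapping `b`–`j` onto the remaining genes in operon
order is this package's convention and should not be read back onto other
software.

## Gene blocks and the neighbor rule

Two genes are *neighbors* when they lie on the same contig and strand with
at most 500 bp of intergenic distance; the boundary is inclusive (a 500-bp
gap still chains, a 501-bp gap splits). An *orthoblock* is a run of at least
two neighboring genes homologous to the reference operon. In the string
notation, neighboring genes are adjacent letters and a split is a `|`:
`"bcdefghi|j"` is the core operon with a distal idi. A `~` suffix marks a
pseudogene (`"a~bcdefghi"`). Coordinates are converted once, at parse time,
to 0-based half-open spans, so the gap between features is simply
`start2 - end1` everywhere downstream; this is the single place where the
1-based inclusive GFF3/GenBank convention is handled, which keeps the 500-bp
rule free of off-by-one ambiguity. The source material states the threshold
both as "500 or fewer" and as "less than 500"; we fix the inclusive reading
and expose the threshold as an argument.

Orthology calls follow three published rules, each of which sits on an
explicit boundary that the tests probe from both sides:

* a hit is an ortholog if its E-value is at most `1e-10` (inclusive);
* a cyp115 hit is a pseudogene (`p-cyp115`) if the subject is strictly
  shorter than 60% of the query and identity is strictly above 50%;
* a missing ferredoxin with a `d`-query hit covering at least half of the
  `d` gene inside a feature already called cyp114 or sdr is a
  `cyp114-fd` or `fd-sdr` fusion. The 0.50 coverage value is our choice
  (the description of the original screen is qualitative); it requires a
  majority of the ferredoxin to map inside the partner ORF.

The pseudogene rule is applied to cyp115 by default, matching the published
screen, and can be pointed at any family set; the synthetic pipeline screens
all families so that simulated truncations never leak into the
concatenated alignment. Length units for the 60% rule are whatever unit the
reference lengths are supplied in (nucleotides throughout this package);
query and subject must use the same unit.

## The event model

Differences between two blocks are counted in three categories:

* **deletions** — families present in exactly one block (gene gains are the
  same kind of unordered presence change and are counted in this category);
* **duplications** — the summed absolute copy-number difference over
  families present in both blocks;
* **splits** — the absolute difference in sub-block counts after each block
  is restricted to the families the pair shares (a sub-block containing
  only unshared families is invisible to the comparison).

The total is the event-based distance. Gene order inside a sub-block is
deliberately ignored — rearrangement is not one of the modelled event
types. Pseudogenes are excluded by default: a cyp115 fragment is annotation,
not a functional gene copy (`count_pseudo = TRUE` reverses this; the effect
on real cohorts is a per-block `!` flag rather than extra events).

Because the three formulas are simple, it is easy to mistake them for
obviously-minimal counts; they are not, and `oracle_distance()` exists to
guard exactly that. It runs a uniform-cost search over sequences of atomic
edits — delete a family (all copies at once), gain an absent family, add or
remove one copy, split or join sub-blocks — until the start block matches
the target's copy numbers and shared-restricted sub-block count. Three
constraints make the edit algebra agree with the component formulas, and
each was found by letting the search discover a cheaper path and deciding
which semantics the event model intends:

* a family deleted along a path is never regained (each presence difference
  is explained exactly once, so copy surpluses cannot be erased by a cheap
  delete-and-regain);
* a duplicated copy arises in tandem, in a sub-block that already holds the
  family (otherwise a duplication could smuggle in a segmentation change);
* removing a copy must leave its sub-block with at least one gene of a
  shared family (otherwise removal would hide a split).

The tests enumerate every pair of blocks over three families (at most two
copies and two sub-blocks — 6,216 pairs) plus randomized larger pairs and
require exact agreement.

## Ancestral reconstruction

Given a rooted tree and one block per leaf, `reconstruct_blocks()` assigns
a block to every internal node so that the edge-sum of event distances is
as small as possible. The search has three layers:

1. **Character decomposition.** Each family's copy number is a Sankoff
   character (states 0..max copies; cost 1 for a presence change, the copy
   difference otherwise), and the counted sub-block number is another
   (cost = absolute difference). These solve exactly in isolation and seed
   realistic ancestral states.
2. **Candidate realization.** Copy vectors and sub-block counts are
   realized as blocks in reference gene order, cut into near-equal
   contiguous sub-blocks, and pooled with the leaf blocks.
3. **Iterated pool DP.** A Sankoff pass over the candidate pool (edge costs
   are full event distances) is globally optimal *for that pool*; after
   each pass every internal node contributes its near-optimal local blocks
   (over the enumerable block space spanned by its current neighbors) to
   the pool, and the DP repeats until neither the total nor the pool
   improves.

The third layer exists because pure decomposition is measurably suboptimal:
deleting a family can absorb a segmentation change (the restriction in the
split term), so the best ancestral segment composition is sometimes not a
reference-order cut. `oracle_reconstruct()` — an exact dynamic program over
the *complete* state space of small instances — certifies the stack: the
acceptance suite requires the iterated DP to reach the exhaustive optimum
on randomized instances with up to six leaves and four families. On
cohort-scale data the pool stays modest (distinct observed blocks plus
realizations), which is what makes 100+ leaf reconstructions practical;
divergences from the true optimum there cannot be certified and the totals
should be read as parsimony upper bounds.

Ties are broken deterministically: prefer presence, then fewer copies, then
fewer sub-blocks, then reference order. The presence preference encodes the
reading that the ancestral operon was complete (e.g. that it carried idi);
the opposite convention can be emulated by reordering candidates, and on
the synthetic cohorts the choice moves single events between adjacent
edges, not the totals. Cumulative per-node triples (deletions,
duplications, splits below that node) are reported leaf-to-root, and gains
appear in the deletions column, mirroring the three-column bracket of the
published reconstructions.

`compare_trees()` runs the same leaf blocks under alternative rooted trees
and sorts by total. This is the computational core of the transfer
argument: if the operon moved horizontally, a tree built from the operon
itself explains the leaf blocks with fewer events than the species tree.
Parsimony totals under a symmetric edge cost do not depend on root
placement, so rooting both trees on the same designated outgroup only fixes
the reported node orientation, not the comparison.

## Trees, distances, taxon reduction

The species tree is built from a marker-gene alignment (rpoB in the study;
the simulator's marker plays that role), the operon tree from the
concatenation of the seven uniformly conserved families cyp112, cyp114, fd,
sdr, cyp117, cps, ks — in that fixed order, with genomes missing any of the
seven excluded and reported. Fusion ORFs are split at the ferredoxin hit
boundary so both constituent slots are filled.

Distances are uncorrected p-distances with pairwise gap deletion; the
original analysis names MUSCLE and neighbor joining but no distance
correction, and at the within-class divergences involved the correction
choice does not move topologies (the NJ acceptance check uses additive
matrices, where recovery is exact regardless). Agglomeration is the
standard Saitou–Nei algorithm via `ape::nj()`, with taxa pre-sorted for
determinism and negative branch lengths clamped to zero. Bootstrap support
resamples alignment columns, rebuilds NJ trees, and counts reference
bipartitions among replicates.

`pd_reduce()` mirrors the published reduction of 118 taxa to 64: greedy
phylogenetic-diversity maximization (start from the farthest pair, then
repeatedly add the leaf contributing the most new branch length), which is
provably optimal for PD on trees; the tests verify it against exhaustive
subset search on small trees. Mandatory keeps (reference, outgroup) are
supported because the published run kept both anchor taxa.

## GC screen

`window_gc()` slides a 500-bp window (any step; step 1 by default, the
window size itself for bar-style summaries — both aggregate to identical
region means, which a test asserts). `region_contrast()` compares the
operon span against 10-kb flanks and reports the difference in percentage
points, matching the "at least 7% higher" phrasing of the source; flanks
truncated by contig ends are flagged rather than silently shortened.
Ambiguous bases are excluded from numerator and denominator by default
(counting them toward the denominator is an option). `subregion_contrast()`
serves the within-operon comparisons, e.g. core operon versus a recently
recruited ggps2 several points below it.

## The simulator

`sim_config()` + `evolve_blocks()` + `emit_genomes()` generate
ground-truthed cohorts. Design choices, all of which are this package's own
(the source study is an inference study and specifies no generative model):

* **Tree prior** — Yule pure birth (`ape::rphylo`), the simplest prior that
  produces realistic unbalanced topologies with branch lengths.
* **Event process** — per branch, each event type arrives as a Poisson
  count with mean rate × branch length × root-block size, targets drawn
  uniformly from the extant block. Scaling by the *root* block size (rather
  than the shrinking current size) keeps the expected number of logged
  events exactly rate × total tree length × root genes, which the rate
  -recovery test exploits; at the sparse event counts used throughout, the
  difference from current-size scaling is negligible.
* **HGT** — whole-block replacement. Events are applied in global time
  order, so the recipient receives a copy of the donor lineage's block
  *and operon sequences* at the moment of transfer, chosen uniformly among
  lineages alive at that time. This is what couples the operon tree to the
  transfer history while the marker keeps tracking the species tree.
* **Pseudogenization** — marks one full-length gene; at emission the
  feature is truncated from the 3' end to a uniform 20–59% of its template,
  guaranteeing the <60% orthology rule fires on it.
* **Sequences** — per-family nucleotide templates drawn at the operon GC;
  substitutions are uniform per-site replacements with GC-biased base
  choice, so target GC is maintained without a rate matrix. Copies of a
  duplicated family share one sequence. There are no indels, so simulated
  sequences of one family are mutually aligned by construction and the
  pipeline needs no aligner.
* **Geometry** — intra-block gaps uniform on [50, 400] bp and split gaps on
  [600, 2000] bp, safely on either side of the 500-bp rule. Intra-block
  spacers are emitted at the *operon* GC — they are part of the mobile
  unit — while split gaps and flanks are host background; this is what
  makes a contiguous operon reproduce the configured GC offset exactly.
* **Event log** — every applied event is logged with enough detail
  (family, sub-block, position, HGT donor) that `replay_event_log()`
  reproduces every leaf block without touching the random stream; the
  replay identity over randomized configurations is a standing test.

What the simulator does *not* emulate — codon structure, indels, genome
rearrangement beyond splits, plasmids, annotation errors, composition drift
after transfer — bounds what green tests mean: they certify the inference
machinery against the model's own assumptions, not the annotation quality
or alignment steps of a real cohort, which enter through Prokka/BLAST/
MUSCLE files upstream of this package.

## Numerical and interface choices

* The internal homology-search adapter scores local alignments
  (`Biostrings::pairwiseAlignment`) and converts scores to E-values with
  ungapped Karlin–Altschul constants; adequate for thresholding synthetic
  data, and explicitly not a BLAST replacement — real cohorts should supply
  outfmt-6 tables via `read_hits()`.
* Best-hit ties break by E-value, then identity, then label order; calls
  are invariant to hit-table row order.
* The problem sizes used by the test and acceptance suites — cohorts of
  6–12 genomes, 500 replay configurations, 100 sparse-event recoveries, 50
  transfer scenarios, full 3-family distance enumeration — were chosen as
  the smallest sizes at which every property is exercised with comfortable
  statistical margins.
* The event-recovery check runs at ~1.5 expected events per cohort, the
  sparse end of the sparse-history regime: at ~3 expected events maximum
  parsimony already compresses the true history (two sister-lineage losses
  of one family explained by a single ancestral loss) in a sixth of runs —
  an inherent property of parsimony, so the recovery guarantee is stated
  for the regime where histories are mostly compression-free.
* The transfer-contrast cohorts use split-dominated variation (high
  rate_split, moderate rate_deletion): deletions tend to remove
  concatenation families and thereby drop exactly the genomes that would
  carry the incongruence signal out of the operon tree, while splits
  differentiate blocks and keep every genome in both trees.

## Known limitations

* The event distance is a fixed scoring convention, not a metric: the split
  term's restriction violates the triangle inequality in corner cases
  (documented in the tests), and the duplication term alone does too when a
  family is absent from the middle block. Deletions alone, and the full
  edit cost, behave metrically on the tested domain.
* Reconstruction totals on large cohorts are certified-optimal only within
  the candidate pool; the oracle bound applies to small instances.
* The GenBank reader handles plain and `complement()` ranges only — enough
  for simple annotated contigs, not compound joins.
* `concat_operon()` concatenates; it does not align. Real-data workflows
  must supply aligned sequences (the simulator's are aligned by
  construction).
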