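---
title: "Methods: models, rules and design choices in armcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in armcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

armcompare re-implements, as reusable and testable components, the kinds of
bespoke computation that chromosome-arm comparative studies in polyploid
crops typically run through one-off scripts: closing assembly N-gaps from
filler-sequence pools, classifying donor genes as retained, relocated or lost
in the polyploid, scanning ortholog pairs for selection with dN/dS and
codon-bias covariates, testing category enrichment of gene sets, dating LTR
retrotransposon insertions, and anchoring primer-pair markers and QTLs. This
vignette records the models behind each stage, the tunable parameters and
their defaults, and the design choices made where more than one reasonable
convention exists.

## The synthetic study

Real inputs to these analyses (a pseudomolecule, BAC and long-read pools,
curated gene sets) are large and access-controlled, so the package carries a
simulator that generates the complete input bundle **with truth tables**,
making every downstream stage testable end to end. `sim_config()` defines the
study conditions; its defaults are the package's standard scenario:

* a **5 Mb arm** with **200** single-exon ORF genes (100-400 codons,
  random strand) and **~40% LTR-retroelement coverage** (elements of
  1.5-5 kb internal domain flanked by two 300 bp LTRs, identical at
  insertion). The gene count and arm length give a gene density in the range
  seen on distal wheat-group chromosome arms while keeping a desk-scale
  problem; real wheat arms are closer to 80% repeat content, but since the
  simulator draws every element independently (no families), the TE fraction
  mainly sets how many datable elements exist, and 40% yields several hundred.
* a **derived arm** evolved from the ancestor: per gene, synonymous changes
  at rate 0.05 substitutions/site and nonsynonymous changes at omega times
  that, applied by rejection sampling over single-nucleotide codon changes
  (proposals creating stops, or touching the start/stop codon, are rejected).
  This makes the realized dN/dS auditable by direct counting, which is why
  rejection sampling was chosen over a rate-matrix exponential. Omega is
  drawn per gene from {0.2, 5} with weights {0.88, 0.12}, echoing the
  roughly one-in-eight share of positively selected genes that selection
  scans of domesticated-vs-donor gene pairs report.
* per-gene **fates**: each gene is lost with probability 0.05 and relocated
  with probability 0.05. Genes tagged as disease-resistance analogues (RGA,
  10% of genes) have their loss probability multiplied by 3, emulating the
  preferential loss of resistance genes that motivates the enrichment test.
  Relocated genes are placed in a decoy "homoeologue" set standing in for
  the sister subgenomes; lost and relocated loci are overwritten with random
  sequence so arm coordinates stay fixed.
* **100 N-gaps** of 100-800 bp (mean ≈ 450 bp, matching the mean gap size
  of published gap censuses) planted by overwriting the true sequence —
  never inside a gene CDS, never within one tile length of each other. The
  true fill of every gap is recorded.
* **three filler pools** (`unmapped`, `singleton_bac`, `longread`, priority
  in that order) built by tiling the true genome with 5 kb tiles at 2 kb
  overlap plus one tile centred on each gap. Tiles spanning a gap go to the
  pool its fill was assigned to (5/40/55%), so per-source accounting is
  disjoint by construction; tiles spanning a *withheld* gap (a configurable
  fraction, default 0) are dropped to exercise the rejection paths. Tiles
  are stored reverse-complemented with probability 0.5, and can be
  substituted at a configurable error rate (default 0: the study condition
  is error-free pools).
* **LTR divergence**: each element draws a true divergence K from an
  exponential with mean 0.0065 substitutions/site — the value that, at the
  conventional grass substitution rate r = 1.3e-8 /site/year, corresponds to
  the ~0.25 MYA insertion-age mode reported for recent wheat LTR cohorts.
  Each LTR copy independently receives Poisson(K/2 x length) substitution
  events.
* **20 primer-pair markers** of 20 bp copied from loci verified unique
  genome-wide (exact-match count of 1 on both strands), with recorded
  positions and product lengths (150-600 bp).

Everything is reproducible bit for bit from `(config, seed)`; stage streams
are fanned out deterministically from the root seed. What the simulator does
**not** model — TE family structure, indels inside genes, segmental
duplication, sequencing error in the assembly itself — bounds what passing
tests show: recovery rates here certify the *logic* of each stage under
clean, fully-known inputs, not performance on noisy real data.

## Gap closure

Following the standard flank-alignment protocol, `close_gaps()` cuts
**1500 bp** of flanking sequence on each side of every N-run (truncated at
sequence ends and neighbouring gaps so flanks never contain N) and aligns
both flanks to each filler pool in priority order. A closure is accepted iff
some filler carries a hit of each flank on one strand with:

* the gap-adjacent end of each alignment within `anchor_tol = 10` bp of the
  flank's gap-adjacent end,
* the correct mutual order on the filler for that strand,
* an implied patch length within `[-200, 20000]` bp, and
* an N-free patch (the filler subsequence between the projected inner
  boundaries, reverse-complemented for minus-strand support).

Flank hits must reach identity ≥ 0.95 over ≥ 200 aligned columns. These
four thresholds are declared defaults — the protocol this mirrors publishes
none — and all sit in `closure_rules()`. Negative implied lengths (flanks
overlapping on the filler) become `merged_overlap` events: the N-run is
deleted and the recorded overlap is trimmed from the right flank, the usual
scaffold-merge semantics. Evidence from a single flank never closes a gap,
and a gap closed by an earlier pool is not re-attempted, keeping per-source
counts disjoint. Patches are applied right-to-left so stored coordinates
remain valid, and a liftover table maps every surviving original position to
the patched sequence.

The closure summary reports, per source, the count, the total and mean
**original gap length** replaced (halves rounded away from zero, as
published gap-census tables do), with total patch length as an extra column:
mean original gap length is the quantity comparable against a gap census,
while patch length is what the assembly actually gained.

## The internal aligner

All sequence search (flank placement, orthology) runs through one
seed-and-extend local aligner: a k-mer index (k = 15 by default) over the
targets with a deterministic repeat cap — seeds occurring more than 100
times are dropped, replacing soft-masking — and affine-gap local
Smith-Waterman extension with match +1, mismatch -1, gap open -2, gap
extend -1 (the first base of a gap costs 3). Seeds are clustered by diagonal
per target, and the DP is run exhaustively over the rectangle the cluster
implies (the whole target when it is ≤ 1 kb); this is slightly more work
than a banded x-drop extension but guarantees that, whenever a seed exists,
the reported score *is* the local-DP optimum under this scoring scheme —
which is exactly what the test suite asserts against an independent
quadratic DP oracle. Overlapping hits on one (target, strand) within 10 bp
are merged keeping the higher score: flank placement needs one best local
anchor per filler, not an HSP enumeration. Minus-strand hits are computed on
the reverse-complemented query but always reported in forward-strand
coordinates of both sequences.

## Orthology and the loss cascade

`reciprocal_best_hits()` searches CDS against CDS (nucleotide) in both
directions, keeps hits with identity ≥ 0.70 and query coverage ≥ 0.50, and
pairs mutual best hits; ties for best between different targets flag the
pair ambiguous, and ambiguous pairs are excluded from the downstream
selection scan, where a wrong pairing would inject noise into omega.
Nucleotide search (rather than protein) keeps a single aligner for the whole
package and is adequate at the simulated 5% divergence; at real
wheat-vs-donor divergence it is still comfortable, but the package should
not be pushed to cross-genus comparisons without a protein-capable search —
a documented limitation.

`classify_absent_genes()` then applies the cascade used in donor-vs-polyploid
gene-loss accounting: a donor gene with an RBH partner on the focal arm is an
`ortholog_on_focal_arm`; otherwise any passing (non-reciprocal) hit in a
homoeologue set makes it `homoeologue`; otherwise any hit in the remaining
genome sets makes it `paralog_elsewhere`; otherwise it is `lost`. The
presence thresholds for steps 2-3 equal the RBH thresholds, another declared
default. The four classes partition the donor set by construction, so counts
always sum to the donor-gene total. `loss_density_profile()` bins lost genes
along the arm with an orientation flag, since loss density is convention-
ally read centromere to telomere.

## Selection scan

`ng86_dnds()` implements the Nei-Gojobori (1986) counting estimator:
per-codon synonymous site fractions averaged over both sequences; for codons
differing at more than one position, the synonymous/nonsynonymous split of
the differences is averaged uniformly over all shortest substitution
pathways, discarding pathways through stop codons; Jukes-Cantor correction
d = -(3/4) ln(1 - 4p/3); omega = dN/dS, undefined when dS = 0 (such pairs
are excluded from PSG/NSG counts rather than forced into a class). Two
conventions are fixed deliberately: mutations *to* stop codons count as
nonsynonymous in site counting, which keeps S + N = 3 x codons exactly; and
saturation (p ≥ 3/4) is an error, not an NA, because a saturated pair
should never silently enter a selection scan. A counting estimator was
chosen over an ML one because the omega > 1 / omega < 1 classification is
estimator-agnostic at these divergences and counting admits an exact
brute-force oracle (pathway enumeration), which the tests exploit; this is a
method substitution relative to ML-based pipelines and is visible to users
in the documentation.

Codon-bias covariates come from `codon_metrics()`: Wright's effective number
of codons with the homozygosity estimator F = (n Σp² - 1)/(n - 1) per amino
acid (n ≥ 2), class means over the degeneracy classes of the standard code
(2 one-codon, 9 twofold, 1 threefold, 5 fourfold, 3 sixfold), the threefold
class imputed as the 2-/4-fold average and any other missing class from the
mean of available class means, capped to [20, 61]; and CAI as the geometric
mean of relative adaptiveness over non-Met/Trp codons, with weights built
from a reference set by `cai_reference_weights()` (zero-count codons floored
at 0.01 so the geometric mean stays defined). `feature_correlation()` gives
the Spearman matrix with average-rank ties and two-sided p from the
t approximation; constant features are reported missing rather than zero.

## Enrichment statistics

`fisher_exact_2x2()` conditions on both margins and sums hypergeometric
point probabilities ≤ that of the observed table (the most common two-sided
convention), evaluated in log space with a 1e-7 relative guard against
floating-point ties; a zero margin returns p = 1 with a warning.
`subset_table()` encodes the construction used for published lost-gene RGA
tables: the foreground is removed from the background before the 2x2 table
is formed, `(k, n-k, K-k, N-n-(K-k))`. This construction reproduces the
published p = 0.000004 for the 12/53 vs 138/2917 RGA table, whereas the
disjoint-rows reading gives ≈ 8e-6 — which is why it was adopted.
`category_enrichment()` runs one test per category with a foreground hit and
adjusts with Benjamini-Hochberg.

## LTR dating

Paired LTRs are identical at insertion, so their divergence dates it:
`ltr_divergence()` drops gap/N columns, computes the mismatch proportion p
and the Jukes-Cantor correction K, and `insertion_time()` applies
T = K/(2r) with r defaulting to the conventional grass rate 1.3e-8
substitutions/site/year (overridable — T scales inversely with r, so the
rate choice is the dominant systematic). Inter-LTR divergence is used rather
than LTR-versus-family-consensus: it is the standard insertion-dating
practice, needs no family model, and the raw p is exposed alongside K for
users who prefer other corrections.

## Markers and QTLs

`epcr_place()` is an electronic-PCR matcher: the forward primer may match
either strand with ≤ 1 mismatch by default but must match its 3'-terminal
3 bases exactly (polymerase extension is 3'-intolerant); the reverse
primer's reverse complement must match downstream on the same molecule under
the same rule; an optional product-size window filters amplicons. QTLs are
anchored to the span of their placed flanking markers' product midpoints
(single-marker QTLs become point intervals padded by 1 Mb), and genes link
to a QTL when their midpoint falls within the anchored interval expanded by
a window defaulting to 3 Mb — the size of the marker-flanked region in the
worked example this mirrors; both radii are parameters, since "closely
linked" has no universal definition.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere in memory; GFF3 is written
  1-based inclusive, BED 0-based half-open.
* IUPAC ambiguity codes on input become N with a logged count — real
  assemblies contain them and an error would be hostile.
* Terminal N-runs are catalogued as genuine gaps but refused for closure
  ("terminal"), having only one flank.
* Census-style means round halves away from zero (`round_half_away`),
  matching how published tables print; base R's banker's rounding would
  differ on exact halves.
* Aligner tie-breaks are total: score descending, then target id, then
  target start — outputs are byte-stable across runs.
* The codon evolver refuses to touch start and stop codons, so every
  derived CDS remains a valid ORF and equal-length codon alignment is
  trivial; real indel-containing pairs must be pre-aligned (gap codons
  stripped, with a logged count) before `ng86_dnds()`.

## Problem sizes used by the test and acceptance runs

Module tests run on 150-300 kb arms (8-25 genes, 5-12 gaps); the
acceptance suite and `scripts/acceptance.R` run the full default study
(5 Mb, 200 genes, 100 gaps, three pools) once, plus 50 aligner-oracle
instances, 500 NG86-oracle pairs, 100 neutral replicates of 500 codons, 200
enumerated Fisher tables with 20 Monte-Carlo comparisons at 1e5 draws, a
100-element LTR cohort and a 500-element exponential cohort. These sizes
give stable recovery statistics (binomial SEs of a few percent or less)
while keeping a complete run in minutes on one core.

## Known limitations

* The aligner is nucleotide-only and ungapped-seed based; highly diverged
  (> ~15%) or heavily rearranged pairs will lose seeds before the DP can
  rescue them.
* The loss cascade trusts presence/absence of alignment hits; it cannot
  distinguish a genuinely lost gene from one hidden in an unassembled region
  of the focal genome — on real data the `lost` class is an upper bound.
* NG86 underestimates dN/dS when substitution rates vary strongly among
  sites; the PSG/NSG split at omega = 1 is robust to this at moderate
  divergence but borderline genes (omega near 1) should be re-examined with
  an ML model.
* The enrichment engine ships no annotation databases; users supply the
  gene-to-category table, and the statistics inherit whatever biases that
  annotation carries.
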