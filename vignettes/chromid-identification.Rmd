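---
title: "Identifying chromids among bacterial replicons: models, parameters and design"
author: "chromidFinder maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying chromids among bacterial replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromidFinder)
```

## The problem

Many bacteria carry their genome on more than one replicon. Besides the
chromosome and ordinary plasmids, a third class exists: **chromids** —
secondary replicons that replicate and segregate with plasmid-type
machinery (Rep and Par systems) yet carry genes that are part of the core
genome in related species, and whose nucleotide composition closely
matches the host chromosome. Telling a chromid apart from a large plasmid
matters because chromids are quasi-essential and evolve with the
chromosome, while megaplasmids are dispensable cargo.

`chromidFinder` implements two decision procedures over this definition:

1. **Complete-genome screen** (`classifyCompleteGenome()`): for an
   assembled genome with two or more replicons, the longest replicon is
   the chromosome; a secondary replicon is a chromid when its GC content
   is within 1 percentage point of the chromosome's **and** it carries
   replication (Rep), partitioning (Par) and core-gene markers.
2. **Pooled (MAG) pipeline** (`runChromidFinder()`): for pools of
   independent sequences whose genome of origin is unknown, four steps —
   (i) GC content, gene prediction and marker scanning with a retention
   filter, (ii–iii) clustering around DnaA-bearing sequences (DnaA-dependent
   replication initiation marks bona fide chromosomes; members must be
   strictly shorter than the center and within the GC band and pass the
   marker rule), (iv) a tetranucleotide relative-abundance distance filter
   against the cluster center. Centers are called `CHROMOSOME`, passing
   members `CHROMID`, everything else `OTHER`.

## The compositional signature and its distance

The genomic signature of a sequence is its vector of k-mer **relative
abundances**. With strand-symmetrized frequencies $f^\*$ (counts
accumulated from the sequence and its reverse complement), each word
$w = x_1\ldots x_k$ gets

$$\rho(w) \;=\; \frac{f^\*(w)}{f^\*(x_1)\cdots f^\*(x_k)},$$

the zero-order (mononucleotide-normalized) form: $\rho \approx 1$
everywhere for a sequence with no structure beyond base composition, and
its departures from 1 are stable within a genome and distinctive between
genomes. The distance between two sequences is the mean absolute
difference scaled by a configurable factor:

$$d(f,g) \;=\; \frac{s}{4^k}\sum_w \big|\rho_f(w)-\rho_g(w)\big|.$$

**Scale and thresholds.** The working thresholds in the field are quoted
as $<1.6$ for tetranucleotide clustering and $\le 0.4$ for the
dinucleotide pre-screen, but the scale on which those numbers live is a
convention, not a law of nature. We therefore expose the scale as
configuration, default $s = 10$ on the mean absolute difference, and
always report the threshold and scale together in the run metadata
(`*.params.tsv` from the CLI). On this scale, independent 50 kb–1 Mb
samples from one compositional model sit well below 1.6, and a 5-point GC
shift sits well above it, which is the regime the thresholds are meant to
separate. Sweeping the threshold (`thresholdSweep()`) only re-applies step
(iv), so sensitivity analyses are cheap.

Windows overlapping an ambiguous base are **dropped, not imputed**:
MAG-derived sequences are gappy, and imputation would bias the ratios.
Every IUPAC code other than N is normalized to N on input so the word
alphabet stays at four letters. Because frequencies are symmetrized,
`signatureDistance(s, reverseComplement(s))` is exactly zero.

## Comparison rules and tie-breaks

* The GC band is **absolute**: $|\Delta GC| \le 1.0$ percentage point
  (60.0% vs 61.0% passes; 60.0% vs 61.01% fails).
* The tetranucleotide comparison is **strict** (`distance < 1.6`), the
  dinucleotide pre-screen inclusive (`distance <= 0.4`). At a threshold of
  0 the strict rule admits nothing — 0 and `Inf` are accepted as
  boundary sentinels.
* Cluster membership requires **strictly** shorter than the center; an
  equal-length candidate is excluded.
* Longest-replicon ties in the complete-genome screen break by DnaA
  presence, then lexicographic id, with a warning.
* A DnaA-bearing sequence is always a center and never callable as
  `CHROMID`.
* A replicon may be a member of several clusters; it yields one `CHROMID`
  call whose evidence lists every supporting center, with the
  smallest-distance center reported as primary.

**Marker rules.** The chromid definition requires Rep, Par and core genes
(`strict`, the complete-genome default). MAG-derived sequences are often
incomplete, so the pooled pipeline defaults to `relaxed`: (Rep **or**
Par) **and** core. Keeping the core-gene requirement in both preserves the
essentiality component of the definition; both rules are selectable
everywhere.

**Step-1 retention.** The pooled pipeline discards replicons with no
predicted gene or no marker hit of any category before clustering. The
exact criteria are an interpretation (the workflow we follow states only
that sequences must "meet specific criteria"); both counts are exposed as
arguments (`minGenes`, `minHits`) and every discard is recorded in the
evidence column of the calls table.

## Marker scanning

Marker detection is backend-pluggable behind one contract
(`scanMarkers()`): the `"hmm"` backend runs HMMER's `hmmsearch` over
user-supplied HMMER3 profiles; the `"motif"` backend declares a hit when a
literal amino-acid motif occurs in a protein, and is what the synthetic
fixtures use. Category identity (REP / PAR / CORE / DNAA) always comes
from the manifest, never from a marker's name, and DnaA models never count
toward the core category. Counts are **distinct-marker** counts — the
screening rules are presence/absence rules, so five hits to one core model
still give `n_core = 1`. The default E-value cutoff is $10^{-5}$
(conventional `hmmsearch` practice; the motif backend's exact matches
report 0).

Gene prediction likewise has two backends: Prodigal (`"prodigal"`), and a
built-in ORF finder (`"naive"`) reporting per reading frame, on both
strands, the longest ORF (first start codon after each stop) of at least
30 codons. The naive backend exists so that the whole pipeline, including
tests, runs without external binaries and deterministically; it
over-predicts relative to a statistical gene finder, which is harmless
here because marker scanning is what confers meaning on a gene.

## What the synthetic generator emulates

`generateAssembly()` draws each replicon from an order-0 or order-1
Markov model parameterized by a target GC, with a fixed
transition-preference structure (mild CpG/TpA suppression, the common
prokaryotic pattern) shared by all replicons of an assembly:

* the **chromosome** (default 500 kb, 60% GC) carries a planted DnaA gene
  and a core gene;
* each **chromid** (default 150 kb) is drawn from the *same* fitted model
  with the GC target nudged by +0.3 percentage points and carries Rep,
  Par and two core genes. Reusing the model is deliberate: compositional
  kinship between chromid and chromosome is a signature property, not
  merely a GC property, and an independently fitted model at matched GC
  would not reproduce it;
* each **plasmid** (default 40 kb) is drawn at a GC diverged by +5
  percentage points and carries Rep and Par but no core gene — a
  megaplasmid-like negative failing both the GC band and the marker rule.
  Two alternative failure modes are selectable: `"no_markers"` (matched
  GC, nothing planted) and `"marker_bearing"` (Rep+Par+core planted so
  that composition is the *only* separator; used to probe false-positive
  behavior as the GC offset varies).

Planted genes are valid ORFs (start codon, ≥30 codons, stop codon,
one fixed codon per residue) so both gene-caller backends can find them,
and are placed at jittered positions on alternating strands.
`generateBenchmark(n, params, seed)` derives per-assembly seeds as
`seed + index`, pools all replicons and strips the genome grouping — the
same "remove the correspondence" treatment used to evaluate pooled
screening. Everything is deterministic given the seed: uniform deviates
are drawn from R's RNG and fed to a small C++ chain sampler.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: realistic gene density and operon structure,
mobile elements, rearrangements, horizontal transfer, sequencing error,
within-replicon compositional heterogeneity (islands), and real marker
sequence divergence (the toy motifs are exact). Recovery rates on this
benchmark characterize the decision rules under the stated noise model,
not expected field performance on MAGs.

## Evaluation

`chromidConfusion()` scores calls against truth with CHROMID as the
positive class (UNASSIGNED counts as a negative prediction), and the four
metrics follow the standard formulas — accuracy $(TP+TN)/(P+N)$,
precision $TP/(TP+FP)$, TPR $TP/(TP+FN)$, FPR $FP/(FP+TN)$ — reported as
percentages rounded **half-up** to two decimals, matching the reporting
style of published screens (e.g. a 33/0/12/111 matrix gives 92.31 / 100 /
73.33 / 0). Zero denominators yield a flagged `NaN` with a warning rather
than an error. `thresholdSweep()` emits one ROC/PR point per grid value
and `aucTrapezoid()` integrates them; no external AUC value is asserted
anywhere.

## Problem sizes used in the tests

Unit tests run the pipeline on reduced replicons (60 kb chromosome, 25 kb
chromid, 12 kb plasmid) — large enough for stable signatures, small
enough to iterate quickly. The end-to-end acceptance checks use the
generator's default study conditions: 50 assemblies, 150 pooled
replicons, base seed 11. At those conditions the pipeline recovers the
planted labels essentially perfectly (recall ≥ 0.90 and FPR ≤ 0.05 are
the package's acceptance bar; the observed values on the seeded benchmark
are 100% and 0%). Oracle-equivalence tests compare the signature distance
against an independently written brute-force enumeration to 12 decimal
places.

## Known limitations

* The relative-abundance normalization is zero-order; higher-order Markov
  normalizations and codon-usage signatures are out of scope.
* The native scale of the published 1.6 / 0.4 thresholds is not
  derivable from their sources; our defaults make them meaningful on the
  ×10 mean-absolute-difference scale, but users comparing against other
  implementations must check the scale first.
* The marker databases are consumed, not built: curating Rep/Par/core/DnaA
  profile HMMs is the user's responsibility (only the toy motif fixture
  ships).
* Megaplasmid sub-classification, taxonomy assignment and gbff parsing
  are non-goals; multi-chromosome genomes yield one cluster per
  DnaA-bearing sequence, which is the behavior of the underlying method,
  not a bug.
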