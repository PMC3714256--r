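---
title: "txwb: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txwb: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txwb)
```

txwb is a scriptable workbench for de novo transcriptome projects —
organisms without a reference genome, where the unit of analysis is an
assembled transcript (or a protein, for proteomics abundance data) with
per-library read counts. This vignette explains the models and rules the
package implements, the parameters that matter, and the design choices made
where more than one reasonable convention exists.

## Expression statistics

**RPKM.** Reads Per Kilobase of transcript per Million mapped reads:

$$\mathrm{RPKM} = \frac{10^9 \, c}{N \, L}$$

with raw count $c$, library total $N$ and transcript length $L$ in
nucleotides. Replicates are summed into their library before
normalisation, mirroring how replicate columns are displayed. $N$ is taken
as the per-library grand total of reads *assigned to the project's
transcripts* (rather than the total sequenced), because that is the only
total the input count files define. A direct consequence used as a
self-check is mass conservation: $\sum_s \mathrm{RPKM}(s, i)\, L_s = 10^9$
in every library $i$, which the test suite asserts to a relative $10^{-6}$.

**R statistic.** A light-weight heterogeneity score for one transcript's
counts $x_i$ across libraries with totals $N_i$, testing proportionality
under a Poisson model:

$$R = \sum_i x_i \ln\!\frac{x_i}{N_i f}, \qquad
  f = \frac{\sum_i x_i}{\sum_i N_i},$$

with the convention $0 \ln 0 = 0$ and natural logarithms (R is reported in
nats). $R = 0$ exactly when all $x_i / N_i$ are equal; larger values mean
more library-specific expression. It is not a calibrated p-value — its role
is cheap whole-group ranking before a proper DE analysis — but under an
equal-rate Poisson null the fraction of transcripts with $R > 8$ stays
small (about 0.1–0.3% in the package's null simulations), which the suite
regression-tests. DE p-values themselves are never computed here: they are
*imported* as named columns from external tools and become queryable and
removable units of the project.

**Fold change** between two libraries is
$\log_2\!\big((a + p)/(b + p)\big)$ on RPKM values with a pseudo-count $p$
(default 0.1 RPKM) so zero counts stay finite; $a = b$ gives exactly 0.

**Co-expression export** computes the Pearson correlation of RPKM profiles
(optionally $\log_2(\mathrm{RPKM}+1)$) across the selected libraries. Pairs
with fewer than three mutually finite points, or involving a zero-variance
profile, are reported as missing rather than fabricated; the diagonal is 1.

## SNP calling

A pileup column with depth $n$ and $k$ reads confirming a non-consensus
base is scored with the exact upper-tail binomial probability
$P(X \ge k)$, $X \sim \mathrm{Binomial}(n, e)$, where $e$ is the estimated
base-call error rate. The upper tail is the only direction under which the
null hypothesis is "the non-consensus reads are sequencing errors". The
test is applied per variant base (not to the pooled non-consensus count),
so two true alleles at one position can both be called. Defaults:
$e = 0.01$, call threshold $\alpha = 10^{-3}$, at least 2 confirming
reads. No multiple-testing correction is applied; the raw p-value and
depth are stored so users can filter at whatever stringency their design
needs. At these defaults a depth-30 column needs $k \ge 4$ to be called,
which keeps error-only columns quiet while a true variant at allele
fraction 0.5 is essentially never missed.

## GC, ORFs and translation

GC content is $(G + C)/(A + C + G + T)$; ambiguity codes (including N) are
excluded from numerator and denominator so N-runs do not drag GC toward
any particular value, and an all-N sequence yields NaN rather than an
error. Coordinates everywhere are 0-based half-open on the forward strand.

The ORF finder scans all six frames for ATG→stop spans, stop codon
included; a span still open at the sequence end is reported with
`has_stop = FALSE` and trimmed to whole codons, because transcript
fragments commonly truncate real ORFs. Ties in length are broken by frame
(+1, +2, +3, −1, −2, −3) then start position, making the ordering total and
deterministic. A `require_start = FALSE` mode reports each inter-stop
region whether or not it begins with ATG; the multi-project merge uses
this mode with a 90 nt minimum to extract a coding sequence from every
transcript (a deliberate, desk-scale stand-in for a trained
coding-prediction model: 5'-truncated fragments would otherwise lose their
ORF entirely). Translation uses the standard genetic code; fuzzy codons
containing ambiguity codes translate to X when unresolvable.

## Pairwise alignment

The hit viewer and cluster member comparison use a semi-global
dynamic-programming alignment with affine gaps (Gotoh recursion, compiled).
End gaps at the *longer* sequence's ends are free, so a short hit region
may sit anywhere inside a transcript without penalty; equal-length inputs
align globally. A gap run of length $k$ costs
$\mathrm{open} + (k-1)\,\mathrm{extend}$ with defaults open = 4,
extend = 1; nucleotide mode scores match/mismatch +1/−1.5 and protein mode
uses a substitution matrix (BLOSUM62 by default, any square matrix with a
residue alphabet accepted). Identity is the percentage of matching columns
between the first and last aligned residue pair (terminal overhangs
excluded). These parameters are explicit package choices — published
descriptions of such viewers rarely state them — and they are configurable
per call. Correctness is checked against an independent exhaustive
enumerator that scores every alignment path directly; the two agree on all
sampled string pairs up to length 8.

## Annotation

BLAST tabular (12-column) files are the only hit format; both legacy and
current BLAST emit it. Reverse-strand HSPs are normalised to forward
coordinates with the strand recorded. Subject ids following the UniProt
`sp|ACC|NAME` / `tr|ACC|NAME` convention are classified Swiss-Prot/TrEMBL;
anything else takes the user's database tag (e.g. a transcription-factor
database tagged "TF"). Descriptions, organisms and GO/KEGG/Pfam/EC cross
references come from UniProt-dialect flat files (`ID`/`AC`/`DE`/`OS`/`DR`
records ended by `//`).

The **best hit** for a sequence is the minimum e-value hit with a total
tie-break order: higher bit score, then Swiss-Prot before TrEMBL before
other databases, then hit id — so the choice is invariant under input
permutation. The **best annotation** applies the same order restricted to
hits whose description contains none of a configurable uninformative
phrase list (default: "uncharacterized protein", "predicted protein",
"hypothetical protein", "unknown", "putative uncharacterized" —
case-insensitive); a sequence whose every description is uninformative has
a best hit but no best annotation.

**GO levels.** The ontology is read from OBO; only `is_a` edges
contribute. A term's level is one plus the shortest `is_a` path to its
namespace root (roots are level 1). Level is an approximate concept — the
ontology is a DAG, not a tree — which is exactly why the shortest-path
convention is stated explicitly and checked against an independent
graph-distance oracle. Obsolete terms are dropped; a cycle is an error.
Sequences receive the union of their hits' GO terms, each carrying the
best contributing e-value; GO queries count direct annotations by default,
with ancestor propagation available behind an explicit flag.

## Multi-project comparison

Merged sequence ids are `dataset|seq_id` (the orthoMCL groups convention),
so provenance survives every downstream step. Similarity pairs come from a
self-BLAST of the merged set: self-hits are dropped, the best HSP per
unordered pair is kept (maximum bit score), **percent overlap** is the
alignment length over the *shorter* sequence's length, and **similarity**
is BLAST percent identity — two terms that needed pinning down, since
usage varies.

**Redundancy filtering** removes near-identical sequences *within* a
dataset only (cross-dataset near-twins are the object of study, not
noise): pairs exceeding both thresholds are visited in decreasing
identity, and where both members survive, the shorter one is removed
(ties: the lexicographically later id). The result provably contains no
surviving same-dataset pair above both thresholds.

**Transitive-closure clustering** takes the connected components of the
graph whose edges are pairs passing the identity and overlap thresholds
(default 80/80), via union-find. Singletons are materialised as one-member
clusters so every sequence belongs to exactly one cluster of a method and
composition queries are total. Because the literature describes this
closure both in e-value terms and in identity/overlap terms, an optional
maximum-e-value edge filter is exposed (off by default) alongside the two
percentage thresholds. Cluster ids are `<prefix>_<7-digit ordinal>` with
the prefix encoding method and threshold (e.g. `TC80_0000001`), numbered
by decreasing size then smallest member — purely cosmetic, but fixed so
rebuilds are reproducible. External cluster sets (orthoMCL groups lines or
`cluster<TAB>member` files, auto-detected) import under
`imported:<name>`; clustering methods coexist side by side.

Each cluster is assigned the hit id that hits the most distinct members
(ties: best e-value among the tied hits, then lexicographic), together
with the percentage of members carrying it and its best e-value in the
cluster.

## The project store

A project is a set of relational tables — sequences, libraries, counts,
expression values, p-value columns, hits, cross-references, the GO graph,
SNP calls, pairs, clusters, remarks, and a build log — held in one
environment and serialised as a directory of plain TSV files. A plain-text
store was chosen deliberately: it is zero-install, diffable, copyable, and
ample at the scale of a desk project. Builds run stage by stage from a
declarative `key = value` config (sections mirror the loader's panels);
a failing stage aborts naming itself and leaves earlier stages' results in
place. Rebuilding from the same inputs gives identical query results,
which the suite checks over a battery of canned queries. Queries never
mutate the store. Filter semantics are a conjunction of all set facets;
the p-value facet takes an explicit all/any mode whenever more than one
column is listed, and every facet is validated against a row-by-row
full-scan oracle on randomised filter specifications.

## The fixture generators

Every input format the workbench reads can be generated synthetically with
a ground-truth manifest, so the whole pipeline is testable offline and
recovery experiments are scorable without re-reading generator code. All
generators are byte-deterministic in their seed.

What they emulate, and the defaults that define the test conditions:

* **Transcriptomes**: uniform-random sequences (length 300–1200 nt,
  per-sequence GC 0.35–0.65) plus substitution-mutated copies forming
  known homology groups. Substitution-only mutation keeps the realised
  identity exactly computable column-wise, at the price of never testing
  indel tolerance through the fixtures (the aligner's gap handling is
  tested directly against the exhaustive oracle instead).
* **Counts**: negative-binomial replicate noise around log-uniform
  baseline means (20–500), dispersion 0.1 — a biological coefficient of
  variation near 0.32, the value typically quoted for biological
  replicates in the RNA-seq DE literature; dispersion 0 gives the Poisson
  limit used for null calibration of the R statistic. The default library
  shape is six libraries, the first four with five replicates and two
  single-replicate, matching a typical multi-tissue design. Planted DE
  transcripts get an 8-fold rate increase in one designated library.
* **Self-BLAST and annotation hits**: HSP lines whose identities are the
  exact planted identities; a synthetic Swiss-Prot/TrEMBL universe with
  controlled e-values, where every tenth sequence's best hit is planted to
  carry an uninformative description (exercising the best-annotation
  rule).
* **Flat files and ontology**: one record per synthetic hit with GO, KEGG,
  Pfam and EC cross references; a 50-term single-namespace ontology built
  level by level (so true levels are known by construction) including a
  diamond, the case where shortest-path levels and naive depth differ.
* **Pileups**: fixed-rate planted variants at allele fraction ~0.5 over
  Poisson(30) depth with uniform miscalls at the error rate.

What the fixtures do **not** emulate — and hence what passing tests do not
show about real data: indels and assembly chimeras, GC- or lane-dependent
count bias, positionally correlated sequencing errors, paralog families
with graded similarity, and real UniProt/GO scale. The fixtures validate
the *mechanics* (formulas, rules, round-trips, recovery under stated
noise), not biological performance.

## Problem sizes and numerical choices

The shipped verification runs use sizes chosen to finish in minutes on one
core while still exercising every code path: the statistics oracles sweep
all $(k, n \le 25)$ binomial cases at three error rates and 10,000 random
R-statistic cases; closure is checked against a reachability oracle on 100
random graphs of up to 300 nodes; the aligner against exhaustive
enumeration on 500 string pairs of length ≤ 8; the ORF finder against the
six-frame oracle on 100 sequences of 300–3000 nt; and the DE ranking
experiment uses 1000 transcripts over the six-library design. Tolerances:
$10^{-12}$ for the binomial tail, $10^{-10}$ for the R statistic,
$10^{-6}$ relative for RPKM conservation — all far inside double
precision for these magnitudes.

Degenerate inputs have defined behaviour rather than errors where a value
is representable (all-N GC → NaN, correlation of a constant profile →
missing, k = 0 variant count → p = 1) and loud errors where the input is
malformed (duplicate FASTA ids, negative counts with file and line,
column-count mismatches in tabular hits, a sequence in two clusters of one
import, cycles in the ontology).

## Known limitations

* Assembly is out of scope: the workbench starts from transcripts and
  counts, and pileups are consumed as per-position tallies, not computed
  from read alignments.
* DE and GO-enrichment p-values are imported, never computed; the package
  deliberately does not wrap external statistical tools.
* The longest-ORF coding-sequence extraction is a heuristic; genuinely
  non-coding transcripts and frameshifted assemblies will still produce a
  "protein".
* GO levels follow the shortest-is_a-path convention; other tools may
  report longest-path or relation-inclusive depths and will disagree by
  design.
* The plain-text store is single-user and loads fully into memory;
  projects beyond a few hundred thousand sequences would want a real
  database behind the same interface.
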