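---
title: "Selecting taxon-specific k-mers and detecting them in raw reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting taxon-specific k-mers and detecting them in raw reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Identifying a plant taxon inside a mixed or degraded DNA sample is classically
done by amplifying and sequencing a small number of barcode loci. That fails
whenever the DNA is too degraded to amplify, the primers do not bind, or the
chosen locus does not discriminate the taxa of interest. `taxkmer` implements
the alternative: find, once, the set of *k*-mers (exact substrings of fixed
length *k*) that are present in the genomes of the target taxon and absent
from all available non-target genomes, and then detect that panel directly in
raw sequencing reads by exact canonical *k*-mer lookup — no assembly, mapping
or alignment.

A *k*-mer and its reverse complement are one entity throughout: every window
is stored as its **canonical form**, the lexicographically smaller of the
window and its reverse complement. Both strands of a genome, and reads from
either strand, therefore hit the same table entries. Because canonical
identity is strand-symmetric there is no reason to prefer odd *k*; both
parities behave identically (palindromic even-*k* windows simply map to
themselves).

The selection model is pure set algebra over per-genome *k*-mer lists:

1. **Universality.** Build one canonical *k*-mer list per target genome file
   and keep the *k*-mers present in at least *m* of them. One genome = one
   file is the unit of presence; presence is binary per genome (count ≥ 1),
   never multiplicity-weighted. Low *m* admits individual-specific variation;
   *m* = 2 (the default) removes *k*-mers private to a single accession while
   tolerating one missing observation.
2. **Specificity, step one.** Subtract every *k*-mer that occurs in any
   non-target *assembly*.
3. **Specificity, step two.** Subtract every *k*-mer whose count in a
   non-target *read set* reaches a frequency cutoff *f* (default 10). Read
   sets sample the whole genome of close relatives — nuclear and
   mitochondrial sequence that assembled organelle genomes do not cover — but
   they also contain sequencing errors, which at roughly 10^-3 per base
   produce a thin layer of singleton noise *k*-mers. The cutoff keeps the
   subtraction to *k*-mers genuinely present in the non-target sample.
   Each read file is filtered separately, so one deep sample cannot raise
   another shallow sample's noise above the cutoff.

The order of the steps does not change the result (set difference commutes
with itself); it is fixed as above so the per-step removal counts form an
interpretable funnel, which `select_specific()` records in its `steps` table.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k` | 32 | nt | window length; longer *k* raises specificity, shortens the universal core |
| `min_targets` (*m*) | 2 | genomes | universality cutoff over target genome files |
| `nontarget_read_min_freq` (*f*) | 10 | occurrences | presence threshold in non-target read sets during selection |
| detection `cutoffs` | 1, 2, 5, 10 | occurrences | frequency thresholds when counting the panel in reads |

`k` is capped at 32 so that a *k*-mer always fits one 64-bit word in 2-bit
encoding — the regime exact *k*-mer counters are designed for. Within the
package the canonical *string* is the working representation (its byte order
equals 2-bit code order, so sorted lists and merges behave identically);
`kmer_encode()`/`kmer_decode()` expose the numeric packing itself, exactly
representable in doubles up to *k* = 26.

The choice of *k* is an empirical trade-off: shorter *k*-mers are more
universal across target accessions but ever more likely to recur in
non-targets by chance (at *k* = 8 only 32,896 canonical species exist, so
every one occurs in any sizable genome collection). `k_sweep()` automates
running the pipeline over a grid of *k* (default 8, 12, 16, 20, 24, 28, 32)
to pick the length that maximizes the panel.

At detection time the same frequency logic reappears: `detected_at_cutoffs()`
reports how many panel *k*-mers reach each cutoff in a read set. Raising the
cutoff suppresses the error-generated detections that accumulate in deep read
sets from close non-target taxa (most specific *k*-mers differ from a
relative's genome by a single substitution, so one sequencing error suffices
to fake them) at the price of sensitivity in shallow target samples. The
appropriate cutoff depends on the expected read depth; the package reports
all four defaults side by side.

## Numerical and edge-case choices

* Windows containing any non-ACGT symbol (N, IUPAC ambiguity codes) are
  skipped entirely; lowercase input is upper-cased. This matches standard
  k-mer-counter behaviour and makes multi-record handling trivial (records
  are joined with `N` internally, so no window ever spans a record
  boundary).
* Genomes are treated as linear exactly as given: no wraparound windows
  across the origin of a circular plastome. A circular treatment would add
  at most *k* − 1 windows per genome; with *k* = 32 this is the likely
  explanation if per-genome unique counts differ from an external counter
  by a small constant.
* `intersect` keeps the minimum of the two counts (the most conservative
  shared multiplicity); `subtract` removes by identity alone and ignores the
  subtrahend's counts, because specificity removal is presence-based.
* Union counts are the *sum* over input lists, so the panel carries total
  target multiplicity as provenance; downstream detection ignores these
  counts.
* Empty inputs degrade gracefully (empty FASTA → empty list; empty list is
  a left/right identity of the set operations), but an *empty target list*
  in `select_specific()` is an error: it means a target file contributed no
  sequence of length ≥ *k*, which is always a data problem.
* FASTQ subsampling keeps reads at indices `0, s, 2s, …` with stride
  `s = floor(n_total / n_out)`, truncated to exactly `n_out` records, each
  record copied verbatim — byte-deterministic by construction. Every-Nth
  subsamples at different sizes are deliberately *not* nested (they emulate
  even sampling of a sequencing run); `mode = "prefix"` is provided where
  nesting matters. Paired-end mates are treated as independent read streams.
* Read counting is per window occurrence: a *k*-mer appearing twice in one
  read counts twice, canonically on both strands. No quality filtering or
  trimming is applied — raw reads as-is.
* Cluster membership on the reference uses interval adjacency: hits whose
  *k*-length windows overlap or touch (next start within *k* of the previous
  start) merge, via `IRanges::reduce()`. A run of *n* hits at consecutive
  starts therefore spans *n* + *k* − 1 bp — 33 bp for 2 overlapping 32-mers,
  62 bp for 31. Coordinates are 0-based half-open (BED) in all outputs;
  1-based inclusive only in printed summaries.

## What the synthetic panels emulate — and what they do not

`generate_panel()` builds the data regime the pipeline was designed for,
at a scale where the exhaustive oracle is cheap: an ancestral plastome-like
genome assembled as LSC + IR~A~ + SSC + IR~B~ (large/small single-copy
regions separated by two inverted repeats, IR~B~ the exact reverse
complement of IR~A~), several near-identical target genomes carrying a set
of shared target-private substitutions, and phylogenetically close
non-targets diverged independently from the ancestor. Both IR copies are
held identical across all taxa, mirroring the strong conservation of real
plastome inverted repeats — with the testable consequence that no
taxon-specific *k*-mer can ever lie inside an IR block.

Defaults (chosen once as a realistic miniature): 20 kb genome (LSC 11 kb,
IR 3 kb × 2, SSC 3 kb — about one-seventh of a real 115–165 kb plastome,
same architecture), 5 targets with intra-taxon divergence 5 × 10^-4
substitutions per single-copy bp (plastomes are nearly invariant within a
species), 10 non-targets at 2 × 10^-2 (percent-level, as between close
congeners), 12 planted target-private variants, 100 bp reads with a
2 × 10^-3 per-base substitution error rate. The test suite and examples use
these sizes or smaller (2–10 kb) so that the full suite runs in well under a
minute of compute per file; all stochastic assertions use fixed seeds.

The mutation model is substitution-only. That is what keeps the
ground-truth oracle exact: every genome has identical coordinates, so
"the windows covering a variant" is well-defined and the truth panel can be
computed by exhaustive window comparison (`oracle_specific_panel()`, a
deliberately naive second implementation sharing no machinery with the
production path). Real data contain indels, rearrangements and structural
variation, and real sequencing errors are neither uniform nor
quality-independent. Passing the synthetic recovery tests therefore shows
that the set algebra, thresholds and bookkeeping are exactly right — it does
not certify performance on diverged real genomes, which depends on the
completeness of the non-target collection more than on the algorithm.

Two qualitative behaviours of real read data are reproduced and asserted
directionally: error-bearing reads from a close non-target accumulate
spurious panel detections as read numbers grow, and raising the frequency
cutoff suppresses those detections proportionally more than detections in
target reads.

## Known limitations

* Exact counts only — no probabilistic or streaming counters; memory scales
  with the number of distinct *k*-mers. Fine for organelle-genome panels and
  read sets of desk scale; a hundred-gigabase metagenome wants a dedicated
  counter in front, with `read_klist()` as the interface.
* Exact-match semantics only: a single mismatch hides a *k*-mer. That is a
  feature at selection time (it defines specificity) and a known sensitivity
  limit at detection time.
* Counts in reads are not abundance estimates: organelle copy number varies
  wildly between tissues and conditions, so detection is presence/frequency
  evidence, not quantification.
* The cluster rule is geometric (interval adjacency), which reproduces the
  span arithmetic of single-variant clusters; a rule based on pairwise
  sequence similarity could split adjacent clusters differently at region
  boundaries.

## A worked miniature

```{r, eval = FALSE}
library(taxkmer)

pp <- panel_params(seed = 1)          # 20 kb plastome, 5 targets, 10 non-targets
tr <- generate_panel(pp, out_dir = tempfile())

sel <- select_specific(tr$target_files, tr$nontarget_files,
                       config = selection_config(k = 32, min_targets = 2))
identical(sel$panel$kmers, tr$truth_panel$kmers)   # TRUE: exact recovery

fq <- tempfile(fileext = ".fq.gz")
simulate_reads(tr$genomes[["target_01"]], pp, fq)
detected_at_cutoffs(count_in_reads(sel$panel, fq))

hits <- locate_kmers(sel$panel, tr$target_files[1])
cluster_hits(hits, k = 32)
```
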