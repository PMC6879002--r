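---
title: "Designing and assessing Linked-Read libraries with lrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and assessing Linked-Read libraries with lrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrkit)
library(data.table)
```

## The model

Linked-Read sequencing partitions long DNA molecules into barcoded
droplets and sequences short reads from them, so that reads sharing a
barcode can be tied back to the same long molecule. The experimental
design space is governed by a small set of coupled parameters:

* **C** — total short-read coverage of the genome;
* **C_F** — *physical* coverage: summed long-fragment length divided by
  the haploid genome length;
* **C_R** — mean short-read coverage attained *within* one fragment;
* **N_F/P** — mean number of fragments sharing one partition (barcode);
* **muFL** — unweighted mean fragment length, and **WmuFL** — the
  length-weighted mean, defined here as `sum(L^2) / sum(L)`.

The identity `C = C_F * C_R` couples the first three: for a fixed
sequencing budget, physical coverage and per-fragment read depth trade
off against each other. `lrkit` lets you generate libraries at chosen
design points, recover the realized parameters from the reads, and score
haplotype-resolved assemblies built from them.

The simulation follows the droplet workflow in five steps: (i) a diploid
template is built by duplicating a reference into two haplotypes and
inserting SNVs; (ii) whole-genome copies of each haplotype are sheared
into fragments with exponential(muFL) lengths until the target `C_F` is
reached (accounted against the *haploid* genome length, fragments split
evenly between haplotypes); (iii) fragments are allocated to partitions
with Poisson(`N_F/P`) occupancy (zero draws redrawn — an empty partition
does not exist physically) and each partition receives a unique random
16-mer barcode; (iv–v) paired-end reads are drawn per fragment at
Poisson(`C_R * L / g`) pairs, where `g = 2 * read_len - 23` counts
genomic bases only — the first 23 bases of every forward read are the
16 bp barcode plus 7 N spacer bases, exactly as they appear in real R1
FASTQ records.

For exponentially distributed fragment lengths, `WmuFL = 2 * muFL`; the
package reports both, together with the PDF/CDF/reverse-CDF tables used
in standard library QC panels.

## A worked design point

```{r design}
params <- library_params(c_f = 200, c_r = 0.2, mu_fl = 37000, n_fp = 10,
                         seed = 1)
params
```

```{r simulate}
spec <- synthetic_reference_spec(n_contigs = 2, contig_len = 500000,
                                 gc_content = 0.41, seed = 1)
template <- build_template(generate_reference(spec), seed = 1)
template
lib <- simulate_library(template, params, with_sequences = FALSE)
lib
```

Reconstructing the molecules from the truth sidecar and profiling them
recovers the design point:

```{r recover}
placements <- placements_from_truth(lib$reads)
molecules <- infer_fragments(placements, use_provenance = TRUE)
profile_library(molecules, ref_len = template$source_len)
```

## Molecule reconstruction and its filters

From barcode-annotated alignments (or the truth sidecar), read pairs
with the same barcode are chained into molecules. Three filters, applied
in this order, define a reconstructed molecule:

1. **Termination**: a molecule ends when the end-to-start gap between
   consecutive same-barcode pair spans exceeds 50 kb (or the contig
   changes). The gap is measured between the previous pair's rightmost
   and the next pair's leftmost coordinate, floored at zero — the
   end-to-start convention is insensitive to read length.
2. **Support**: molecules need at least 2 read pairs and at least 2 kb
   of span.
3. **Partition plausibility**: barcodes retaining fewer than 3 molecules
   are removed entirely.

All thresholds are exposed as arguments with these defaults.

### A known scale limitation

The 50 kb proximity heuristic assumes that two co-barcoded molecules
rarely land near each other — true on a gigabase genome, where the
expected number of same-barcode molecule pairs within the termination
window is effectively zero, but not on the megabase toy genomes used for
testing. With 10 molecules per barcode on 2 Mb, a substantial fraction
of adjacent co-barcoded molecules fall within the window and are merged,
inflating inferred lengths and deflating molecules-per-partition. This
artifact is a property of the genome size, not of the chaining code; it
disappears as genome length grows with the design point held fixed.

For this reason, parameter-recovery studies on synthetic data use
`infer_fragments(..., use_provenance = TRUE)`: when the truth sidecar
supplies the true source molecule of each read, chaining is additionally
keyed by it, so reads from different molecules are never merged while
every filter above still applies. Alignment input carries no provenance
and always uses plain barcode chaining. At a 2 Mb / `C_F` 200 / `C_R`
0.2 design point the provenance path recovers muFL within ~1% and `C_F`
and `N_F/P` with a systematic downward bias of 7–8%, caused by the
support filters (edge reads do not reach the true molecule ends; small
or weakly covered molecules are dropped) — the quantity the recovery
tests measure.

### Subsampling

`subsample_reads()` thins pairs molecule-by-molecule to a target `C_R`
(rounded per molecule, capped at what is available), and
`subsample_fragments()` drops whole molecules uniformly until a target
`C_F` is first reached — the standard way to match design points across
libraries before comparing assemblies. `filter_linked_fastq()` realizes
a retained-read set as a filtered FASTQ pair.

## Assembly evaluation

`break_scaffolds()` decomposes scaffolds into contigs at runs of >= 10
N; `nx()` computes N50-type statistics by descending cumulative sum.
NA50 uses `break_at_misassemblies()`: alignment blocks of a query are
scanned in query order and a breakpoint is declared when consecutive
blocks map to different reference contigs, to different strands, or with
a target/query gap disagreement above 1 kb (defaults: blocks >= 500 bp;
contigs >= 500 bp or scaffolds >= 1 kb considered). Queries with no
surviving alignment are kept unbroken, which is conservative: NA50 can
only be pushed down by detected breakpoints, never up.

Diploid-state assessment tiles the reference with 500-bp windows. A
contig covers a window when the union of its blocks spans the whole
window (`min_cov_frac = 1` by default). A window is **diploid** when
covered by at least one contig from each haplotype, **haploid** when
covered by exactly one labelled contig, **excess** when covered by a
single haplotype through more than one contig (the haploid class is
deliberately "covered by one contig exactly", which is also what a
hemizygous region check wants), and **uncovered** otherwise. Unlabelled
contigs contribute to overall coverage only. Maximal runs of diploid
windows are the diploid regions; their N50 is the package's
operationalisation of phase-block length, since haplotype phase is by
construction consistent within such a run.

```{r asm-toy}
h1 <- as.character(template$hap1[["contig1"]])
h2 <- as.character(template$hap2[["contig1"]])
blocks <- alignment_blocks(qname = c("c1/1", "c2/2"),
                           qlen = c(300000, 400000),
                           qstart = 0, qend = c(300000, 400000),
                           tname = "contig1",
                           tstart = c(0, 100000), tend = c(300000, 500000))
cls <- classify_windows(blocks, c(contig1 = 500000))
cls
```

For several assemblies of the same genome, the expected chance overlap
of their diploid regions under independence is the product of the
per-assembly diploid fractions (`chance_overlap()`), and
`overlap_chi2()` performs the 1-df goodness-of-fit comparison of the
observed overlapping window count against that expectation. When window
counts are large, minute effects become formally significant and
neighbouring windows are correlated, so the test's p-value should be
read as descriptive rather than exact.

## Numerical and design choices

* **Exactly two** of `C`, `C_F`, `C_R` are specified; the third is
  derived (1e-9 relative consistency check if all three are given).
* `C_R` and all coverage accounting count **genomic bases only**
  (`2 * read_len - 23` per pair); barcode and spacer bases carry no
  genomic information. Whether published coverages count barcode bases
  is generally ambiguous; this convention is the conservative one.
* Template SNVs outside supplied high-confidence calls are placed
  per-base Bernoulli at 1 per kb in expectation (not a fixed count),
  with het:hom drawn 2:1 and the heterozygous haplotype chosen by fair
  coin per site; N bases are never mutated. Adjacent sites may occur, as
  in real data.
* Shearing truncates the last piece of each genome copy at the contig
  end and discards pieces below `min_len` (default 1 kb — real
  libraries contain sub-2 kb molecules, which the inference filters then
  remove). Retained totals overshoot the `C_F` target by at most one
  fragment before random trimming.
* Insert sizes are Normal(500, 50) rounded and clamped to
  `[2 * read_len, L]`; per-fragment pair counts are Poisson, reflecting
  the stochastic capture of molecule sequence into short fragments.
* Barcodes are unique random 16-mers rather than a vendor whitelist;
  uniqueness is the property downstream logic needs. Partition counts
  above 4.8 million trigger a warning, the practical barcode limit of
  the droplet system.
* Every stage draws from its own RNG stream derived from the master
  seed via `stage_seed()`, so changing one stage's parameters does not
  perturb another stage's draws; identical configuration and seed give
  byte-identical outputs.
* Coordinates are 0-based half-open internally; FASTA/FASTQ/VCF/BED
  conventions apply at the file boundaries.

## What the synthetic generator does and does not emulate

The generator reproduces the *parametric* structure of a Linked-Read
library: exponential molecule lengths, Poisson partition occupancy,
within-molecule uniform read placement, uniform substitution errors and
the barcode read layout. It does not model PCR duplicates, GC or
coverage bias, barcode sequencing errors or collisions beyond the
`N_F/P` model, chimeric molecules, or structural variation (templates
diverge by SNVs only, so haplotype and reference coordinates coincide).
Passing tests on this generator therefore demonstrate correctness of
the accounting and inference machinery under the stated model, not
robustness to artifacts of real libraries.

Test and vignette problem sizes (0.2–2 Mb genomes, `C_F` up to 200) are
chosen so a full run completes in minutes on a laptop while keeping
per-library fragment counts in the tens of thousands, which is enough to
estimate the design parameters to within a few percent.
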