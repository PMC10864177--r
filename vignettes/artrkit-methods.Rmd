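---
title: "Profiling RBP binding sites from in situ RT sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling RBP binding sites from in situ RT sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artrkit)
library(dplyr)
```

## The assay and the analysis problem

Antibody-guided in situ reverse transcription converts RNA in the immediate
neighbourhood of a targeted RNA-binding protein (RBP) into cDNA, tagged
during library construction with an 8-nt unique molecular identifier (UMI)
and, for multiplexed runs, an 8-nt sample barcode read out on read 2. An
*input* library, prepared identically but with the primary antibody
omitted, measures the non-specific background. The computational task is to
go from raw paired FASTQ to

1. **usable reads** — demultiplexed, trimmed, uniquely aligned,
   UMI-deduplicated reads;
2. **binding peaks** — strand-separated intervals where the IP read pileup
   exceeds the input-derived local background;
3. **gene-level enrichment** — a stratified odds-ratio statistic across
   replicate pairs; and
4. **binding dynamics** — fuzzy clustering of per-gene binding-strength
   trajectories across a stress time course.

`artrkit` implements all four stages plus a synthetic-data generator that
emulates the assay, so every stage is tested against planted ground truth
rather than against downloaded datasets.

## The synthetic-data generator

`sim_config()` + `build_reference()` create a random genome whose genes
(default 1.5–3 kb, both strands, log-normal expression with
`meanlog = 0, sdlog = 1`) carry planted binding sites at whose anchor the
binding motif (default `UGCAUG`) is written into the sequence on the gene
strand. `simulate_library()` then draws reads:

* **IP mixture.** With probability `ip_signal_fraction` (default 0.5) a
  molecule is *site-origin*: a site is chosen with weight occupancy ×
  gene expression and the fragment centre is drawn from a truncated
  Gaussian (`site_kernel_sd`, default 50 nt) around the site anchor.
  Otherwise the molecule is *background*: a gene is chosen proportional to
  expression and the fragment placed uniformly inside it. Input libraries
  use a site probability of zero, so IP and input share the same background
  generative process.
* **Read architecture.** Read 1 is `[8-nt UMI][cDNA]`, where the cDNA is
  the reverse complement of the sense RNA fragment (the library is
  *reverse-stranded*; `strandedness = "reverse"` is the pipeline default).
  Fragments shorter than the read are followed by the 3' adapter and, if
  needed, dark-cycle `G`s. Read 2 begins with the sample barcode.
* **PCR duplication.** Each read is, with probability
  `pcr_duplication_rate` (default 0.2, a typical desk value), a verbatim
  copy of a previously generated molecule (same UMI, position and
  sequence). UMIs are drawn at random but regenerated on collision within
  an identical (contig, 5' position, strand) group, so exact-UMI
  deduplication recovers the pre-PCR molecule count exactly. Real libraries
  can contain such collisions; any exact-UMI deduplicator merges them, so
  this choice isolates the deduplication logic from an irreducible
  ambiguity of the assay.
* **Expected enrichment.** The per-gene IP/input read-rate ratio implied by
  the mixture, `pi * w_g / sum(w) * sum(x) / x_g + (1 - pi)` with `w_g` the
  gene's occupancy-weighted site mass and `x_g` its expression, is stored
  in the truth object; enrichment-recovery tests compare estimates against
  this quantity rather than against the nominal occupancy multipliers.

What the generator deliberately does **not** emulate: spliced (junction)
reads, indels, position-dependent error profiles, ribosomal RNA beyond a
single decoy contig, and fragment-length biases. Tests passing on this
generator therefore validate the statistical machinery and the coordinate
conventions, not robustness to alignment artefacts of real data.

## Read preparation

* **Demultiplexing** assigns a pair to the unique barcode within
  `max_mismatch` of the read-2 prefix; the barcode table must have pairwise
  Hamming distance `> 2 * max_mismatch`, which makes the assignment a
  partition (anything else goes to `undetermined`).
* **Trimming** (`trim_reads()`) moves the first 8 nt of read 1 to the UMI
  field, then quality-trims the 3' tail with a simplified two-colour rule
  (trailing bases removed while below Q20 or part of a trailing G run — in
  two-colour chemistry a dark cycle reads as a high-confidence G), then
  removes the adapter at the *leftmost* position where the read suffix
  matches a prefix of the adapter with ≥ 3 nt overlap and ≤ 10%
  mismatches, then removes 4 further 3' bases (the imperfectly paired
  random-primer positions), and finally discards reads shorter than 24 nt.
* **Alignment.** The built-in `align_exact()` is a *fixture aligner* for
  synthetic reads: an ungapped exact or 1-mismatch search on both strands
  (trusted-band dictionaries; the 1-mismatch mode uses a pigeonhole pair of
  leading/trailing bands). Reads with exactly one best locus are kept.
  Production data comes in through `read_sam()` from any external aligner,
  with `NH == 1` defining uniqueness and a 24-nt minimum match expected
  upstream. Only read 1 is aligned: the mate carries barcode, not sequence,
  and the pipeline treats the library as single-end after demultiplexing.
* **Deduplication** keeps one read per (contig, 5' position on the
  alignment strand, alignment strand, exact UMI); representatives are the
  first record in (position, UMI, read id) order — a deterministic
  tie-break the assay itself does not constrain. No UMI error-correction
  clustering is attempted.

## Peak calling

Coverage is built per transcript strand by extending each usable read
`extsize = 30` nt 3'-ward from its 5' end — all reads are kept, since
duplicates were already removed. For each base with nonzero treatment
pileup, the local background is

```
lambda_local = max(lambda_bg, lambda_ext, lambda_1k, lambda_10k)
```

where the windowed terms are centred means of the matching-strand *input*
pileup scaled by the depth ratio (treatment reads / control reads; the
smaller library is scaled up) and `lambda_bg` is the genome-wide control
rate. The fragment-sized (`extsize`) window is part of the composition for
a reason worth stating: at sharp coverage boundaries — gene edges above an
empty intergenic background — kilobase windows dilute the control rate with
zeros and systematically understate the local background, which manufactures
false peaks precisely at gene boundaries. The small window tracks the
control rate at the scale of the signal itself and removes that artefact;
site detection is unaffected because the input carries no site enrichment
for the small window to absorb. Without a control, the treatment's own genome-wide rate is used. The
p-value is the upper-tail Poisson probability `P(X >= pileup)`;
Benjamini–Hochberg correction runs over exactly the bases with nonzero
treatment pileup (a finite, well-defined testing family). Bases with
`q < qcut` (default 0.05 — exposed, since the assay literature reports only
"stringent" cutoffs qualitatively) merge across gaps up to
`merge_gap = extsize`; peaks shorter than 30 nt are dropped; the summit is
the leftmost pileup maximum; and the signal value is
`(pileup + 0.1) / (lambda_local + 0.1)` at the summit, the pseudocount
guarding against empty control windows. The two strands are called
independently against their matching-strand controls and concatenated, so
overlapping sense/antisense peaks are both legitimate.

## Annotation and composition statistics

Feature assignment is strand-aware and uses the longest-overlap rule, with
exact ties broken by the declared precedence 3'UTR > 5'UTR > CDS >
noncoding exon > intron; reads are assigned by the feature containing their
5' base. When a gene has several isoforms, the longest transcript defines
the UTR/CDS partition. Motif distances are measured centre-to-centre
against the nearest strand-matched occurrence. CU-enriched regions are
80-nt windows (1-nt step) within protein-coding genes whose sense-strand
C+T fraction strictly exceeds 0.70, merged when overlapping; C+T on the
sense DNA strand equals C+U on the RNA. Metagene profiles map exonic peak
centres to fractional positions along a binned 5'UTR/CDS/3'UTR axis and
normalise the density to sum to one. `shuffle_regions()` draws
length-matched intervals uniformly over the merged exonic space (every
admissible placement equally likely), the null used for peak–site overlap
percentages.

## Gene-level enrichment

For each gene, every (IP replicate, input replicate) pair contributes one
2×2 table: reads inside the gene versus outside, IP versus input —
"all combinations" is read literally as the Cartesian product (R × S strata
for R IP and S input replicates); index-paired strata are available via
`pairing = "paired"`. The enrichment is the Mantel–Haenszel common odds
ratio

```
OR_MH = sum_i(a_i d_i / n_i) / sum_i(b_i c_i / n_i)
```

with significance from the Cochran–Mantel–Haenszel chi-squared statistic
(1 df, optional continuity correction). The Haldane–Anscombe 0.5 correction
is applied only when a zero margin leaves the estimator undefined, and is
flagged. Genes are grouped as No (`OR <= 1`), Low (`1 < OR <= 2`) and High
(`OR > 2`), boundaries inclusive on the lower group; grouping is applied to
all genes with the CMH q-value reported alongside, since filtering on
significance before grouping is a choice the downstream analyst should
make.

## Binding dynamics

`binding_strength()` normalises per-gene counts by median-of-ratios size
factors, reports `log2((ip/s_ip + 1) / (input/s_in + 1))`, drops genes with
a raw read sum below 10, and attaches a two-sided binomial test of the IP
count against the depth-ratio expectation. This is a deliberately simple,
fully documented replacement for a negative-binomial GLM: with a single
library pair per time point there is no dispersion information, and the
binomial test is exact for the in/out split at fixed total. Targets are
genes with `FC >= 2` (inclusive) and `p < 0.05` (raw by default; a BH
switch is provided, as the convention is not fixed in the field).

For clustering, genes in the top 50% of trajectory standard deviation are
z-scored row-wise and clustered with fuzzy c-means (`m = 2` by default;
the fuzzifier is rarely reported, and 2 is the classical choice), Euclidean
distance, convergence at a maximum centroid shift below 1e-9 with a 10,000
iteration cap. The cluster number is chosen by eye from the minimum
centroid distance curve (`dmin_curve()`); the elbow is reported, not
automated, because any automatic rule hides a judgement call.

## Numerical and design choices

* Intervals are 0-based half-open everywhere in tibbles; GTF emission is
  1-based closed. Summit ties break leftmost; feature ties break by the
  precedence above; duplicate ties break lexicographically.
* All randomness flows through explicit seeds; stage seeds derive from the
  run seed by a stable hash of the stage name, so stages are independently
  reproducible and two runs with one config are byte-identical (FASTQ is
  written uncompressed for this reason).
* Empty inputs error early and explicitly (empty read set, zero-depth
  treatment, no gene passing the read-sum filter) rather than propagating
  NaNs.
* Problem sizes in the test-suite simulations (50-gene / ~0.5 Mb genomes
  with 200k-read libraries for recovery; 2,000 genes at alignment level
  for null calibration; 300 genes × 4 time points for clustering) were
  chosen so each check exercises the intended asymptotics at desk scale.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 20, n_sites = 20, n_reads = 5e4)
truth <- build_reference(cfg)
ip <- simulate_library(truth, "IP", cfg, seed = 2, sample = "S1")
input <- simulate_library(truth, "input", cfg, seed = 3, sample = "S2")

usable <- lapply(list(ip = ip, input = input), function(lib) {
  trim_reads(lib$reads, cfg$adapter_seq) |>
    align_exact(truth$genome) |>
    deduplicate()
})

peaks <- combine_strands(
  call_peaks(build_coverage(usable$ip, truth$genome, "+"),
             build_coverage(usable$input, truth$genome, "+")),
  call_peaks(build_coverage(usable$ip, truth$genome, "-"),
             build_coverage(usable$input, truth$genome, "-")))

idx <- feature_index(truth$genome)
assign_peaks(peaks, idx) |> count(feature)
motif_distance(peaks, "UGCAUG", truth$genome) |>
  summarize_motif_distance()
```

## Known limitations

The fixture aligner is ungapped and caps mismatches at one, so it cannot
stand in for a spliced aligner on real data; the peak caller tests bases
with nonzero treatment pileup only, so extremely sparse treatments have a
smaller multiple-testing family than a genome-wide scan; the binomial
binding-strength test ignores biological overdispersion and will be
anti-conservative on real replicates (use it for ranking and simulation
work, or bring replicate-aware statistics for publication-grade target
lists); and the generator's Gaussian read-start kernel is a convenience,
not a mechanistic model of RTase processivity.
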