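---
title: "Titration-design benchmarking of RNA-seq quantifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Titration-design benchmarking of RNA-seq quantifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titrabench)
```

# The titration design and its fold-change model

The benchmark is organised around a classic two-reference titration: two
total-RNA references A and B are mixed by mass into sample C (3 parts A,
1 part B) and sample D (1 part A, 3 parts B). Because mass mixing is
linear in molar concentration per unit mass, every gene's C/D fold
change is a deterministic function of its A/B fold change. With `r` the
measured A/B fold change and `z` the total-signal ratio of A to B,

    log2(C/D) = log2(k1 * r + (1 - k1)) - log2(k2 * r + (1 - k2)),
    k1 = 3z / (3z + 1),   k2 = z / (z + 3).

`k1` is the fraction of sample-C signal contributed by A and `k2` the
corresponding fraction in D; `k1 > k2` for every `z > 0`, the function
is monotone in `r`, and a gene identical in A and B (`r = 1`) maps to 0.
The default `z = 1.43` follows the value conventionally used with these
reference RNAs. The model turns fold-change accuracy into a supervised
problem: a quantifier is scored by how well its measured C/D fold
changes match the model's prediction from its own measured A/B fold
changes, via `R2 = 1 - sum((y - f)^2) / sum((y - ybar)^2)` (which is
negative when the fit is worse than the mean predictor) and RMSE.

A second, independent source of truth is the spike-in design: 92
ERCC-like in vitro transcripts (250-2000 nt) are split into four groups
of 23 with designed A:B ratios 0.67, 1, 2 and 4, so exactly 69 are truly
differentially expressed and 23 are null. The designed ratios are forced
before the global rescale that pins `sum(A)/sum(B)` to `z`; since that
rescale multiplies all of sample A by one common factor, within-design
ratios are preserved exactly and the 1:1 group is null in normalized
(CPM/TPM) measurement space, which is where differential expression is
assessed. DE calls between A and B,
swept over p-value thresholds against this truth, give an ROC curve and
its Mann-Whitney AUC (ties counted 1/2).

## Why generation happens in molar space

`makeAbAbundances()` draws concentrations in molar-per-unit-mass units,
the space in which 3:1 mass mixing is linear; `mixTitration()` then
forms C and D by exact arithmetic, and sample A is rescaled globally so
that `sum(A)/sum(B) = z` holds exactly rather than approximately. As a
result the fold-change model above is an exact identity of the
generator (to numerical precision, about 1e-15 in practice), which the
test suite verifies at 1e-9: a perfect quantifier attains `R2 = 1`, and
every deviation measured downstream is attributable to the quantifier,
not to the simulation.

## The abundance sampler

Expression levels are drawn as `base * sqrt(ratio)` for A and
`base / sqrt(ratio)` for B, with `log10(base)` uniform on (-1.25, 1.25)
plus a gene-type offset, and `log10(ratio)` uniform on (-0.75, 0.75)
for non-spike-ins (spike-ins are forced to their group ratio). Two
choices deserve comment.

First, the factored form. Drawing A and B independently over several
decades would make extreme per-gene fold changes (hundreds-fold) the
norm; real reference tissues differ by a few fold for most genes while
expression levels span orders of magnitude. The factored sampler keeps
the ratio spread at about 1.5 decades — still well over an order of
magnitude, so DE structure is rich — without generating genes that are
essentially absent from one reference.

Second, the type offsets (log10 molar): tRNA +3.5, rRNA +1, snoRNA
+0.5, others 0. tRNAs are a substantial mass fraction of total RNA and
are ~75 nt long, so their molar concentration exceeds that of a typical
mRNA by orders of magnitude; +3.5 yields a tRNA read share of roughly
10-30% at the default read length, consistent with tRNA-rich total-RNA
libraries produced by thermostable group II intron reverse
transcriptase (TGIRT) protocols. The rRNA offset reflects a
ribo-depleted but not rRNA-free library.

## Reads, modifications and errors

`simulateReads()` draws a read's source transcript proportionally to
molar abundance times effective length `max(L - readLength + 1, 1)`,
uniform start, sense strand only (stranded library chemistry), no
indels. tRNA-like transcripts carry 1-4 modification sites drawn from
Normal clusters centred at positions 20, 30 and 50 (sd 3, clipped
inside the transcript) — or exactly `{20, 30, 50}` in the canonical
mechanism scenario. Each site covered by a read is misread with
probability `misRate` (default 0.8), substituting a uniformly chosen
different base: this emulates reverse-transcription misincorporation at
modified bases (e.g. m1A, m2,2G, inosine), which is the biological
signal the benchmark is built around. True per-site misincorporation
rates are not established quantities; `misRate` is a free parameter,
not an estimate. Sequencing errors are independent per-base flips
(default 0.001). Every injected error is recorded in the read set's
error log, so downstream assignment behaviour can be checked against
ground truth read by read.

The pipeline-level default read length is 75 nt. The function-level
default of `simulateReads()` is 50 nt (a neutral short-read length),
but the benchmark uses 75 so that reads from ~75-nt tRNAs are
full-length, as they are in TGIRT-seq libraries: the error-shadowing
mechanism below concerns reads that span all modification sites of a
short transcript, which 50-nt reads never do. Replicate counts are
negative binomial with mean proportional to TPM times effective length
and variance `mu + dispersion * mu^2` (default dispersion 0.01, a
typical technical-replicate scale; at dispersion 0 the library is a
multinomial draw of exactly `depth` reads).

# The two quantifiers

Both quantifiers consume the same reads and the same transcriptome and
differ only in read assignment — the variable under study.

**Alignment-free (`quantifyKmer`)**: an exact k-mer index
(`buildKmerIndex`) maps every k-mer to its transcript set;
`pseudomapRead` intersects the sets of the read's k-mers, skipping
k-mers absent from the index; reads with identical compatibility sets
form equivalence classes; `emAbundances` runs the standard
length-aware EM on class counts. The E-step weight for transcript `t`
in class `c` is `(theta_t / l_t) / sum_{u in c} (theta_u / l_u)`, so
the converged `theta` is a per-transcript read fraction; TPM divides
out effective length and renormalizes,
`TPM_t = 1e6 (theta_t/l_t) / sum(theta_u/l_u)`. Uniform initialization
defines the answer when the maximizer is not unique; convergence is
`max |delta theta| < 1e-8` or 1000 iterations. This is deliberately the
plain intersection rule — no skip-ahead, no bias models, no
error-tolerant matching — because the mechanism of interest is the
availability of error-free k-mers, which the plain rule isolates.

**Alignment-based (`quantifyAlign`)**: an exhaustive end-to-end Hamming
scan (`alignReads`, implemented in C++ with 2-bit packed popcount
comparisons) returns every placement within a mismatch budget (default
`ceiling(0.15 * readLength)`). Selection mimics small-RNA-aware
pipelines: placements on tRNA/rRNA transcripts pre-empt all others;
then fewest mismatches (the single-end analogue of a smallest-insert
criterion — both are most-parsimonious rules); then rRNA-locus
preference; then primary over decoy (decoys stand in for
haplotype/patch sequences); remaining ties break by a seeded uniform
draw, so each read is counted at most once. Gene counts sum reads per
gene; `aggregateAnticodon` sums tRNA genes per anticodon. Soft-clip
filtering has no analogue here because alignment is end-to-end; indels
and spliced alignment are out of scope.

# The error-shadowing mechanism

A substitution corrupts every k-mer window overlapping it. For a read
of length `L` with error positions splitting it into error-free gaps
`g`, the number of intact k-mers is `sum(max(g - k + 1, 0))`
(`errorfreeKmerCount`, verified exhaustively against brute-force window
enumeration). The canonical case: a 75-nt tRNA read with
misincorporations at positions 20, 30 and 50 has gaps 19, 9, 19, 25 —
all shorter than 31 — so at the common default `k = 31` *no* error-free
k-mer exists and an exact index cannot match the read at all, while at
`k = 21` the trailing 25-nt gap still yields 5 intact k-mers. The
largest workable k is the longest gap (`minDetectableK`, here 25).
`assignmentProbability` extends this to random per-site errors by exact
enumeration over error subsets (up to 20 sites) or Monte Carlo with a
binomial standard error; the two agree within sampling error by
construction, which the tests check. The alignment quantifier tolerates
the same three mismatches comfortably within its budget — this single
contrast, run on identical reads, is the benchmark's central result.

# Evaluation conventions

Several conventions had to be fixed where reasonable alternatives
exist; they are deliberate and encoded in one place each.

- **DE testing.** Gene-level log2 fold change is the difference of mean
  `log2(CPM + 0.5)`; the p-value is a two-sided Welch t-test on the
  same values. A shrinkage-based caller would be the field standard on
  real data, but would entangle the benchmark's read-assignment signal
  with shrinkage behaviour; the Welch test is transparent, calibrated
  under the null (the suite checks type-I error in [0.03, 0.07] at
  alpha = 0.05 over 5000 null genes), and applies identically to both
  quantifiers. Consequence: shrinkage-induced fold-change
  underestimation is not reproduced here. Genes with zero counts on
  one side get the pseudocount rather than exclusion, avoiding
  infinite fold changes.
- **ybar in R2** is the mean of the measured vector.
- **Gene aggregation** of transcript TPM multiplies by effective
  length, sums within genes, and rescales each library to its read
  count (length-scaled summation). Gene length is the longest
  transcript's length; gene TPM for detection divides by gene
  effective length and renormalizes.
- **Detection** is strict: TPM > 0.1. A gene is "detected in a sample"
  if detected in any of its replicates; this per-sample rule selects
  the genes whose fold-change metrics are computed (a gene must be
  quantified in all four samples to be testable). The *reported
  detected count* is the mean number of detected genes per library,
  which resolves sporadic dropout better than the per-sample rule when
  a quantifier assigns a gene in only a few libraries.
- **Per-stratum metrics** (expression top 1/10/25% and bottom 75%,
  length quartiles, gene types) are computed over each quantifier's own
  detected genes, mirroring per-pipeline tested-gene counts. For
  head-to-head mechanism comparisons `compareQuantifiers()` instead
  restricts to the genes detected by *every* compared quantifier:
  on a per-pipeline basis the better-detecting method is penalised for
  detecting (and thus being scored on) noisier genes, whereas the
  common-set comparison isolates assignment accuracy on identical
  genes. Quantile ties break by ascending gene identifier, so strata
  are deterministic.

# What the generator emulates, and what it does not

Emulated: the titration design with its exact fold-change identity;
spike-in groups with built-in truth; a long/short mixed transcriptome
with multi-isoform genes sharing long regions (genuine multi-mapping);
tRNA modification-driven misincorporation clustered at canonical
positions; replicate overdispersion; seeded, byte-reproducible
FASTA/FASTQ/TSV output.

Not emulated: GC and positional coverage bias, fragment-length
distributions, adapter read-through, paired-end reads, indels, RNA
secondary-structure effects on reverse transcription (premature
stops/truncations), sample-dependent modification stoichiometry, and
genome-level artefacts (splicing, repeat families). Passing tests
therefore demonstrate the k-mer error-shadowing mechanism and the
correctness of the evaluation machinery at desk scale; they do not
certify quantifier rankings on real libraries, where the excluded
effects (notably bias correction and sample-dependent modification
levels) also act.

# Numerical choices and degenerate inputs

- All randomness flows through explicit integer seeds; stage seeds are
  derived deterministically from the run seed and stay below 2^31.
- EM: uniform start, tolerance 1e-8, 1000 iterations; empty class maps
  return all-zero TPM with a warning; transcripts in no class get TPM
  0. Equivalence-class conservation (class totals + unassigned = reads)
  is asserted after every library.
- TPM tables must sum to 1e6 per library within 1e-6 relative; an
  all-zero library is an error, not a silent NaN.
- `rSquared` refuses constant measured vectors (zero denominator), and
  `rocAuc` refuses single-class truth.
- Degenerate DE inputs (zero variance on both sides) give p = 1 for
  equal means and p = 0 otherwise.
- The Hamming scanner disallows terminal overhangs; reads longer than a
  transcript simply have no placement there.

# Problem sizes

The default study conditions are 60 protein-coding genes (5 with two
isoforms), 92 spike-ins, 20 tRNAs, 10 snoRNAs, 2 rRNAs and 10 other
non-coding transcripts; 4 samples x 3 replicates at 50,000 counts per
library; 8,000 simulated reads of 75 nt per library for quantification;
k in {11, 15, 21, 31}. These sizes keep a full
simulate-quantify-evaluate cycle within a few minutes on one core while
leaving every gene type populated enough for per-type metrics. At this
depth absolute R2 values for the noisiest strata are much lower than
one would observe at realistic sequencing depth — the benchmark's
claims are therefore directional (method A vs method B on identical
inputs), which is also why the acceptance checks compare quantifiers
rather than asserting absolute accuracy levels.

# Known limitations

- A single `misRate` shared by all samples means dropout thins tRNA
  counts symmetrically across A-D, so k-mer fold-change damage at this
  scale appears as variance (sporadic surviving reads) rather than
  bias; sample-dependent modification stoichiometry, which would add
  systematic distortion, is not modelled.
- The weak CPM pseudocount makes fold changes of near-zero genes
  noisy at desk-scale library sizes; metrics are therefore computed
  over detected genes.
- The equivalence-class intersection rule is stricter than production
  pseudoaligners (no skip-ahead rescue), so absolute dropout rates are
  upper bounds on what those tools would show at the same k.
- At very small k (around 11) corrupted k-mers start colliding with the
  index at an appreciable rate on a toy transcriptome (4^11 possible
  words against ~1e5 indexed ones), and a collision can empty the
  intersection of an otherwise assignable read. Dropout at small k is
  therefore not purely the shadowing mechanism; the closed-form module
  deliberately excludes collisions, and the monotone-dropout property
  is only guaranteed for k large enough that collisions are negligible
  (k >= 15 at these sizes).
- Exhaustive alignment is exact but quadratic; it is intended for toy
  transcriptomes, not real references.
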