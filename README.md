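# titrabench

Desk-scale benchmarking of total RNA-seq quantification built on the
MAQC-style titration design, for people studying how read-assignment
strategy (exact k-mer matching vs mismatch-tolerant alignment) affects
the quantification of short, modification-bearing RNAs such as tRNAs in
total-RNA libraries.

## The design and the model

Two reference samples A and B are mixed by mass into C (3:1) and
D (1:3). With *r* the measured A/B fold change of a gene and *z* the
total-signal ratio of A to B (default 1.43),

```
log2(C/D) = log2(k1·r + (1 − k1)) − log2(k2·r + (1 − k2)),
k1 = 3z/(3z+1),  k2 = z/(z+3)
```

so every gene's C/D fold change is predictable from its own A/B
measurement, and a quantifier can be scored without external truth via
R² = 1 − Σ(yᵢ−fᵢ)²/Σ(yᵢ−ȳ)² (negative when worse than the mean
predictor) and RMSE. Additionally, 92 ERCC-like spike-ins in four
designed ratio groups (0.67:1, 1:1, 2:1, 4:1; 23 each, 69 truly DE)
provide ground truth for ROC/AUC of differential-expression calls.

The package simulates the whole design — transcriptome, molar-space
titration abundances (the fold-change model holds exactly, to 1e-15),
negative-binomial replicate counts, and reads carrying
reverse-transcription misincorporations at tRNA modification sites —
then quantifies the same reads two ways:

- **`quantifyKmer`**: exact k-mer index → compatibility-set
  pseudoassignment → equivalence classes → length-aware EM (TPM);
- **`quantifyAlign`**: exhaustive mismatch-tolerant end-to-end
  alignment (C++), tRNA/rRNA routing, multi-map selection by fewest
  mismatches / rRNA locus / primary-over-decoy, seeded tie-breaks,
  gene and anticodon counting;

and evaluates both with the titration model (`expectedCdLog2fc`,
`rSquared`, `rmse`), spike-in ROC/AUC (`rocAuc`), detection (TPM >
0.1), and stratification by expression, length and gene type. A
closed-form module (`errorfreeKmerCount`, `minDetectableK`,
`assignmentProbability`) gives the combinatorics of error-free k-mer
availability that explain alignment-free dropout on short RNAs.

## Worked example

A 75-nt tRNA read with misincorporations at positions 20, 30 and 50
has error-free gaps 19, 9, 19 and 25 nt, so at the common default
k = 31 no intact k-mer survives, while k = 21 still finds five:

```r
library(titrabench)
errorfreeKmerCount(75, 31, c(20, 30, 50))
#> [1] 0
errorfreeKmerCount(75, 21, c(20, 30, 50))
#> [1] 5
minDetectableK(75, c(20, 30, 50))        # longest gap
#> [1] 25
assignmentProbability(75, 31, c(20, 30, 50), misRate = 0.5)$estimate
#> [1] 0.625
```

The same contrast end to end — simulate 12 titration libraries (8,000
reads each) with misincorporation probability 0.8 at those sites, then
quantify with both methods and compare tRNA fold-change accuracy on
the genes both detect:

```r
cfg <- runConfig(
  txConfig = transcriptomeConfig(trnaModSites = c(20, 30, 50)),
  kGrid = c(21, 31), nReads = 8000, seed = 101)
res <- runBenchmark(cfg)
compareQuantifiers(res, geneType = "tRNA")
#>   quantifier rmse_common n_common detected
#> 1      align   0.5848903       17 19.58333
#> 2   kmer_k21   0.6810894       17 19.33333
#> 3   kmer_k31   1.3629346       17 16.50000
```

On identical reads and identical genes, the k-mer quantifier at k = 31
more than doubles the tRNA fold-change RMSE relative to the alignment
quantifier and detects about three fewer of the 20 tRNA genes per
library; k = 21 recovers most of the loss — because at 21 the trailing
error-free gap of the canonical site layout still admits intact
k-mers, and at 31 it does not. `res$report` holds the full per-stratum
table (R², RMSE, AUC by expression/length/type strata) and
`writeBenchmark(res, dir)` writes FASTA/FASTQ/TSV/JSON artifacts,
byte-identical on rerun with the same configuration.

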