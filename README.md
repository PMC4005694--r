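# codonreuse

Genome-scale analysis of **co-tRNA codon pairing bias (CTCPB)**: the
tendency, within protein-coding genes, for successive occurrences of the
same amino acid to be encoded by the same codon — or by codons decoded by
the same tRNA isoacceptor — more often than positional independence
predicts. That bias is the genomic signature of tRNA recycling at the
ribosome: a tRNA recharged near the ribosome can be reused at the next
occurrence of a codon it reads. The package is aimed at researchers in
codon usage, translational efficiency and tRNA biology who want to
quantify this bias in any annotated genome, and at methodologists who
want a calibrated, fully seeded re-implementation of the measurement.

## What it computes

For each synonymous codon family (the 6-fold amino acids split by
degeneracy rules into quartet + doublet: Ser4 = TCN, Ser2 = AGY, Arg4 =
CGN, Arg2 = AGR, Leu4 = CTN, Leu2 = TTR; 21 blocks over 18 amino acids),
the pipeline tabulates ordered codon-pair co-occurrence counts
*C<sub>ij</sub>* within genes and compares them with the independence
expectation

> *E<sub>ij</sub> = N · f<sub>i</sub> · f<sub>j</sub>*

(*N* = class occurrence total, *f* = codon frequencies), using three
statistics per ordered pair:

* **percent deviation** 100 · (*C* − *E*) / *E*;
* **binomial z** (*C* − *E*) / √(*N p* (1 − *p*)), *p* = *f<sub>i</sub> f<sub>j</sub>*;
* **log2 ratio** of joint over product-of-marginal pair probabilities,
  located as a quantile in a Monte-Carlo **empirical null** built from
  random sequences drawn at the family's codon frequencies (default
  5000 replicates of 1000 residues); pairs at quantile ≥ 0.95 with
  positive deviation are flagged.

A synthetic-genome generator with a tunable tRNA-reuse probability ρ
(first-order Markov reuse of the previous synonymous codon, or of its
co-tRNA group) provides ground truth: under consecutive pairing its
diagonal percent deviation is exactly 100 · ρ · (1 − *f*) / *f*, which
the pipeline recovers to within ±0.03 in ρ.

## Worked example

Simulate a 500-gene genome with 20% tRNA reuse, then analyze it:

```r
library(codonreuse)

cfg <- synthetic_config(n_genes = 500, gene_length = 300, rho = 0.2, seed = 7)
sim <- simulate_genome(cfg, "demo")
res <- analyze("demo/genome.fasta", "demo/analysis",
               normalization = "pair_total", null_B = 500, null_L = 1000,
               seed = 8)
res
#> <analysis_result> 500 records, 21 families, strategy=consecutive, scope=block
#>   185 ordered pairs tabulated; 59 flagged at q >= 0.95

subset(res$table, family == "Ser4" & codon_i == codon_j)
#>  codon_i codon_j count  pct_dev         z quantile significant
#>      TCA     TCA   388 55.95253  9.144621        1        TRUE
#>      TCC     TCC   397 67.85001 10.792537        1        TRUE
#>      TCG     TCG   372 64.37574 10.001408        1        TRUE
#>      TCT     TCT   354 79.66572 11.499153        1        TRUE

estimate_rho(res$per_family$Ser4$table, res$per_family$Ser4$profile)$rho_hat
#> [1] 0.2207763
```

Every Ser4 diagonal cell is strongly over-represented (the analytic
expectation at ρ = 0.2 and uniform f = 0.25 is +60%), each sits at the
top of its empirical null (quantile 1.0), and inverting the diagonal
enrichment recovers the simulated reuse probability (0.22 vs 0.2). The
written output (`demo/analysis/`) contains, per family, four aligned
blocks — counts, expected counts, percent deviation (3 decimals),
quantiles — plus a combined long table, per-strategy block totals and a
run log echoing every parameter.

Real genomes enter the same way: `analyze("genome.gb", "out")` accepts a
GenBank flat file (minus-strand and `join` CDS locations resolved to
mRNA sense; partial and pseudo features excluded by default). A thin
command-line wrapper is installed at
`system.file("scripts", "codon-pairing.R", package = "codonreuse")`.

## A note on raw pair counts

Published pair-count tables are reproducible only relative to a pairing
rule, and the rule is not always stated: in the shipped
*M. thermautotrophicus* Ser/Arg reference table the Ser2 counts block
sums to 3057 ordered pairs against a class total of 2729 occurrences —
more pairs than occurrences, which no consecutive next-occurrence rule
can produce. The package therefore does not promise to reproduce raw
published counts from a genome; it implements three explicit strategies
(`consecutive`, `all_pairs`, `windowed`) and reports each strategy's
block totals (`pair_total_summary()`) so users can compare directly.
The percent-deviation arithmetic is rule-independent and is reproduced
exactly from published counts.

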