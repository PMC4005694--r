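---
title: "Quantifying co-tRNA codon pairing bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-tRNA codon pairing bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonreuse)
```

## The question

During translation a tRNA that has just decoded a codon does not diffuse
away instantly; if it is recharged near the ribosome it can be reused at
the next occurrence of a codon it reads. If that happens at appreciable
rates, selection on translational efficiency should order synonymous
codons within genes so that successive occurrences of the same amino
acid tend to use the *same codon*, or at least codons decoded by the
*same tRNA isoacceptor* (co-tRNA codons). The genomic signature of this
tRNA recycling is co-tRNA codon pairing bias (CTCPB): within each
synonymous codon family, ordered pairs on the diagonal of the
pair-co-occurrence matrix (and co-tRNA off-diagonal cells) are
over-represented relative to positional independence.

`codonreuse` measures that signature in any set of annotated coding
sequences, and ships a generative model of it so every stage of the
measurement can be calibrated against a known truth.

## From genome to pair counts

Coding sequences enter either from a GenBank flat file
(`read_genbank_cds()`; `complement`/`join` locations are resolved to
mRNA sense, partial and `/pseudo` features are excluded by default) or
from a CDS FASTA (`read_fasta_cds()`). `validate_records()` trims the
terminal stop, rejects sequences with internal stops, and masks any
codon containing an ambiguity code — masked codons keep their position
(so occurrence order is preserved) but never enter counts.

The genetic code (NCBI tables 1 or 11; identical codon assignments) is
partitioned by `partition_families()` into synonymous families, with the
three 6-fold amino acids split by degeneracy rules into a quartet and a
doublet (Ser4 = TCN / Ser2 = AGY, Arg4 = CGN / Arg2 = AGR, Leu4 = CTN /
Leu2 = TTR), Ile kept as one 3-codon block, and Met/Trp/stops excluded:
21 blocks over 18 amino acids. Each block's codons are further grouped
by decoding isoacceptor (`cotrna_groups()`); because wobble-position
base modifications cannot be inferred from sequence, the inventory is
plain-text configuration (`read_isoacceptor_config()`), with a shipped
*M. thermautotrophicus* Ser/Arg inventory (`mth_isoacceptors()`) and a
generic wobble-rule fallback (`generic_isoacceptors()`: anticodon G34
reads C/T, U34 reads A/G, C34 reads G, A34 reads T; purine-ending
doublets are split into separate groups when both a C34 and a U34
isoacceptor exist, the usual situation when U34 is modified).

Within each gene, each family's occurrences form an ordered stream
(`family_stream()`), and `count_pairs()` tabulates ordered pairs under
one of three strategies:

* **consecutive** (default) — each occurrence pairs with the next
  occurrence in the same gene; this is the direct reading of the
  recycling hypothesis (could the *next* occurrence reuse the tRNA?);
* **all_pairs** — every ordered pair of occurrences within a gene;
* **windowed** — ordered pairs separated by at most `W` codons.

Gene boundaries are never crossed: recycling is a per-transcript
hypothesis. Pairs are ordered (the matrices are asymmetric). All three
strategies are exposed because published pair-count tables do not always
state their rule, and block totals can be inconsistent with pure
next-occurrence counting (see Limitations); `pair_total_summary()`
reports each strategy's totals so users can compare against any
published table directly.

The default *scope* builds each block's stream independently (Ser4 and
Ser2 separately), matching how such tables are normally tabulated and
normalised; `scope = "amino-acid"` interleaves all codons of the amino
acid into one stream before tabulating within-block pairs, as a
sensitivity analysis.

## The independence model and three statistics

For a family with class total $N$ (occurrences of the block) and codon
frequencies $f_i$, the expected ordered-pair count under positional
independence is

$$E_{ij} = N \cdot f_i f_j .$$

`expected_counts()` offers two normalisations: `class_occurrences`
(default) uses the class total $N$, the conventional definition even
though it is not the number of tabulated pairs; `pair_total` uses
$n_{\text{pairs}}$, under which $\sum_{ij} E_{ij} = n_{\text{pairs}}$
exactly — the properly normalised version used for calibration tests
(the expectation-weighted mean percent deviation is then identically
zero). Both are recorded in output metadata. Expected counts stay
real-valued internally; table rendering rounds for display only.

Each ordered pair gets three deviation statistics:

1. **percent deviation** $100\,(C_{ij}-E_{ij})/E_{ij}$ — sign gives
   direction; rendered to 3 decimals; cells with $E=0$ render `NA`.
2. **binomial z** $(C_{ij}-E_{ij})/\sqrt{N p (1-p)}$, $p = f_i f_j$ —
   deviation in standard-deviation units. Because $\sigma/E \to 0$ as
   $N$ grows, genome-scale counts make even small relative deviations
   score many standard deviations, which motivates the third statistic.
3. **log2 ratio** $\log_2 \frac{(C_{ij}+c)/(n_{\text{pairs}}+ck^2)}{f_i f_j}$
   — the log joint-over-marginals probability ratio, with pseudocount
   $c$ (default 0.5, shared over the $k^2$ cells) guarding empty cells;
   at $c=0$ it equals $\log_2(1 + \text{pct}/100)$ exactly.

## The Monte-Carlo empirical null

Genome-wide codon frequencies vary between genes (e.g. with local GC
content), so an analytic binomial reference can misstate significance.
`simulate_null()` instead draws, per family, $B$ random sequences of
$L$ family occurrences iid from the observed $f$ (defaults $B = 5000$,
$L = 1000$, emulating random 1000-residue protein sequences), scores
the $L-1$ adjacent ordered pairs of each replicate with the same log2
statistic, and stores each pair's sorted null vector.
`observed_quantile()` places the observed log2 ratio as
$(\#\{\text{null} \le \text{obs}\})/B$ — a weak-inequality quantile,
ties counted in, stated explicitly because the convention affects
boundary behaviour. `flag_significant()` marks pairs with quantile
$\ge$ threshold (default 0.95) *and* positive percent deviation: only
over-representation is evidence of reuse. No multiple-testing
correction is applied across pairs; the flag is the empirical-quantile
rule alone.

The null replicates are freshly generated sequences, not resampled
genes; the genome-side pairing strategy is deliberately *not* applied
to the null, whose pairs are simply adjacent draws of an iid sequence.
Note the null's sampling noise is that of an $L$-residue sequence; at
genome scale the observed statistic has far less noise, so on
reuse-free data observed quantiles concentrate near 0.5 and the flagged
fraction at 0.95 stays well below 5% (verified in the test suite on a
2000-gene × 300-codon reuse-free synthetic genome; quantile uniformity
is checked by drawing probe replicates from the null process itself,
pooling the per-pair quantiles of all 2-codon families — 200 probes,
Kolmogorov–Smirnov statistic below 0.05).

## The synthetic genome generator

`generate_genome()` emulates exactly the process the statistics are
meant to detect. Amino-acid (family) identities are drawn iid from a
background composition — uniform over the 18 analyzed amino acids by
default, with 6-fold amino acids splitting their weight equally between
quartet and doublet, because the reuse chain is defined on family
streams. Within a gene, a family's first occurrence draws its codon
from $f$; each later occurrence, with probability $\rho$, *reuses*
(identical mode: repeats the previous codon; cotrna mode: draws
uniformly within the previous codon's co-tRNA group), else draws afresh
from $f$. An ATG is prepended and a TAA appended so the FASTA re-enters
the pipeline unchanged. Identical configuration and seed give
byte-identical output.

In identical mode the chain's transition kernel is
$P(i \to i) = \rho + (1-\rho) f_i$ and its stationary distribution is
$f$ — marginal codon usage is preserved for every $\rho$ (realized
counts do fluctuate more than iid draws: successive occurrences are
autocorrelated, inflating count variance by $(1+\rho)/(1-\rho)$, which
the recovery tests account for). Under consecutive pairing and
pair-total normalisation the expected diagonal percent deviation has
the closed form

$$\text{pct}_{ii} = 100\,\rho\,(1-f_i)/f_i$$

(`analytic_diagonal_pct()`), e.g. 60 for $\rho = 0.2$ at uniform
$f = 0.25$; inverting it per diagonal cell gives the estimator
`estimate_rho()`, which recovers $\rho$ to within ±0.03 at $10^5$ class
occurrences in the test suite ($\rho \in \{0, 0.15, 0.3\}$, 250 genes ×
400 codons of a single 4-codon family).

What the generator does *not* emulate: amino-acid autocorrelation and
composition clustering along real proteins, inter-gene codon-usage
heterogeneity (GC gradients, expression-level adaptation), and any
ribosome kinetics. Passing calibration on synthetic data therefore
shows the *statistics* are correct under the stated model, not that
real genomes satisfy the model's independence assumptions — that is
precisely why the empirical null exists on the real-data path.

## Numerical and design choices

* **Seeds.** Every stochastic stage takes an explicit seed
  (`analyze_genome()` seeds one RNG stream and processes families in
  name order), so `analyze(simulate(config))` is byte-reproducible.
* **Pseudocount** default 0.5 (half a count per cell); set 0 for the
  bare log2 definition. The observed table and its null must use the
  same value, which `analyze_genome()` enforces.
* **Degenerate inputs.** Empty families are flagged and skipped with
  warnings, never errors; single-codon frequency vectors skip the null;
  $E=0$ cells render `NA`, never 0.
* **Problem sizes in the shipped tests** were chosen as the smallest
  that leave comfortable statistical margins: null calibration on a
  2000 × 300-codon genome at $B = 500$ (the analysis default is
  $B = 5000$), recovery at $10^5$ class occurrences, counting oracle on
  200 random genomes of up to 20 × 50 codons.
* **Open-ended choices.** Partial and pseudo CDS default to excluded
  (the toggles exist); Ile stays one block; the Arg4 isoacceptor
  assignment (CGC/CGT to GCG, CGA/CGG to TCG) is configuration, not an
  assertion, since two-isoacceptor 4-fold blocks admit alternative
  wobble readings.

## Limitations

Raw pair-count tables are reproducible only relative to a pairing rule.
For the *M. thermautotrophicus* reference values shipped with the
package the published Ser2 block sums to 3057 tabulated pairs against a
class total of 2729 — more pairs than occurrences, which no
next-occurrence rule can produce — so the exact published counting rule
cannot be reconstructed, and the package does not claim to reproduce
raw counts from the genome. The percent-deviation arithmetic is
rule-independent and is reproduced exactly; for counts, use
`pair_total_summary()` to compare each strategy's block totals against
any published table.
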