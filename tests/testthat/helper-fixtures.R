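# Shared fixtures and independent oracles, built in code at test time.

# two-gene GenBank flat file: geneA plus strand at 4..12, geneB on the
# minus strand (genomic text TTATGACAT at 21..29, mRNA sense ATGTCATAA)
write_genbank_fixture <- function(path) {
  seq60 <- paste0("NNNATGTCATAANNNNNNNN", "TTATGACAT",
                  strrep("N", 31))
  stopifnot(nchar(seq60) == 60L)
  writeLines(c(
    "LOCUS       TESTSEQ1                 60 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  synthetic two-gene test sequence.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             4..12",
    '                     /locus_tag="geneA"',
    "     CDS             complement(21..29)",
    '                     /locus_tag="geneB"',
    "ORIGIN",
    paste0("        1 ", tolower(seq60)),
    "//"), path)
  path
}

# GenBank file exercising join, partial and pseudo features
write_genbank_edge_fixture <- function(path) {
  # join(4..9,13..15) -> ATGTCA + TAA
  seq45 <- paste0("NNNATGTCANNNTAAN", "ATGAAATAG", strrep("N", 20))
  stopifnot(nchar(seq45) == 45L)
  writeLines(c(
    "LOCUS       TESTSEQ2                 45 bp    DNA     linear   BCT 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(4..9,13..15)",
    '                     /locus_tag="geneJ"',
    "     CDS             <17..25",
    '                     /locus_tag="genePartial"',
    "     CDS             17..25",
    '                     /locus_tag="genePseudo"',
    "                     /pseudo",
    "     CDS             4..11",
    '                     /locus_tag="geneBadLen"',
    "ORIGIN",
    paste0("        1 ", seq45),
    "//"), path)
  path
}

mk_record <- function(codons, id = "g", masked = integer()) {
  codonreuse:::new_cds_record(id, codons, masked_positions = masked)
}

# independent O(n^2) oracle: enumerate all occurrence index pairs of a
# family within each record and filter by the strategy predicate
brute_force_pairs <- function(records, family, strategy, window = NULL) {
  codons <- family$codons
  k <- length(codons)
  counts <- matrix(0L, k, k, dimnames = list(codons, codons))
  n_pairs <- 0L
  for (r in records) {
    keep <- r$codons %in% codons
    if (length(r$masked_positions)) keep[r$masked_positions] <- FALSE
    occ_idx <- which(keep)
    occ <- r$codons[occ_idx]
    m <- length(occ)
    if (m < 2L) next
    for (s in seq_len(m - 1L)) for (t in seq((s + 1L), m)) {
      ok <- switch(strategy,
                   consecutive = t == s + 1L,
                   all_pairs = TRUE,
                   windowed = (occ_idx[t] - occ_idx[s]) <= window)
      if (ok) {
        counts[occ[s], occ[t]] <- counts[occ[s], occ[t]] + 1L
        n_pairs <- n_pairs + 1L
      }
    }
  }
  list(counts = counts, n_pairs = n_pairs)
}

# random small genome of codon soup (valid CDS records, no stops inside)
random_genome <- function(n_genes, max_len = 50L, code = standard_code(11)) {
  sense <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
  lapply(seq_len(n_genes), function(g) {
    len <- sample(2:max_len, 1L)
    mk_record(sample(sense, len, replace = TRUE), sprintf("r%03d", g))
  })
}

ALL_FAMILIES <- partition_families(standard_code(11))
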