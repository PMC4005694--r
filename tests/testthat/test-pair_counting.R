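test_that("family streams extract in-order unmasked occurrences", {
  fams <- ALL_FAMILIES
  rec <- mk_record(c("ATG", "TCA", "GGC", "TCA", "TCT", "AGC"))
  s4 <- family_stream(rec, fams$Ser4)
  expect_identical(s4$codons, c("TCA", "TCA", "TCT"))
  expect_identical(s4$index, c(2L, 4L, 5L))
  s2 <- family_stream(rec, fams$Ser2)
  expect_identical(s2$codons, "AGC")
  expect_identical(s2$index, 6L)
  expect_length(family_stream(mk_record(c("ATG", "GGC")), fams$Ser4)$codons,
                0L)
  # masked occurrences are excluded
  recm <- mk_record(c("TCA", "TCA", "TCT"), masked = 2L)
  expect_identical(family_stream(recm, fams$Ser4)$codons, c("TCA", "TCT"))
})

test_that("count_pairs matches the hand-enumerated examples", {
  fams <- ALL_FAMILIES
  rec <- mk_record(c("TCA", "TCA", "TCT"))
  st <- family_stream(rec, fams$Ser4)
  cons <- count_pairs(st, "consecutive", codons = fams$Ser4$codons)
  expect_identical(cons$counts["TCA", "TCA"], 1L)
  expect_identical(cons$counts["TCA", "TCT"], 1L)
  expect_identical(cons$n_pairs, 2L)
  ap <- count_pairs(st, "all_pairs", codons = fams$Ser4$codons)
  expect_identical(ap$counts["TCA", "TCA"], 1L)
  expect_identical(ap$counts["TCA", "TCT"], 2L)
  expect_identical(ap$n_pairs, 3L)
  # single occurrence -> zero table under any strategy
  single <- family_stream(mk_record("TCA"), fams$Ser4)
  for (strat in c("consecutive", "all_pairs"))
    expect_identical(count_pairs(single, strat,
                                 codons = fams$Ser4$codons)$n_pairs, 0L)
  # windowed counting respects the codon-index distance
  rec2 <- mk_record(c("TCA", "GGC", "GGC", "TCT"))
  st2 <- family_stream(rec2, fams$Ser4)
  w2 <- count_pairs(st2, "windowed", window = 2L, codons = fams$Ser4$codons)
  expect_identical(w2$n_pairs, 0L)  # separation is 3 codons
  w3 <- count_pairs(st2, "windowed", window = 3L, codons = fams$Ser4$codons)
  expect_identical(w3$counts["TCA", "TCT"], 1L)
})

test_that("mixed-family streams and bad windows are rejected", {
  fams <- ALL_FAMILIES
  rec <- mk_record(c("TCA", "AGC", "TCA"))
  s4 <- family_stream(rec, fams$Ser4)
  s2 <- family_stream(rec, fams$Ser2)
  expect_error(count_pairs(list(s4, s2)), "mix")
  expect_error(count_pairs(s4, "windowed"), "window")
})

test_that("count_pairs equals the brute-force oracle on random genomes", {
  set.seed(101)
  fams <- ALL_FAMILIES[c("Ser4", "Ser2", "Arg4", "Ile3")]
  for (g in 1:40) {
    genome <- random_genome(n_genes = sample(1:8, 1), max_len = 40L)
    fam <- fams[[sample(length(fams), 1)]]
    strat <- sample(c("consecutive", "all_pairs", "windowed"), 1)
    W <- sample(1:12, 1)
    streams <- lapply(genome, family_stream, family = fam)
    got <- count_pairs(streams, strat, window = W, codons = fam$codons)
    want <- brute_force_pairs(genome, fam, strat, W)
    expect_identical(got$counts, want$counts)
    expect_identical(got$n_pairs, want$n_pairs)
  }
})

test_that("consecutive counting obeys its marginal identities", {
  set.seed(202)
  fams <- ALL_FAMILIES
  genome <- random_genome(n_genes = 12, max_len = 50L)
  for (fam in fams[c("Ser4", "Gly4", "Lys2")]) {
    streams <- lapply(genome, family_stream, family = fam)
    tab <- count_pairs(streams, "consecutive", codons = fam$codons)
    k_g <- vapply(streams, function(s) length(s$codons), 0L)
    expect_identical(tab$n_pairs, sum(pmax(0L, k_g - 1L)))
    # row sums equal per-codon non-terminal occurrence counts
    nonterm <- table(factor(unlist(lapply(streams, function(s)
      utils::head(s$codons, -1L))), levels = fam$codons))
    expect_identical(rowSums(tab$counts), stats::setNames(
      as.numeric(nonterm), fam$codons))
  }
})

test_that("class profiles count unmasked occurrences and normalise", {
  fams <- ALL_FAMILIES
  recs <- list(mk_record(c("TCA", "GGC", "TCA")),
               mk_record(c("TCT", "ATG")))
  prof <- class_profile(recs, fams$Ser4)
  expect_identical(prof$N, 3L)
  expect_equal(prof$f, c(TCA = 2 / 3, TCC = 0, TCG = 0, TCT = 1 / 3))
  expect_equal(sum(prof$f), 1, tolerance = 1e-12)
  # masked occurrence decrements N
  recs2 <- list(mk_record(c("TCA", "TCA"), masked = 1L))
  expect_identical(class_profile(recs2, fams$Ser4)$N, 1L)
  # empty profile is flagged with a warning
  expect_warning(p0 <- class_profile(list(mk_record("ATG")), fams$Ser4),
                 "no occurrences")
  expect_true(p0$empty)
})

test_that("pair_total_summary reports per-strategy totals for each family", {
  set.seed(7)
  genome <- random_genome(n_genes = 6, max_len = 30L)
  fams <- ALL_FAMILIES[c("Ser4", "Ser2")]
  tot <- pair_total_summary(genome, fams, window = 5L)
  expect_identical(tot$family, c("Ser4", "Ser2"))
  for (i in seq_len(nrow(tot))) {
    fam <- fams[[tot$family[i]]]
    for (strat in c("consecutive", "all_pairs", "windowed")) {
      want <- brute_force_pairs(genome, fam, strat, 5L)$n_pairs
      expect_identical(tot[[paste0("n_pairs_", strat)]][i], want)
    }
  }
})
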