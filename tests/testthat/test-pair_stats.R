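ser2_profile <- function() {
  rec <- mk_record(c(rep("AGC", 1637), rep("AGT", 1092)))
  class_profile(list(rec), ALL_FAMILIES$Ser2)
}

test_that("expected counts follow E = N * f_i * f_j in both normalisations", {
  prof <- ser2_profile()
  E <- expected_counts(prof, "class_occurrences")
  expect_equal(E$N_used, 2729)
  expect_equal(E$expected["AGC", "AGC"], 1637^2 / 2729, tolerance = 1e-12)
  expect_equal(round(E$expected["AGC", "AGC"]), 982)
  expect_equal(round(E$expected["AGC", "AGT"]), 655)
  expect_equal(round(E$expected["AGT", "AGT"]), 437)
  expect_equal(sum(E$expected), E$N_used, tolerance = 1e-9 * E$N_used)
  # uniform frequencies: every cell N / k^2
  unif <- class_profile(list(mk_record(rep(ALL_FAMILIES$Ser4$codons, 400))),
                        ALL_FAMILIES$Ser4)
  Eu <- expected_counts(unif, "class_occurrences")
  expect_true(all(abs(Eu$expected - 100) < 1e-9))
  # degenerate single-codon profile: E = N on the occupied cell
  one <- class_profile(list(mk_record(rep("AGC", 50))), ALL_FAMILIES$Ser2)
  E1 <- expected_counts(one, "class_occurrences")
  expect_equal(E1$expected["AGC", "AGC"], 50)
  # pair_total normalisation sums to the tabulated pair count
  st <- family_stream(mk_record(rep(c("AGC", "AGT"), 10)),
                      ALL_FAMILIES$Ser2)
  pairs <- count_pairs(st, "consecutive", codons = ALL_FAMILIES$Ser2$codons)
  Ep <- expected_counts(prof, "pair_total", pairs)
  expect_equal(sum(Ep$expected), pairs$n_pairs, tolerance = 1e-9)
})

test_that("percent deviation reproduces the published reference cells", {
  ref <- mth_reference_pairs()
  pct <- percent_deviation(ref$count, ref$expected)
  cell <- function(fam, i, j)
    round(pct[ref$family == fam & ref$codon_i == i & ref$codon_j == j], 3)
  expect_equal(cell("Ser4", "TCA", "TCA"), 4.993)
  expect_equal(cell("Ser2", "AGC", "AGC"), 17.006)
  expect_equal(cell("Ser4", "TCT", "TCT"), 21.951)
  expect_equal(cell("Arg4", "CGG", "CGG"), 29.697)
  expect_equal(cell("Ser2", "AGT", "AGT"), 17.391)
  expect_equal(cell("Arg4", "CGC", "CGC"), 29.762)
  expect_equal(percent_deviation(100, 100), 0)
  expect_warning(u <- percent_deviation(3, 0), "undefined")
  expect_true(is.na(u))
})

test_that("binomial z matches direct evaluation and its scaling law", {
  N <- 14857
  f <- sqrt(3505 / N)
  expect_equal(binomial_z(3680, 3505, N, f, f), 3.382, tolerance = 5e-4)
  expect_equal(binomial_z(500, 500, 1000, 0.5, 0.5), 0)
  # doubling N at fixed frequencies and fixed pct scales z by sqrt(2)
  z1 <- binomial_z(120, 100, 1600, 0.25, 0.25)
  z2 <- binomial_z(240, 200, 3200, 0.25, 0.25)
  expect_equal(z2, sqrt(2) * z1, tolerance = 1e-12)
  expect_true(is.na(binomial_z(5, 0, 100, 0, 0.5)))
})

test_that("log2 ratio agrees with log2(1 + pct/100) at zero pseudocount", {
  expect_equal(log2_norm(3680, 14857, sqrt(3505 / 14857), sqrt(3505 / 14857),
                         4, pseudocount = 0),
               log2(3680 / 3505), tolerance = 1e-12)
  expect_equal(log2(3680 / 3505), 0.0703, tolerance = 5e-4)
  # independence: C/n exactly f_i f_j -> 0
  expect_equal(log2_norm(25, 400, 0.25, 0.25, 4, pseudocount = 0), 0)
  # pseudocount keeps zero counts finite
  expect_true(is.finite(log2_norm(0, 400, 0.25, 0.25, 4, pseudocount = 0.5)))
  set.seed(11)
  # identity holds across a whole random table (pair_total normalisation)
  genome <- random_genome(10, 40)
  fam <- ALL_FAMILIES$Gly4
  streams <- lapply(genome, family_stream, family = fam)
  pairs <- count_pairs(streams, "consecutive", codons = fam$codons)
  prof <- class_profile(genome, fam)
  E <- expected_counts(prof, "pair_total", pairs)
  tab <- assemble_deviation_table(pairs, E, prof, pseudocount = 0)
  pos <- tab$count > 0
  expect_equal(tab$log2norm[pos], log2(1 + tab$pct_dev[pos] / 100),
               tolerance = 1e-12)
  # expectation-weighted mean percent deviation vanishes under pair_total
  expect_equal(sum(tab$expected * tab$pct_dev) / sum(tab$expected), 0,
               tolerance = 1e-9)
})

test_that("assembled tables reproduce the full published Ser2 block", {
  ref <- mth_reference_pairs()
  ser2 <- ref[ref$family == "Ser2", ]
  prof <- ser2_profile()
  counts <- matrix(ser2$count, 2, 2, byrow = TRUE,
                   dimnames = list(c("AGC", "AGT"), c("AGC", "AGT")))
  pairs <- structure(list(family = "Ser2", counts = counts,
                          strategy = "consecutive", window = NA_integer_,
                          n_pairs = sum(counts)),
                     class = "pair_count_table")
  E <- expected_counts(prof, "class_occurrences")
  # published expectations are the rounded version of ours
  expect_equal(round(as.vector(t(E$expected))), ser2$expected)
  tab <- assemble_deviation_table(pairs, E, prof)
  # against the printed (rounded) expectations the printed cells return
  pct_printed <- round(percent_deviation(ser2$count, ser2$expected), 3)
  expect_equal(pct_printed, c(17.006, 9.618, 3.359, 17.391))
  # against full-precision expectations the same cells agree closely
  expect_equal(tab$pct_dev, pct_printed, tolerance = 2e-3)
  expect_identical(tab$codon_i, c("AGC", "AGC", "AGT", "AGT"))
  # identity input: C = E everywhere -> all statistics zero
  pairs0 <- pairs
  pairs0$counts <- round(E$expected)
  pairs0$n_pairs <- sum(pairs0$counts)
  tab0 <- assemble_deviation_table(pairs0, E, prof)
  expect_true(all(abs(tab0$pct_dev) < 0.2))  # only count rounding remains
  expect_true(all(abs(tab0$z) < 0.05))
  # empty family -> empty table
  expect_warning(p0 <- class_profile(list(mk_record("ATG")),
                                     ALL_FAMILIES$Ser2))
  expect_identical(nrow(assemble_deviation_table(pairs, NULL, p0)), 0L)
})

test_that("z scores are calibrated on reuse-free simulated data", {
  cfg <- synthetic_config(n_genes = 300, gene_length = 300, rho = 0,
                          seed = 97)
  g <- generate_genome(cfg)
  res <- analyze_genome(g$records, normalization = "pair_total",
                        null_B = 0)
  z <- res$table$z
  expect_gt(min(attr(res$per_family$Ser4$table, "n_pairs"),
                attr(res$per_family$Lys2$table, "n_pairs")), 1e3)
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(stats::sd(z), 0.8)
  expect_lt(stats::sd(z), 1.2)
})
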