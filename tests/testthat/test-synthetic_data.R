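test_that("analytic diagonal pct matches its closed form", {
  expect_equal(analytic_diagonal_pct(0, 0.3), 0)
  expect_equal(analytic_diagonal_pct(0.2, 0.25), 60)
  expect_equal(analytic_diagonal_pct(0.5, 0.5), 50)
  expect_error(analytic_diagonal_pct(0.2, 1), "inside")
})

test_that("configuration validation rejects inconsistent inputs", {
  expect_error(synthetic_config(rho = 1.5), "rho")
  expect_error(synthetic_config(rho = -0.1), "rho")
  fams <- ALL_FAMILIES["Ser2"]
  expect_error(synthetic_config(families = fams,
                                family_freqs = list(Ser2 = c(0.5, 0.4))),
               "inconsistent")
  expect_error(synthetic_config(families = fams,
                                family_freqs = list(Ser2 = c(XXX = 0.5,
                                                             YYY = 0.5))),
               "codons")
})

test_that("full reuse makes every consecutive family pair identical", {
  cfg <- synthetic_config(n_genes = 30, gene_length = 150, rho = 1,
                          reuse_mode = "identical", seed = 13)
  g <- generate_genome(cfg)
  for (fam in ALL_FAMILIES[c("Ser4", "Arg2", "Val4")]) {
    streams <- lapply(g$records, family_stream, family = fam)
    tab <- count_pairs(streams, "consecutive", codons = fam$codons)
    off <- tab$counts
    diag(off) <- 0L
    expect_identical(sum(off), 0L)
    expect_gt(sum(diag(tab$counts)), 0L)
  }
})

test_that("cotrna reuse keeps consecutive pairs within one co-tRNA group", {
  fams <- ALL_FAMILIES[c("Ser4", "Ser2", "Arg4", "Arg2")]
  iso <- mth_isoacceptors()
  cfg <- synthetic_config(n_genes = 30, gene_length = 150, rho = 1,
                          families = fams, reuse_mode = "cotrna",
                          iso = iso, seed = 19)
  g <- generate_genome(cfg)
  for (fam in fams) {
    groups <- cotrna_groups(fam, iso)
    grp_of <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                              unlist(groups))
    for (rec in g$records) {
      s <- family_stream(rec, fam)
      if (length(s$codons) < 2L) next
      gs <- grp_of[s$codons]
      expect_true(all(gs[-1] == gs[-length(gs)]))
    }
  }
})

test_that("no-reuse genomes show no diagonal enrichment", {
  fams <- ALL_FAMILIES["Val4"]
  cfg <- synthetic_config(n_genes = 150, gene_length = 300, families = fams,
                          background = c(Val4 = 1), rho = 0, seed = 29)
  g <- generate_genome(cfg)
  prof <- class_profile(g$records, fams$Val4)
  streams <- lapply(g$records, family_stream, family = fams$Val4)
  pairs <- count_pairs(streams, "consecutive", codons = fams$Val4$codons)
  tab <- assemble_deviation_table(
    pairs, expected_counts(prof, "pair_total", pairs), prof)
  dg <- tab$pct_dev[tab$codon_i == tab$codon_j]
  f <- prof$f
  p <- f^2
  se <- 100 * sqrt(p * (1 - p) / pairs$n_pairs) / p
  expect_true(all(abs(dg) < 3 * se))
})

test_that("the reuse chain preserves marginal codon frequencies", {
  fams <- ALL_FAMILIES["Ser4"]
  fr <- list(Ser4 = c(TCA = 0.5, TCC = 0.3, TCG = 0.15, TCT = 0.05))
  for (rho in c(0, 0.5, 0.9)) {
    cfg <- synthetic_config(n_genes = 100, gene_length = 300,
                            families = fams, family_freqs = fr,
                            background = c(Ser4 = 1), rho = rho, seed = 37)
    g <- generate_genome(cfg)
    counts <- g$truth$realized_counts$Ser4
    N <- sum(counts)
    # reuse runs autocorrelate successive draws: var inflated by (1+rho)/(1-rho)
    infl <- sqrt((1 + rho) / (1 - rho))
    for (cod in names(counts)) {
      se <- sqrt(N * fr$Ser4[cod] * (1 - fr$Ser4[cod])) * infl
      expect_lt(abs(counts[cod] - N * fr$Ser4[cod]), 4 * se)
    }
  }
})

test_that("rho is recovered from the analyzed synthetic genome", {
  fams <- ALL_FAMILIES["Val4"]
  cfg <- synthetic_config(n_genes = 120, gene_length = 300, families = fams,
                          background = c(Val4 = 1), rho = 0.25, seed = 43)
  g <- generate_genome(cfg)
  prof <- class_profile(g$records, fams$Val4)
  streams <- lapply(g$records, family_stream, family = fams$Val4)
  pairs <- count_pairs(streams, "consecutive", codons = fams$Val4$codons)
  tab <- assemble_deviation_table(
    pairs, expected_counts(prof, "pair_total", pairs), prof)
  rho_hat <- estimate_rho(tab, prof)$rho_hat
  expect_lt(abs(rho_hat - 0.25), 0.03)
})

test_that("identical configuration and seed give byte-identical FASTA", {
  cfg <- synthetic_config(n_genes = 15, gene_length = c(50, 120), rho = 0.3,
                          seed = 51)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_genome(cfg, d1)
  simulate_genome(cfg, d2)
  expect_identical(readLines(file.path(d1, "genome.fasta")),
                   readLines(file.path(d2, "genome.fasta")))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
  # generated genomes are valid genome_io input
  recs <- validate_records(read_fasta_cds(file.path(d1, "genome.fasta")))
  expect_length(recs, 15L)
  expect_true(all(vapply(recs, function(r) r$codons[1] == "ATG", TRUE)))
})
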