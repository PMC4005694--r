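# Synthetic genomes with a known first-order synonymous-codon reuse process.

#' Synthetic genome configuration
#'
#' Defines a genome of protein-coding genes whose successive
#' synonymous-codon choices follow a first-order reuse (Markov) process:
#' within each gene, the first occurrence of a family draws its codon
#' from the family's frequency vector f; every subsequent occurrence of
#' the same family either reuses tRNA-compatible coding with probability
#' \code{rho} (identical mode: repeat the previous codon; cotrna mode:
#' draw uniformly within the previous codon's co-tRNA group) or draws
#' afresh from f. The chain's stationary distribution is f in identical
#' mode, so marginal codon usage is preserved for every rho.
#'
#' @param n_genes Number of genes.
#' @param gene_length Codons per gene (amino-acid positions, excluding
#'   the prepended ATG and appended stop); a length-2 vector gives a
#'   uniform integer draw in [min, max].
#' @param families List of \code{synonymous_family} objects to simulate
#'   over (default: the full split-6-fold partition, 21 blocks over the
#'   18 multi-codon amino acids).
#' @param family_freqs Named list, family name -> frequency vector over
#'   that family's codons (default uniform within each family).
#' @param rho Reuse probability in [0, 1].
#' @param reuse_mode \code{"identical"} or \code{"cotrna"}.
#' @param background Named numeric, weight of each family in the
#'   amino-acid-level composition (default uniform over the 18 amino
#'   acids, 6-fold amino acids splitting their weight equally between
#'   their quartet and doublet blocks).
#' @param iso Isoacceptor map used for co-tRNA groups in cotrna mode
#'   (default \code{\link{generic_isoacceptors}} of the families).
#' @param seed Integer seed.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_genes = 200L, gene_length = 300L,
                             families = partition_families(standard_code(11)),
                             family_freqs = NULL, rho = 0,
                             reuse_mode = c("identical", "cotrna"),
                             background = NULL, iso = NULL, seed = 1L) {
  reuse_mode <- match.arg(reuse_mode)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop("rho must be a single probability in [0, 1]")
  stopifnot(n_genes >= 1L, all(gene_length >= 1L),
            length(gene_length) %in% c(1L, 2L))
  fam_names <- vapply(families, `[[`, "", "name")
  names(families) <- fam_names
  if (is.null(family_freqs)) {
    family_freqs <- lapply(families, function(f)
      stats::setNames(rep(1 / f$degeneracy, f$degeneracy), f$codons))
  }
  for (nm in fam_names) {
    fv <- family_freqs[[nm]]
    if (is.null(fv) || length(fv) != families[[nm]]$degeneracy ||
        abs(sum(fv) - 1) > 1e-8)
      stop("family_freqs inconsistent with family definition: ", nm)
    if (is.null(names(fv))) names(family_freqs[[nm]]) <- families[[nm]]$codons
    else if (!setequal(names(fv), families[[nm]]$codons))
      stop("family_freqs codons do not match family ", nm)
  }
  if (is.null(background)) {
    aa <- vapply(families, `[[`, "", "amino_acid")
    per_aa <- 1 / length(unique(aa))
    background <- stats::setNames(per_aa / as.vector(table(aa)[aa]), fam_names)
  }
  if (is.null(names(background)) || !setequal(names(background), fam_names))
    stop("background must be named by family")
  background <- background[fam_names] / sum(background)
  if (is.null(iso)) iso <- generic_isoacceptors(families)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 families = families, family_freqs = family_freqs,
                 rho = rho, reuse_mode = reuse_mode,
                 background = background, iso = iso,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# vectorised reuse chain over one family's occurrences across the whole
# genome: `first` marks each gene's first occurrence, where a fresh draw
# is forced (chains never cross gene boundaries)
reuse_chain <- function(n, first, f, rho, mode, groups) {
  k <- length(f)
  fresh <- stats::runif(n) >= rho
  fresh[first] <- TRUE
  draw <- sample.int(k, n, replace = TRUE, prob = f)
  idx <- which(fresh)
  src <- idx[cumsum(fresh)]           # index of the governing fresh draw
  codon <- draw[src]
  if (mode == "cotrna" && any(!fresh)) {
    grp_of <- integer(k)
    for (g in seq_along(groups)) grp_of[groups[[g]]] <- g
    glen <- lengths(groups)
    reuse_pos <- which(!fresh)
    g <- grp_of[codon[reuse_pos]]
    pick <- ceiling(stats::runif(length(reuse_pos)) * glen[g])
    memb <- matrix(NA_integer_, length(groups), max(glen))
    for (gg in seq_along(groups)) memb[gg, seq_len(glen[gg])] <- groups[[gg]]
    codon[reuse_pos] <- memb[cbind(g, pick)]
  }
  codon
}

#' Generate a synthetic genome
#'
#' Draws each gene's amino-acid (family) sequence iid from the background
#' composition, then fills in codons with the per-family reuse chain of
#' the configuration (see \code{\link{synthetic_config}}). An ATG start
#' is prepended and a TAA stop appended to every gene, so the output is
#' valid input for \code{\link{read_fasta_cds}} +
#' \code{\link{validate_records}}.
#'
#' @param config A \code{synthetic_config}.
#' @return List with \code{records} (list of \code{cds_record}) and
#'   \code{truth} (a \code{truth_record}: config echo, realized per-family
#'   codon counts, analytic expected diagonal percent deviations under
#'   identical-mode consecutive pairing with pair-total normalisation).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  fams <- config$families
  fam_names <- names(fams)
  n_genes <- config$n_genes
  lens <- if (length(config$gene_length) == 2L)
    sample.int(config$gene_length[2] - config$gene_length[1] + 1L,
               n_genes, replace = TRUE) + config$gene_length[1] - 1L
  else rep.int(config$gene_length, n_genes)
  total <- sum(lens)
  gene_of <- rep.int(seq_len(n_genes), lens)
  fam_seq <- sample.int(length(fams), total, replace = TRUE,
                        prob = config$background)
  codon_chr <- character(total)
  realized <- list()
  for (fi in seq_along(fams)) {
    fam <- fams[[fi]]
    pos <- which(fam_seq == fi)
    if (!length(pos)) {
      realized[[fam$name]] <- stats::setNames(integer(fam$degeneracy),
                                              fam$codons)
      next
    }
    f <- config$family_freqs[[fam$name]][fam$codons]
    first <- c(TRUE, gene_of[pos][-1L] != gene_of[pos][-length(pos)])
    groups <- NULL
    if (config$reuse_mode == "cotrna") {
      groups <- lapply(cotrna_groups(fam, config$iso), match, table = fam$codons)
    }
    ids <- reuse_chain(length(pos), which(first), f, config$rho,
                       config$reuse_mode, groups)
    codon_chr[pos] <- fam$codons[ids]
    realized[[fam$name]] <- stats::setNames(
      tabulate(ids, nbins = fam$degeneracy), fam$codons)
  }
  gene_codons <- split(codon_chr, gene_of)
  records <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    records[[g]] <- new_cds_record(sprintf("synth_%05d", g),
                                   c("ATG", gene_codons[[g]], "TAA"))
  }
  truth <- structure(list(
    config = config,
    realized_counts = realized,
    analytic_diag_pct = lapply(config$family_freqs, function(f)
      vapply(f, function(fi) analytic_diagonal_pct(config$rho, fi), 0))),
    class = "truth_record")
  list(records = records, truth = truth)
}

#' Analytic diagonal percent deviation of the reuse process
#'
#' Under identical-mode reuse with probability rho, consecutive pairing
#' and pair-total normalisation, the transition probability to the same
#' codon is P(i -> i) = rho + (1 - rho) f_i, so the diagonal percent
#' deviation from the independence expectation f_i^2 is
#' 100 * rho * (1 - f_i) / f_i. Serves as the closed-form oracle for
#' generator recovery tests.
#'
#' @param rho Reuse probability in [0, 1].
#' @param f_i Codon frequency, strictly inside (0, 1).
#' @return Expected diagonal percent deviation.
#' @examples
#' analytic_diagonal_pct(0.2, 0.25)  # 60
#' @export
analytic_diagonal_pct <- function(rho, f_i) {
  if (any(f_i <= 0 | f_i >= 1)) stop("f_i must lie strictly inside (0, 1)")
  100 * rho * (1 - f_i) / f_i
}

#' Estimate the reuse probability from diagonal percent deviations
#'
#' Inverts \code{\link{analytic_diagonal_pct}}: rho_hat =
#' (pct / 100) * f_i / (1 - f_i) per diagonal codon; the estimate is the
#' frequency-weighted mean over the family's diagonal cells.
#'
#' @param table A \code{deviation_table} computed with the consecutive
#'   strategy and pair-total normalisation.
#' @param profile The matching \code{class_profile}.
#' @return List with \code{per_codon} (named vector of per-codon
#'   estimates) and \code{rho_hat} (pooled estimate).
#' @export
estimate_rho <- function(table, profile) {
  diag_rows <- table$codon_i == table$codon_j &
    table$family == profile$family
  cods <- table$codon_i[diag_rows]
  f <- profile$f[cods]
  per <- (table$pct_dev[diag_rows] / 100) * f / (1 - f)
  names(per) <- cods
  list(per_codon = per, rho_hat = sum(per * f) / sum(f))
}

#' Write the ground-truth record as plain text
#'
#' Flat key=value lines (generator parameters) followed by tabular
#' per-family realized counts and analytic diagonal expectations.
#'
#' @param truth A \code{truth_record} from \code{\link{generate_genome}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  cf <- truth$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("n_genes=%d", cf$n_genes),
    sprintf("gene_length=%s", paste(cf$gene_length, collapse = ",")),
    sprintf("rho=%g", cf$rho),
    sprintf("reuse_mode=%s", cf$reuse_mode),
    sprintf("seed=%d", cf$seed),
    "", "family\tcodon\trealized_count\tanalytic_diag_pct"), con)
  for (nm in names(truth$realized_counts)) {
    cnt <- truth$realized_counts[[nm]]
    pct <- truth$analytic_diag_pct[[nm]]
    writeLines(sprintf("%s\t%s\t%d\t%.6g", nm, names(cnt), cnt,
                       pct[names(cnt)]), con)
  }
  invisible(path)
}
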