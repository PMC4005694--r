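# End-to-end analysis pipeline and Table-style rendering.

#' Analyze a set of coding sequences for codon pairing bias
#'
#' Runs the full chain over every synonymous family: occurrence streams,
#' ordered pair counts, class profile, independence expectation, the
#' three deviation statistics, and (optionally) the Monte-Carlo empirical
#' null with quantile flags.
#'
#' With \code{scope = "block"} (default) each family block (e.g. Ser4 and
#' Ser2) forms its own stream and is normalised by its own class total,
#' the arrangement under which such tables are usually published. With
#' \code{scope = "amino-acid"} one stream is built per amino acid (both
#' blocks of a 6-fold amino acid interleaved) and pairs are then
#' tabulated within each block, for sensitivity analysis.
#'
#' @param records List of validated \code{cds_record} objects (see
#'   \code{\link{validate_records}}).
#' @param families List of \code{synonymous_family} objects (default:
#'   full split-6-fold partition).
#' @param scope \code{"block"} or \code{"amino-acid"}.
#' @param strategy Pairing strategy (see \code{\link{count_pairs}}).
#' @param window Window for the windowed strategy.
#' @param normalization Expected-count normalisation (see
#'   \code{\link{expected_counts}}).
#' @param null_B,null_L Empirical-null replicate count and sequence
#'   length; \code{null_B = 0} skips the null entirely.
#' @param pseudocount Pseudocount for the log2 ratio (default 0.5).
#' @param sig_threshold Quantile threshold for significance flags.
#' @param seed Seed governing the null simulations (one RNG stream,
#'   families processed in name order, so results are reproducible).
#' @return An \code{analysis_result}: list with \code{table} (combined
#'   \code{deviation_table} over all families), \code{per_family} (list
#'   of per-family lists: \code{pairs}, \code{profile}, \code{expected},
#'   \code{table}, \code{null}), \code{params}, \code{n_records}.
#' @export
analyze_genome <- function(records,
                           families = partition_families(standard_code(11)),
                           scope = c("block", "amino-acid"),
                           strategy = c("consecutive", "all_pairs",
                                        "windowed"),
                           window = NULL,
                           normalization = c("class_occurrences",
                                             "pair_total"),
                           null_B = 0L, null_L = 1000L,
                           pseudocount = 0.5, sig_threshold = 0.95,
                           seed = 1L) {
  scope <- match.arg(scope)
  strategy <- match.arg(strategy)
  normalization <- match.arg(normalization)
  if (!length(records)) stop("no valid coding sequences to analyze")
  fam_names <- vapply(families, `[[`, "", "name")
  names(families) <- fam_names
  ord <- order(fam_names)
  families <- families[ord]
  if (!is.null(seed)) set.seed(seed)
  per_family <- list()
  for (fam in families) {
    if (scope == "block") {
      streams <- lapply(records, family_stream, family = fam)
      pairs <- count_pairs(streams, strategy = strategy, window = window,
                           codons = fam$codons)
      pairs$family <- fam$name
    } else {
      pairs <- aa_scope_pairs(records, fam, families, strategy, window)
    }
    profile <- suppressWarnings(class_profile(records, fam))
    if (profile$empty) {
      per_family[[fam$name]] <- list(pairs = pairs, profile = profile,
                                     expected = NULL,
                                     table = empty_deviation_table(),
                                     null = NULL)
      next
    }
    expected <- expected_counts(profile, normalization, pairs)
    null <- NULL
    if (null_B >= 1L)
      null <- simulate_null(profile, null_config(B = null_B, L = null_L),
                            pseudocount = pseudocount)
    tab <- assemble_deviation_table(pairs, expected, profile, null = null,
                                    pseudocount = pseudocount,
                                    sig_threshold = sig_threshold)
    per_family[[fam$name]] <- list(pairs = pairs, profile = profile,
                                   expected = expected, table = tab,
                                   null = null)
  }
  combined <- do.call(rbind, c(lapply(per_family, `[[`, "table"),
                               make.row.names = FALSE))
  class(combined) <- c("deviation_table", "data.frame")
  structure(list(table = combined, per_family = per_family,
                 params = list(scope = scope, strategy = strategy,
                               window = window,
                               normalization = normalization,
                               null_B = null_B, null_L = null_L,
                               pseudocount = pseudocount,
                               sig_threshold = sig_threshold, seed = seed),
                 n_records = length(records)),
            class = "analysis_result")
}

# amino-acid scope: one stream per amino acid over the union of its
# blocks' codons; pairs are counted over that union and the block's
# submatrix is retained
aa_scope_pairs <- function(records, fam, families, strategy, window) {
  share <- Filter(function(g) g$amino_acid == fam$amino_acid, families)
  universe <- sort(unique(unlist(lapply(share, `[[`, "codons"))))
  streams <- lapply(records, family_stream, family = universe)
  big <- count_pairs(streams, strategy = strategy, window = window,
                     codons = universe)
  counts <- big$counts[fam$codons, fam$codons, drop = FALSE]
  structure(list(family = fam$name, counts = counts,
                 strategy = big$strategy, window = big$window,
                 n_pairs = sum(counts)),
            class = "pair_count_table")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result> %d records, %d families, strategy=%s, scope=%s\n",
              x$n_records, length(x$per_family), x$params$strategy,
              x$params$scope))
  flagged <- sum(x$table$significant, na.rm = TRUE)
  cat(sprintf("  %d ordered pairs tabulated; %s\n", nrow(x$table),
              if (x$params$null_B >= 1L)
                sprintf("%d flagged at q >= %.2f", flagged,
                        x$params$sig_threshold)
              else "no empirical null run"))
  invisible(x)
}

format_block <- function(mat, digits = NULL) {
  out <- if (is.null(digits)) format(mat, trim = TRUE)
         else format(round(mat, digits), nsmall = digits, trim = TRUE)
  out
}

write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(mat, path, header_lines = character()) {
  df <- data.frame(codon = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path, header_lines)
}

params_echo <- function(params) {
  vapply(names(params), function(nm) {
    v <- params[[nm]]
    sprintf("%s=%s", nm, if (is.null(v)) "NA" else paste(v, collapse = ","))
  }, "")
}

#' Write an analysis to disk as aligned per-family blocks
#'
#' For each family writes four aligned square blocks (co-occurrence
#' counts; expected counts, displayed rounded to integers; percent
#' deviation to 3 decimals; empirical quantiles when a null was run) plus
#' one combined long-format table, a per-strategy block-total summary and
#' a run log. Every file header echoes the run parameters, so reruns
#' with identical inputs and seed are byte-identical.
#'
#' @param result An \code{analysis_result}.
#' @param out_dir Output directory (created if needed).
#' @param records The analyzed records (for the strategy-total summary
#'   and skipped-CDS accounting); optional.
#' @param families Families used (defaults to those in \code{result}).
#' @return \code{out_dir}, invisibly.
#' @export
write_analysis <- function(result, out_dir, records = NULL,
                           families = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- params_echo(result$params)
  for (nm in names(result$per_family)) {
    pf <- result$per_family[[nm]]
    if (isTRUE(pf$profile$empty)) next
    base <- file.path(out_dir, nm)
    write_matrix_tsv(pf$pairs$counts, paste0(base, "_counts.tsv"), hdr)
    write_matrix_tsv(round(pf$expected$expected),
                     paste0(base, "_expected.tsv"), hdr)
    k <- nrow(pf$pairs$counts)
    pct <- matrix(pf$table$pct_dev, k, k, byrow = TRUE,
                  dimnames = dimnames(pf$pairs$counts))
    write_matrix_tsv(format_block(pct, 3), paste0(base, "_pct.tsv"), hdr)
    if (!all(is.na(pf$table$quantile))) {
      qm <- matrix(pf$table$quantile, k, k, byrow = TRUE,
                   dimnames = dimnames(pf$pairs$counts))
      write_matrix_tsv(format_block(qm, 4), paste0(base, "_quantile.tsv"), hdr)
    }
  }
  long <- result$table
  long$expected <- sprintf("%.6f", long$expected)
  long$pct_dev <- sprintf("%.3f", long$pct_dev)
  long$z <- sprintf("%.4f", long$z)
  long$log2norm <- sprintf("%.6f", long$log2norm)
  long$quantile <- ifelse(is.na(result$table$quantile), "NA",
                          sprintf("%.4f", result$table$quantile))
  write_tsv(long, file.path(out_dir, "deviation_table.tsv"), hdr)
  log_lines <- c(hdr, sprintf("n_records=%d", result$n_records))
  if (!is.null(records)) {
    if (is.null(families)) {
      families <- partition_families(standard_code(11))
      families <- families[names(result$per_family)]
      families <- families[!vapply(families, is.null, TRUE)]
    }
    tot <- pair_total_summary(records, families,
                              window = if (is.null(result$params$window)) 10L
                                       else result$params$window)
    write_tsv(tot, file.path(out_dir, "strategy_totals.tsv"), hdr)
    skip <- attr(records, "skip_log")
    log_lines <- c(log_lines,
                   sprintf("n_skipped=%d", length(skip)), skip)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' File-level analysis entry point
#'
#' Reads CDS from a GenBank flat file or CDS FASTA (chosen by sniffing
#' the first non-blank line), validates and trims them, runs
#' \code{\link{analyze_genome}} and writes the output files.
#'
#' @param input Input path (GenBank flat file or FASTA).
#' @param out_dir Output directory.
#' @param include_partial,include_pseudo GenBank CDS toggles.
#' @param ... Passed to \code{\link{analyze_genome}}.
#' @return The \code{analysis_result}, invisibly.
#' @export
analyze <- function(input, out_dir, include_partial = FALSE,
                    include_pseudo = FALSE, ...) {
  if (!file.exists(input))
    stop("missing input: ", input,
         "\nusage: analyze(<genbank or fasta file>, <output dir>, ...)")
  first <- ""
  lines <- readLines(input, n = 20L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines)) first <- lines[1]
  records <- if (startsWith(first, ">"))
    read_fasta_cds(input)
  else
    read_genbank_cds(input, include_partial = include_partial,
                     include_pseudo = include_pseudo)
  records <- validate_records(records)
  if (!length(records)) stop("no valid coding sequences in ", input)
  args <- list(...)
  fams <- if (is.null(args$families))
    partition_families(standard_code(11)) else args$families
  result <- analyze_genome(records, ...)
  write_analysis(result, out_dir, records = records, families = fams)
  invisible(result)
}

#' Generate a synthetic genome and write it to disk
#'
#' Writes \code{genome.fasta} (one CDS per record) and
#' \code{truth.tsv} (generator parameters and ground truth) into
#' \code{out_dir}. Given identical configuration and seed the FASTA is
#' byte-identical across runs.
#'
#' @param config A \code{synthetic_config}.
#' @param out_dir Output directory.
#' @return List with \code{fasta}, \code{truth} file paths and the
#'   in-memory \code{records}/\code{truth}, invisibly.
#' @export
simulate_genome <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(config)
  fasta <- file.path(out_dir, "genome.fasta")
  truth <- file.path(out_dir, "truth.tsv")
  write_fasta_cds(gen$records, fasta)
  write_truth(gen$truth, truth)
  invisible(list(fasta = fasta, truth = truth,
                 records = gen$records, truth_record = gen$truth))
}

#' Load the shipped reference pair-count table
#'
#' Published co-occurrence and (rounded) independence-expected counts for
#' the Ser4/Ser2/Arg4/Arg2 codon families of the
#' \emph{M. thermautotrophicus} deltaH genome (NC_000916.1), ordered
#' pairs in long format. Useful for checking the percent-deviation
#' arithmetic against printed values.
#'
#' @return \code{data.frame} with columns \code{family}, \code{codon_i},
#'   \code{codon_j}, \code{count}, \code{expected}.
#' @export
mth_reference_pairs <- function() {
  utils::read.delim(system.file("extdata", "mth_ser_arg_reference.tsv",
                                package = "codonreuse", mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}
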