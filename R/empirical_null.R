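# Monte-Carlo empirical null for the per-pair log2 ratio.

#' Null simulation configuration
#'
#' @param B Number of random replicate sequences (analysis default 5000;
#'   a reduced B = 500 is used in tests for speed).
#' @param L Residues (family occurrences) per replicate sequence
#'   (default 1000).
#' @param seed Integer seed; \code{NULL} leaves the RNG state untouched.
#' @return A \code{null_config} list.
#' @export
null_config <- function(B = 5000L, L = 1000L, seed = NULL) {
  stopifnot(B >= 1L, L >= 2L)
  structure(list(B = as.integer(B), L = as.integer(L), seed = seed),
            class = "null_config")
}

#' Simulate the empirical null distribution of the log2 pair ratio
#'
#' For one family, draws B random sequences of L codons, each codon an
#' independent draw from the family's observed frequencies f, counts the
#' L - 1 adjacent ordered pairs of each sequence, and computes the log2
#' observed/expected ratio (\code{\link{log2_norm}}) per ordered pair per
#' replicate. This emulates scoring random protein sequences generated at
#' the class's codon usage, so the null carries the sampling noise of a
#' finite sequence but no positional dependence.
#'
#' @param profile A \code{class_profile}.
#' @param config A \code{null_config}.
#' @param pseudocount Pseudocount passed to \code{\link{log2_norm}}
#'   (default 0.5; use the same value for the observed table).
#' @return A \code{null_distribution}: list with \code{family},
#'   \code{values} (B x k^2 matrix, each column the ascending-sorted null
#'   values of one ordered pair, named "i->j"), \code{B}, \code{L},
#'   \code{pseudocount}, \code{f}.
#' @export
simulate_null <- function(profile, config = null_config(),
                          pseudocount = 0.5) {
  stopifnot(inherits(profile, "class_profile"))
  if (isTRUE(profile$empty)) {
    warning("empty profile for ", profile$family, ": null skipped",
            call. = FALSE)
    return(NULL)
  }
  f <- profile$f
  k <- length(f)
  if (sum(f > 0) < 2L) {
    warning("degenerate frequencies for ", profile$family,
            " (single codon): null skipped", call. = FALSE)
    return(NULL)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  B <- config$B; L <- config$L
  codons <- names(f)
  x <- matrix(sample.int(k, B * L, replace = TRUE, prob = f), nrow = L)
  pid <- (x[-L, , drop = FALSE] - 1L) * k + x[-1L, , drop = FALSE]
  counts <- vapply(seq_len(B),
                   function(b) tabulate(pid[, b], nbins = k * k),
                   integer(k * k))                       # k^2 x B
  f_i <- rep(f, each = k)
  f_j <- rep(f, times = k)
  vals <- log2_norm(counts, L - 1L, f_i, f_j, k, pseudocount)  # k^2 x B
  vals <- t(vals)                                        # B x k^2
  vals <- apply(vals, 2L, sort)
  if (B == 1L) vals <- matrix(vals, nrow = 1L)
  colnames(vals) <- paste0(rep(codons, each = k), "->", rep(codons, times = k))
  structure(list(family = profile$family, values = vals, B = B, L = L,
                 seed = config$seed, pseudocount = pseudocount, f = f),
            class = "null_distribution")
}

#' Locate observed log2 ratios in the empirical null
#'
#' quantile_ij = (number of null values <= observed log2norm_ij) / B,
#' a weak-inequality empirical quantile in [0, 1] (ties counted in).
#'
#' @param null A \code{null_distribution}.
#' @param observed A \code{deviation_table} for the same family.
#' @return The \code{deviation_table} with its \code{quantile} column
#'   filled (\code{NA}, with a warning, for pairs missing from the null).
#' @export
observed_quantile <- function(null, observed) {
  stopifnot(inherits(observed, "deviation_table"))
  if (is.null(null)) return(observed)
  fam_rows <- which(observed$family == null$family)
  if (!length(fam_rows))
    stop("families do not match: null is for ", null$family)
  keys <- paste0(observed$codon_i[fam_rows], "->", observed$codon_j[fam_rows])
  pos <- match(keys, colnames(null$values))
  if (anyNA(pos))
    warning("pairs missing from null: ",
            paste(keys[is.na(pos)], collapse = ", "), call. = FALSE)
  q <- rep(NA_real_, length(keys))
  for (ii in which(!is.na(pos))) {
    q[ii] <- findInterval(observed$log2norm[fam_rows[ii]],
                          null$values[, pos[ii]]) / null$B
  }
  observed$quantile[fam_rows] <- q
  observed
}

#' Flag significantly over-represented pairs
#'
#' A pair is flagged when its empirical quantile reaches the threshold
#' AND its percent deviation is positive (only over-representation is
#' evidence of tRNA reuse; extreme under-representation is not flagged).
#'
#' @param table A \code{deviation_table} with quantiles present.
#' @param threshold Quantile threshold in [0, 1] (default 0.95).
#' @return The table with its \code{significant} column set.
#' @export
flag_significant <- function(table, threshold = 0.95) {
  stopifnot(inherits(table, "deviation_table"),
            threshold >= 0, threshold <= 1)
  table$significant <- !is.na(table$quantile) &
    table$quantile >= threshold &
    !is.na(table$pct_dev) & table$pct_dev > 0
  table
}

#' Persist a null distribution as TSV
#'
#' Long format (pair, replicate, value), binary-free, for audit.
#'
#' @param null A \code{null_distribution}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_null_tsv <- function(null, path) {
  long <- data.frame(
    family = null$family,
    pair = rep(colnames(null$values), each = null$B),
    replicate = rep(seq_len(null$B), times = ncol(null$values)),
    value = as.vector(null$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# family=%s B=%d L=%d seed=%s pseudocount=%g",
                     null$family, null$B, null$L,
                     if (is.null(null$seed)) "NA" else null$seed,
                     null$pseudocount), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
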