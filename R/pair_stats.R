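# Expected-count model and the three per-pair deviation statistics.

#' Expected codon-pair counts under positional independence
#'
#' E_ij = N_used * f_i * f_j, the number of ordered pairs (i, j) expected
#' if successive synonymous codon choices were independent draws from the
#' family's codon frequencies. Two normalisations are available:
#' \code{class_occurrences} (default) takes N_used = N, the family's
#' class occurrence total; \code{pair_total} takes N_used = the number of
#' tabulated pairs, under which the expected matrix sums exactly to the
#' observed pair total (the properly normalised null used for
#' calibration).
#'
#' @param profile A \code{class_profile}.
#' @param normalization \code{"class_occurrences"} or \code{"pair_total"}.
#' @param pairs A \code{pair_count_table}; required for
#'   \code{pair_total}.
#' @return An \code{expected_table}: list with \code{family},
#'   \code{expected} (real matrix), \code{normalization}, \code{N_used}.
#' @export
expected_counts <- function(profile,
                            normalization = c("class_occurrences",
                                              "pair_total"),
                            pairs = NULL) {
  normalization <- match.arg(normalization)
  if (isTRUE(profile$empty)) {
    warning("empty class profile for ", profile$family,
            ": expected counts skipped", call. = FALSE)
    return(NULL)
  }
  N_used <- switch(normalization,
                   class_occurrences = profile$N,
                   pair_total = {
                     if (is.null(pairs))
                       stop("pair_total normalization needs the pair table")
                     pairs$n_pairs
                   })
  E <- N_used * outer(profile$f, profile$f)
  structure(list(family = profile$family, expected = E,
                 normalization = normalization, N_used = as.numeric(N_used)),
            class = "expected_table")
}

#' Percent deviation of a count from its expectation
#'
#' 100 * (C - E) / E; the sign gives the direction of the deviation
#' (positive = over-represented). Vectorised. Cells with E = 0 return
#' \code{NA} (never 0) with a warning when their count is positive.
#'
#' @param count Observed count(s) C.
#' @param expected Expected count(s) E.
#' @return Numeric percent deviation(s).
#' @examples
#' percent_deviation(3680, 3505)  # 4.993 (to 3 decimals)
#' @export
percent_deviation <- function(count, expected) {
  out <- 100 * (count - expected) / expected
  und <- expected == 0
  if (any(und & count > 0, na.rm = TRUE))
    warning("percent deviation undefined where expected = 0 and count > 0",
            call. = FALSE)
  out[und] <- NA_real_
  out
}

#' Binomial-model deviation in standard-deviation units
#'
#' z = (C - E) / sqrt(N * p * (1 - p)) with p = f_i * f_j: how many
#' binomial standard deviations the observed pair count lies from its
#' expectation when each of the N_used trials produces pair (i, j) with
#' probability p. Note sd/E -> 0 as N grows, so at genome scale even
#' small relative deviations score many standard deviations.
#'
#' @param count Observed count C.
#' @param expected Expected count E.
#' @param n_used Trial count N (the normalisation total used for E).
#' @param f_i,f_j Marginal codon frequencies.
#' @return z score(s); \code{NA} where p is 0 or 1.
#' @export
binomial_z <- function(count, expected, n_used, f_i, f_j) {
  p <- f_i * f_j
  sd <- sqrt(n_used * p * (1 - p))
  out <- (count - expected) / sd
  out[p <= 0 | p >= 1] <- NA_real_
  out
}

#' Log2 observed/expected pair ratio
#'
#' log2 of the joint probability of observing the ordered pair divided by
#' the product of the marginal codon probabilities:
#' log2( ((C + pc) / (n_pairs + pc * k^2)) / (f_i * f_j) ), where pc is a
#' pseudocount (default 0.5) shared across the k^2 cells of the family's
#' pair matrix, guarding zero counts; set \code{pseudocount = 0} for the
#' bare definition (finite whenever C > 0).
#'
#' @param count Observed count C.
#' @param n_pairs Total tabulated pairs in the family.
#' @param f_i,f_j Marginal codon frequencies.
#' @param family_size Number of codons k in the family.
#' @param pseudocount Pseudocount (default 0.5).
#' @return log2 ratio(s) in bits.
#' @export
log2_norm <- function(count, n_pairs, f_i, f_j, family_size,
                      pseudocount = 0.5) {
  p_hat <- (count + pseudocount) / (n_pairs + pseudocount * family_size^2)
  log2(p_hat / (f_i * f_j))
}

#' Assemble the full per-pair deviation table
#'
#' Combines counts, expectations and the three deviation statistics into
#' one long-format table, one row per ordered codon pair; when an
#' empirical null is supplied the observed log2 ratios are additionally
#' located as quantiles and flagged.
#'
#' @param pairs A \code{pair_count_table}.
#' @param expected An \code{expected_table} for the same family.
#' @param profile The matching \code{class_profile}.
#' @param null Optional \code{null_distribution}
#'   (see \code{\link{simulate_null}}).
#' @param pseudocount Pseudocount for \code{\link{log2_norm}}
#'   (default 0.5; must match the null's if one is supplied).
#' @param sig_threshold Quantile threshold for
#'   \code{\link{flag_significant}} (default 0.95).
#' @return A \code{deviation_table}: data.frame with columns
#'   \code{family}, \code{codon_i}, \code{codon_j}, \code{count},
#'   \code{expected}, \code{pct_dev}, \code{z}, \code{log2norm},
#'   \code{quantile}, \code{significant}; attributes record the
#'   normalisation, N_used, n_pairs and strategy.
#' @export
assemble_deviation_table <- function(pairs, expected, profile, null = NULL,
                                     pseudocount = 0.5,
                                     sig_threshold = 0.95) {
  if (is.null(expected) || isTRUE(profile$empty)) {
    return(empty_deviation_table())
  }
  stopifnot(identical(pairs$family, expected$family) || is.na(pairs$family),
            identical(expected$family, profile$family))
  codons <- names(profile$f)
  if (!identical(rownames(pairs$counts), codons) ||
      !identical(rownames(expected$expected), codons))
    stop("dimension mismatch between pair counts, expected table and profile")
  k <- length(codons)
  grid <- expand.grid(codon_j = codons, codon_i = codons,
                      stringsAsFactors = FALSE)[, c("codon_i", "codon_j")]
  C <- pairs$counts[cbind(grid$codon_i, grid$codon_j)]
  E <- expected$expected[cbind(grid$codon_i, grid$codon_j)]
  f_i <- profile$f[grid$codon_i]
  f_j <- profile$f[grid$codon_j]
  tab <- data.frame(
    family = profile$family,
    codon_i = grid$codon_i, codon_j = grid$codon_j,
    count = as.integer(C), expected = E,
    pct_dev = percent_deviation(C, E),
    z = binomial_z(C, E, expected$N_used, f_i, f_j),
    log2norm = log2_norm(C, pairs$n_pairs, f_i, f_j, k, pseudocount),
    quantile = NA_real_, significant = NA,
    row.names = NULL)
  attr(tab, "normalization") <- expected$normalization
  attr(tab, "N_used") <- expected$N_used
  attr(tab, "n_pairs") <- pairs$n_pairs
  attr(tab, "strategy") <- pairs$strategy
  attr(tab, "pseudocount") <- pseudocount
  class(tab) <- c("deviation_table", "data.frame")
  if (!is.null(null)) {
    tab <- observed_quantile(null, tab)
    tab <- flag_significant(tab, sig_threshold)
  }
  tab
}

empty_deviation_table <- function() {
  tab <- data.frame(family = character(), codon_i = character(),
                    codon_j = character(), count = integer(),
                    expected = numeric(), pct_dev = numeric(),
                    z = numeric(), log2norm = numeric(),
                    quantile = numeric(), significant = logical())
  class(tab) <- c("deviation_table", "data.frame")
  tab
}
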