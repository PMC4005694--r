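# Reading and validating coding sequences from GenBank flat files or FASTA.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

new_cds_record <- function(gene_id, codons, strand = "+",
                           masked_positions = integer(),
                           source_coords = NA_character_,
                           valid = TRUE, reason = NA_character_,
                           flags = character()) {
  structure(list(gene_id = gene_id, strand = strand, codons = codons,
                 masked_positions = as.integer(masked_positions),
                 source_coords = source_coords, valid = valid,
                 reason = reason, flags = flags),
            class = "cds_record")
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record> %s (%s) %d codons%s%s\n", x$gene_id, x$strand,
              length(x$codons),
              if (length(x$masked_positions))
                sprintf(", %d masked", length(x$masked_positions)) else "",
              if (!x$valid) sprintf(" [invalid: %s]", x$reason) else ""))
  invisible(x)
}

# split a nucleotide string into codons; returns NULL (caller warns) if the
# length is not a multiple of 3
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L || n == 0L) return(NULL)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

masked_idx <- function(codons) {
  which(grepl("[^ACGT]", codons))
}

make_record <- function(gene_id, seq, strand = "+", source_coords = NA) {
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, NULL)[[1]]), IUPAC_CHARS)
  if (length(bad))
    stop("record '", gene_id, "' contains non-IUPAC characters: ",
         paste(bad, collapse = ""))
  codons <- split_codons(seq)
  if (is.null(codons)) return(NULL)
  new_cds_record(gene_id, codons, strand, masked_idx(codons),
                 source_coords = as.character(source_coords))
}

# -- FASTA -------------------------------------------------------------------

#' Read coding sequences from a CDS FASTA file
#'
#' One CDS per record. The first whitespace-delimited header token becomes
#' the gene id; lowercase bases are accepted and upper-cased; codons
#' containing IUPAC ambiguity codes are kept in place but masked (excluded
#' from all downstream counting). Records whose length is not a multiple
#' of 3 are skipped with a warning.
#'
#' @param path FASTA file path.
#' @return List of \code{cds_record} objects, with a character vector of
#'   skip messages in \code{attr(, "skip_log")}.
#' @export
read_fasta_cds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  records <- list(); log <- character()
  for (i in seq_along(seqs)) {
    rec <- make_record(ids[i], as.character(seqs[[i]]))
    if (is.null(rec)) {
      msg <- sprintf("skipped %s: length %d not a multiple of 3",
                     ids[i], length(seqs[[i]]))
      warning(msg, call. = FALSE)
      log <- c(log, msg)
    } else records[[length(records) + 1L]] <- rec
  }
  attr(records, "skip_log") <- log
  records
}

#' Write coding sequences to FASTA
#'
#' Inverse of \code{\link{read_fasta_cds}}: codon lists (including masked
#' codons, whose ambiguous bases are preserved) are concatenated and
#' written 60 columns wide, so a write/read round trip reproduces codons
#' and masks exactly.
#'
#' @param records List of \code{cds_record} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_cds <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, function(r)
    paste(r$codons, collapse = ""), ""))
  names(seqs) <- vapply(records, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# -- GenBank flat file -------------------------------------------------------

# location grammar: 123..456 | 123 | complement(X) | join(X,Y,...) | order(...)
# returns list(seq = mRNA-sense sequence, partial = logical)
resolve_location <- function(loc, genome, feature_id) {
  loc <- gsub("\\s", "", loc)
  partial <- grepl("[<>]", loc)
  loc <- gsub("[<>]", "", loc)
  resolve <- function(expr) {
    if (grepl("^complement\\(", expr)) {
      inner <- substr(expr, 12L, nchar(expr) - 1L)
      return(revcomp_chr(resolve(inner)))
    }
    if (grepl("^(join|order)\\(", expr)) {
      inner <- sub("^(join|order)\\(", "", expr)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      parts <- split_toplevel(inner)
      return(paste(vapply(parts, resolve, ""), collapse = ""))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", expr)) {
      ab <- as.integer(strsplit(expr, "..", fixed = TRUE)[[1]])
      if (ab[1] > ab[2] || ab[2] > nchar(genome))
        stop("location out of range in feature ", feature_id, ": ", expr)
      return(substr(genome, ab[1], ab[2]))
    }
    if (grepl("^[0-9]+$", expr)) {
      p <- as.integer(expr)
      if (p > nchar(genome))
        stop("location out of range in feature ", feature_id, ": ", expr)
      return(substr(genome, p, p))
    }
    stop("cannot parse location of feature ", feature_id, ": ", expr)
  }
  list(seq = resolve(loc), partial = partial,
       strand = grepl("complement", loc))
}

# split "a..b,complement(c..d)" at top-level commas only
split_toplevel <- function(x) {
  depth <- 0L; out <- character(); cur <- ""
  for (ch in strsplit(x, NULL)[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) { out <- c(out, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

parse_genbank_entry <- function(lines, entry_no) {
  feat_start <- grep("^FEATURES", lines)
  orig_start <- grep("^ORIGIN", lines)
  if (!length(orig_start))
    stop("GenBank entry ", entry_no, " has no ORIGIN section")
  seq_lines <- lines[(orig_start[1] + 1L):length(lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(genome))
    stop("GenBank entry ", entry_no, " has an empty sequence")
  features <- list()
  if (length(feat_start)) {
    flines <- lines[(feat_start[1] + 1L):(orig_start[1] - 1L)]
    cur <- NULL
    for (ln in flines) {
      if (grepl("^ {5}\\S", ln)) {               # new feature
        if (!is.null(cur)) features[[length(features) + 1L]] <- cur
        key <- sub("^ +", "", substr(ln, 1L, 20L))
        key <- sub(" +$", "", key)
        cur <- list(key = key,
                    loc_text = trimws(substr(ln, 21L, nchar(ln))),
                    quals = character())
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
        else if (length(cur$quals) == 0L)        # location continuation
          cur$loc_text <- paste0(cur$loc_text, txt)
        else                                      # qualifier continuation
          cur$quals[length(cur$quals)] <-
            paste0(cur$quals[length(cur$quals)], txt)
      }
    }
    if (!is.null(cur)) features[[length(features) + 1L]] <- cur
  }
  list(genome = genome, features = features)
}

qual_value <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
}

#' Read CDS features from a GenBank flat file
#'
#' Parses one or more GenBank entries and returns each CDS feature as a
#' \code{cds_record}, with minus-strand (\code{complement}) and
#' multi-segment (\code{join}) locations resolved to the mRNA-sense
#' nucleotide sequence before codon splitting. Features marked partial
#' (\code{<}/\code{>} in the location) and features carrying a
#' \code{/pseudo} qualifier are excluded by default. CDS whose resolved
#' length is not a multiple of 3 are skipped with a warning; all skip
#' reasons are collected in \code{attr(, "skip_log")}.
#'
#' @param path GenBank flat file path.
#' @param include_partial Keep partial CDS features (default \code{FALSE}).
#' @param include_pseudo Keep \code{/pseudo} CDS features (default
#'   \code{FALSE}).
#' @return List of \code{cds_record} objects with a \code{skip_log}
#'   attribute.
#' @export
read_genbank_cds <- function(path, include_partial = FALSE,
                             include_pseudo = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(lines))) {
    warning("empty GenBank file: ", path, call. = FALSE)
    out <- list(); attr(out, "skip_log") <- "empty file"
    return(out)
  }
  ends <- grep("^//", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- list(); log <- character(); n_cds <- 0L
  for (e in seq_along(starts)) {
    chunk <- lines[starts[e]:ends[e]]
    chunk <- chunk[!grepl("^//", chunk)]
    if (!any(nzchar(chunk))) next
    entry <- parse_genbank_entry(chunk, e)
    for (feat in entry$features) {
      if (feat$key != "CDS") next
      n_cds <- n_cds + 1L
      gene_id <- qual_value(feat$quals, "locus_tag")
      if (is.na(gene_id)) gene_id <- qual_value(feat$quals, "gene")
      if (is.na(gene_id)) gene_id <- sprintf("CDS_%d", n_cds)
      skip <- function(why) {
        msg <- sprintf("skipped %s (%s): %s", gene_id, feat$loc_text, why)
        warning(msg, call. = FALSE)
        log <<- c(log, msg)
      }
      if (!include_pseudo &&
          any(grepl("^/pseudo($|=)", feat$quals))) { skip("pseudo"); next }
      res <- resolve_location(feat$loc_text, entry$genome, gene_id)
      if (res$partial && !include_partial) { skip("partial"); next }
      codons <- split_codons(res$seq)
      if (is.null(codons)) { skip("length not a multiple of 3"); next }
      records[[length(records) + 1L]] <-
        new_cds_record(gene_id, codons,
                       strand = if (res$strand) "-" else "+",
                       masked_positions = masked_idx(codons),
                       source_coords = feat$loc_text)
    }
  }
  attr(records, "skip_log") <- log
  records
}

# -- validation --------------------------------------------------------------

#' Validate a CDS record and trim its terminal stop codon
#'
#' Removes a terminal stop codon if present (flagging
#' \code{no_terminal_stop} otherwise); a record containing an unmasked
#' internal stop codon is returned invalid with reason
#' \code{internal_stop}; a record that is empty after trimming is invalid
#' with reason \code{empty}. Masked codons are never interpreted as stops.
#'
#' @param record A \code{cds_record}.
#' @param code A \code{genetic_code} (default table 11).
#' @return The updated \code{cds_record}; check \code{$valid} and
#'   \code{$reason}.
#' @export
validate_and_trim <- function(record, code = standard_code(11)) {
  stopifnot(inherits(record, "cds_record"))
  map <- code$codon_to_aa
  codons <- record$codons
  masked <- record$masked_positions
  n <- length(codons)
  if (n == 0L) { record$valid <- FALSE; record$reason <- "empty"; return(record) }
  is_stop <- logical(n)
  unmasked <- setdiff(seq_len(n), masked)
  is_stop[unmasked] <- map[codons[unmasked]] == STOP_AA
  if (is_stop[n]) {
    codons <- codons[-n]
    is_stop <- is_stop[-n]
    masked <- masked[masked < n]
    n <- n - 1L
  } else {
    record$flags <- union(record$flags, "no_terminal_stop")
  }
  if (n == 0L) { record$valid <- FALSE; record$reason <- "empty"; return(record) }
  if (any(is_stop)) {
    record$valid <- FALSE
    record$reason <- "internal_stop"
    return(record)
  }
  record$codons <- codons
  record$masked_positions <- masked
  record$valid <- TRUE
  record
}

#' Validate and trim a whole CDS set
#'
#' Applies \code{\link{validate_and_trim}} to every record and drops the
#' invalid ones, logging each rejection.
#'
#' @inheritParams validate_and_trim
#' @param records List of \code{cds_record} objects.
#' @return List of valid, stop-trimmed records; rejection messages in
#'   \code{attr(, "skip_log")} (appended to any incoming log).
#' @export
validate_records <- function(records, code = standard_code(11)) {
  log <- attr(records, "skip_log")
  out <- list()
  for (r in records) {
    v <- validate_and_trim(r, code)
    if (v$valid) out[[length(out) + 1L]] <- v
    else log <- c(log, sprintf("rejected %s: %s", r$gene_id, v$reason))
  }
  attr(out, "skip_log") <- log
  out
}
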